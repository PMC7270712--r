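#' Normalised mutual information between two images
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` computed from the joint histogram
#' over the overlap of the two nonzero supports. Intensity limits are
#' taken from the 1st-99th percentiles of each image inside the
#' overlap, which keeps the binning robust to background zeros and
#' stray extremes. Higher values mean more similar; `nmi(X, X) = 2`
#' for any non-constant X and independent images approach 1.
#'
#' @param image_a,image_b images (or bare 3D arrays) on the same grid.
#' @param bins number of histogram bins per image (>= 8).
#' @return a number in (0, 2].
#' @export
nmi <- function(image_a, image_b, bins = 32L) {
  a <- if (is.list(image_a)) image_a$data else image_a
  b <- if (is.list(image_b)) image_b$data else image_b
  if (!all(dim(a) == dim(b)))
    stop("nmi requires images on the same grid")
  if (bins < 8L) stop("nmi requires bins >= 8")
  nmi_arrays(as.vector(a), as.vector(b), bins)
}

nmi_arrays <- function(a, b, bins) {
  ov <- a != 0 & b != 0
  if (!any(ov)) stop("nmi: the nonzero supports of the two images do not overlap")
  a <- a[ov]; b <- b[ov]
  ia <- bin_index(a, bins)
  ib <- bin_index(b, bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  hab <- entropy_p(p)
  ha <- entropy_p(rowSums(matrix(p, bins, bins)))
  hb <- entropy_p(colSums(matrix(p, bins, bins)))
  if (hab == 0) return(1)   # both constant on the overlap
  (ha + hb) / hab
}

bin_fixed <- function(v, lims, bins) {
  lo <- lims[1]; hi <- lims[2]
  if (hi <= lo) hi <- lo + 1
  i <- floor((v - lo) / (hi - lo) * bins) + 1L
  pmax(1L, pmin(bins, as.integer(i)))
}

range_or <- function(v) {
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
  if (q[2] <= q[1]) q <- range(v)
  q
}

bin_index <- function(v, bins) {
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
  lo <- q[1]; hi <- q[2]
  if (hi <= lo) { lo <- min(v); hi <- max(v) }
  if (hi <= lo) hi <- lo + 1
  i <- floor((v - lo) / (hi - lo) * bins) + 1L
  pmax(1L, pmin(bins, as.integer(i)))
}

entropy_p <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# robust support mask of a volume: above 5% of its 99th percentile
auto_support <- function(image) {
  v <- image$data
  thr <- 0.05 * stats::quantile(v[v > 0], 0.99, names = FALSE, type = 7)
  if (!is.finite(thr)) thr <- 0
  v > thr
}

support_centroid <- function(image, mask = NULL) {
  m <- if (!is.null(mask)) mask$data == 1L else auto_support(image)
  if (!any(m)) stop("image has no support for centroid pre-alignment")
  idx <- arrayInd(which(m), dim(image$data)) - 1L
  colMeans(voxel_to_world(image$affine, idx))
}

masked_volume <- function(image, mask) {
  if (is.null(mask)) return(image)
  volume_image(image$data * (mask$data == 1L), image$affine)
}

#' Rigid-body image registration
#'
#' Estimates the 6-parameter rigid transform that best aligns `source`
#' to `target` by maximising normalised mutual information (or an SSD
#' option for same-contrast images) over a 3-level multiresolution
#' pyramid (x4, x2, x1 downsampling of the target grid) with a
#' derivative-free direction-set (Powell) search per level, preceded
#' at the coarsest level by an exhaustive rotation sweep that guards
#' against secondary basins. When brain masks are supplied the
#' metric is evaluated on the brain-extracted images, but the returned
#' transform applies to whole heads. The search is initialised by
#' aligning support centroids and is fully deterministic.
#'
#' The returned transform maps target world coordinates into source
#' world coordinates, i.e. `resample(source, target, transform)`
#' produces the aligned source.
#'
#' @param source,target `volume_image`s.
#' @param source_mask,target_mask optional `mask_image`s gating the
#'   metric.
#' @param metric `"nmi"` (default) or `"ssd"`.
#' @param bins histogram bins for NMI.
#' @param pyramid integer downsampling factors, coarse to fine.
#' @param init optional `affine_transform` used as the initial guess
#'   instead of centroid alignment.
#' @param sweeps direction-set (Powell) sweeps per level (recycled).
#' @return an `affine_transform` tagged `rigid6`. If the optimiser
#'   fails to improve on its initialisation the best transform found
#'   is returned with attribute `warning` set.
#' @export
register_rigid <- function(source, target, source_mask = NULL,
                           target_mask = NULL, metric = c("nmi", "ssd"),
                           bins = 32L, pyramid = c(4L, 2L, 1L),
                           init = NULL, sweeps = c(8L, 6L, 4L)) {
  metric <- match.arg(metric)
  reg_linear(source, target, source_mask, target_mask, metric, bins,
             pyramid, init, sweeps, dof = "rigid6")
}

#' Affine (12-parameter) image registration
#'
#' As [register_rigid()], with scales and shears added; the search is
#' initialised at the rigid solution, so the affine similarity score
#' can never fall below the rigid one on the final level.
#'
#' @inheritParams register_rigid
#' @return an `affine_transform` tagged `affine12`.
#' @export
register_affine <- function(source, target, source_mask = NULL,
                            target_mask = NULL, metric = c("nmi", "ssd"),
                            bins = 32L, pyramid = c(4L, 2L, 1L),
                            init = NULL, sweeps = c(8L, 6L, 5L)) {
  metric <- match.arg(metric)
  if (is.null(init))
    init <- register_rigid(source, target, source_mask, target_mask,
                           metric = metric, bins = bins, pyramid = pyramid)
  reg_linear(source, target, source_mask, target_mask, metric, bins,
             pyramid, init, sweeps, dof = "affine12")
}

reg_linear <- function(source, target, source_mask, target_mask, metric,
                       bins, pyramid, init, sweeps, dof) {
  npar <- if (dof == "rigid6") 6L else 12L
  sweeps <- rep_len(sweeps, length(pyramid))
  # the metric sees lightly smoothed copies of both images: resampling
  # the moving image attenuates its highest frequencies, and comparing
  # it against an unsmoothed fixed image biases the optimum (grid
  # locking, scale shrinkage); symmetric smoothing removes the bias
  src <- masked_volume(source, source_mask)
  tgt <- masked_volume(target, target_mask)
  src <- volume_image(smooth121(src$data), src$affine)
  tgt <- volume_image(smooth121(tgt$data), tgt$affine)
  center <- grid_center_world(target)

  p0 <- numeric(npar)
  if (is.null(init)) {
    # translation taking the target centroid onto the source centroid
    # (pull-back: target world -> source world)
    p0[4:6] <- support_centroid(src) - support_centroid(tgt)
  } else {
    p0 <- params_from_affine(init, center, npar)
  }

  make_tf <- function(p) {
    if (dof == "rigid6") rigid_transform(p, center)
    else affine12_transform(p, center)
  }

  vs <- voxel_sizes(target)
  src_arr <- src$data
  src_inv <- solve(src$affine)
  src_vals <- src_arr[src_arr != 0]
  src_lims <- if (length(src_vals))
    stats::quantile(src_vals, c(0.01, 0.99), names = FALSE, type = 7)
  else c(0, 1)
  # never downsample below ~8 voxels per axis: tiny levels lose the
  # similarity basin entirely
  min_dim <- min(grid_shape(target))
  pyramid <- vapply(pyramid, function(f) {
    while (f > 1L && min_dim / f < 8) f <- f %/% 2L
    as.integer(max(f, 1L))
  }, 1L)
  keep <- !duplicated(pyramid)
  pyramid <- pyramid[keep]
  sweeps <- sweeps[keep]
  for (lev in seq_along(pyramid)) {
    f <- pyramid[lev]
    tgt_l <- downsample_volume(tgt, f)
    tgt_arr <- tgt_l$data
    tgt_sup <- which(tgt_arr != 0)
    if (length(tgt_sup) == 0) tgt_sup <- seq_along(tgt_arr)
    # cap the metric sample count: a strided subset of the support
    # carries the same information at a fraction of the cost
    if (length(tgt_sup) > 24000L)
      tgt_sup <- tgt_sup[seq(1L, length(tgt_sup),
                             by = ceiling(length(tgt_sup) / 24000L))]
    grid_l <- as_grid(tgt_l)
    bins_l <- max(8L, as.integer(round(bins / f)))
    # fixed per level: domain world coords, target bins, intensity limits
    pts <- voxel_to_world(grid_l$affine,
                          index_grid0(grid_l$shape)[tgt_sup, , drop = FALSE])
    pts1 <- cbind(pts, 1)
    tgt_dom <- tgt_arr[tgt_sup]
    tgt_bins <- bin_fixed(tgt_dom, range_or(tgt_dom), bins_l)
    cost <- function(p) {
      M <- src_inv %*% make_tf(p)$matrix
      vox <- pts1 %*% t(M[1:3, , drop = FALSE])
      w <- interpolate_at(src_arr, vox, "trilinear")
      if (metric == "ssd") return(mean((w - tgt_dom)^2))
      wb <- bin_fixed(w, src_lims, bins_l)
      joint <- tabulate(wb + bins_l * (tgt_bins - 1L), nbins = bins_l * bins_l)
      p_ <- joint / length(wb)
      hab <- entropy_p(p_)
      if (hab == 0) return(-1)
      -(entropy_p(rowSums(matrix(p_, bins_l, bins_l))) +
          entropy_p(colSums(matrix(p_, bins_l, bins_l)))) / hab
    }
    if (lev == 1L && dof == "rigid6" && is.null(init)) {
      # exhaustive rotation sweep at the coarsest level: the metric can
      # have a secondary basin at identity for near-symmetric anatomy
      best <- cost(p0); best_p <- p0
      for (rx in seq(-9, 9, by = 3)) for (ry in seq(-9, 9, by = 3))
        for (rz in seq(-9, 9, by = 3)) {
          p <- p0; p[1:3] <- p0[1:3] + c(rx, ry, rz)
          v <- cost(p)
          if (v < best) { best <- v; best_p <- p }
        }
      p0 <- best_p
    }
    # per-level search scales: degrees and multiples of the level's
    # voxel size (log-scale / shear units for the affine extras)
    scales <- c(rep(8 / 2^(lev - 1), 3), 4 * vs * f)
    if (npar == 12L) scales <- c(scales, rep(0.08 / lev, 3),
                                 rep(0.08 / lev, 3))
    res <- powell_minimize(p0, cost, scales, outer = sweeps[lev])
    last_cost <- res$value
    if (lev == length(pyramid)) {
      # Powell's direction set degenerates along ridges; if the final
      # level was still moving when it stopped, restart it with a
      # fresh (shrunken) direction set
      for (round in 2:4) {
        moved <- sqrt(sum(((res$par - p0) / scales)^2))
        p0 <- res$par
        if (moved < 0.05) break
        res <- powell_minimize(p0, cost, scales / round,
                               outer = sweeps[lev])
      }
    }
    p0 <- res$par
    last_cost <- res$value
  }

  out <- make_tf(p0)
  out$params <- p0
  out$center <- center
  # guard: the search must have produced a usable similarity
  if (!is.finite(last_cost)) {
    warning("registration failed to produce a finite similarity; ",
            "returning best transform found")
    attr(out, "warning") <- "non-finite final similarity"
  }
  out
}

# recover optimisation parameters from an affine transform about `center`
params_from_affine <- function(tf, center, npar) {
  M <- tf$matrix
  A <- M[1:3, 1:3]
  t <- M[1:3, 4] - center + A %*% center
  if (npar == 6L) {
    ang <- angles_from_rotation(A)
    return(c(ang, t))
  }
  # polar-like decomposition consistent with affine12_transform: A = R G S
  qr_ <- qr(A)
  R <- qr.Q(qr_); U <- qr.R(qr_)
  sg <- sign(diag(U)); sg[sg == 0] <- 1
  R <- R %*% diag(sg); U <- diag(sg) %*% U
  if (det(R) < 0) { R <- -R; U <- -U }
  s <- diag(U)
  G <- U %*% diag(1 / s)
  c(angles_from_rotation(R), t, log(s), G[1, 2], G[1, 3], G[2, 3])
}

angles_from_rotation <- function(R) {
  # inverse of Rz Ry Rx (degrees)
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

# Powell's direction-set minimisation with Brent line searches: the
# classical derivative-free optimiser of intensity-based registration.
# `scales` sets the unit step of each parameter; after each sweep over
# the direction set the aggregate move replaces the direction of the
# largest single decrease (conjugate-direction update), which copes
# with the ridge-shaped similarity surfaces of coupled parameters.
powell_minimize <- function(p0, fn, scales, outer = 6L, span = 1.5,
                            line_tol = 1e-3) {
  n <- length(p0)
  dirs <- diag(scales, n)
  p <- p0
  fp <- fn(p)
  for (it in seq_len(outer)) {
    p_start <- p; f_start <- fp
    biggest <- 0; bigdir <- 1L
    for (i in seq_len(n)) {
      d <- dirs[, i]
      ls <- stats::optimize(function(t) fn(p + t * d), c(-span, span),
                            tol = line_tol)
      if (ls$objective < fp) {
        if (fp - ls$objective > biggest) {
          biggest <- fp - ls$objective; bigdir <- i
        }
        p <- p + ls$minimum * d
        fp <- ls$objective
      }
    }
    dnew <- p - p_start
    if (sqrt(sum((dnew / scales)^2)) < 1e-6) break
    ls <- stats::optimize(function(t) fn(p + t * dnew), c(-1, 2),
                          tol = line_tol)
    if (ls$objective < fp) {
      p <- p + ls$minimum * dnew
      fp <- ls$objective
    }
    dirs[, bigdir] <- dnew
    if (f_start - fp < 1e-12) break
  }
  list(par = p, value = fp)
}
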