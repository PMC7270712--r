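#' Polynomial bias-field correction
#'
#' Models the smooth multiplicative intensity non-uniformity of
#' high-field MR images as the exponential of a low-order spatial
#' polynomial, estimated by least squares on log-intensities inside
#' the head. Because anatomy itself contributes structured
#' log-intensity variation, the fit targets a single reference tissue
#' class: a first pass removes only a linear trend (so tissue classes
#' stay separated in the residual), then the voxels of the sharpest
#' residual mode are selected as the reference class and the
#' full-order polynomial is refitted on them, iterating selection and
#' fit. Tissue contrast is thereby kept out of the field. The
#' estimated field is normalised to mean 1 over the head mask.
#'
#' @param image `volume_image`, positive within the head (zeros
#'   allowed in the background).
#' @param poly_order polynomial order, 2, 3 or 4 (default 3).
#' @param head_mask optional `mask_image`; when absent it is derived
#'   by histogram-valley thresholding of the image.
#' @param n_refine trimming/refit iterations targeting the dominant
#'   tissue class.
#' @return a `bias_result` list: `corrected` (image / field), `field`
#'   (multiplicative, mean 1 within the head mask, strictly positive
#'   everywhere) and `head_mask`. `corrected * field` reconstructs the
#'   input to within floating-point rounding.
#' @export
correct_bias <- function(image, poly_order = 3L, head_mask = NULL,
                         n_refine = 4L) {
  if (!poly_order %in% 2:4) stop("poly_order must be 2, 3 or 4")
  if (is.null(head_mask)) {
    thr <- histogram_valley_threshold(image$data)
    m <- image$data > thr
    if (!any(m)) stop("automatic head mask is empty")
    head_mask <- mask_image(array(as.integer(m), dim = dim(image$data)),
                            image$affine)
  }
  hm <- head_mask$data == 1L & image$data > 0
  if (!any(hm)) stop("head mask is empty (or covers no positive voxels)")
  if (diff(range(image$data)) == 0)
    stop("image is constant; bias fit is degenerate")

  sh <- grid_shape(image)
  xyz <- voxel_to_world(image$affine, index_grid0(sh))
  xyz <- sweep(xyz, 2, colMeans(xyz))
  xyz <- sweep(xyz, 2, apply(abs(xyz), 2, max), "/")
  X <- poly_design(xyz, poly_order)
  X1 <- X[, 1:4, drop = FALSE]   # linear sub-design

  sel <- which(hm)
  logi_all <- suppressWarnings(log(image$data))
  fit_field <- function(sel_idx, design) {
    cf <- stats::lm.fit(design[sel_idx, , drop = FALSE],
                        logi_all[sel_idx])$coefficients
    cf[is.na(cf)] <- 0
    drop(design %*% cf)
  }
  # First pass with a linear field only: a full-order first fit would
  # absorb the (smooth, e.g. radial) anatomy and blur the tissue
  # classes together in the residual. The residual after the linear
  # pass still separates tissue classes, whose sharpest mode is then
  # used as the reference class for the full-order fit.
  logf <- fit_field(sel, X1)
  for (i in seq_len(n_refine)) {
    res <- logi_all[sel] - logf[sel]
    ctr <- residual_mode(res)
    keep <- abs(res - ctr) < 0.12
    if (sum(keep) < ncol(X) * 3) break
    logf <- fit_field(sel[keep], X)
  }
  field <- exp(logf)
  field <- field / mean(field[hm])
  field_arr <- array(field, dim = sh)
  corrected <- image$data / field_arr
  structure(list(corrected = volume_image(corrected, image$affine),
                 field = volume_image(field_arr, image$affine),
                 head_mask = head_mask),
            class = "bias_result")
}

# centre of the tallest smoothed-histogram mode of a residual sample
residual_mode <- function(res, bins = 64L, sigma = 2) {
  rng <- range(res)
  if (diff(rng) == 0) return(res[1])
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(res, br, rightmost.closed = TRUE),
                          1L), bins), nbins = bins)
  k <- seq(-ceiling(3 * sigma), ceiling(3 * sigma))
  kern <- exp(-k^2 / (2 * sigma^2)); kern <- kern / sum(kern)
  hp <- c(rep(h[1], length(k) %/% 2), h, rep(h[bins], length(k) %/% 2))
  hs <- as.numeric(stats::filter(hp, kern, sides = 2))
  hs <- hs[seq_len(bins) + length(k) %/% 2]
  peak <- which.max(hs)
  (br[peak] + br[peak + 1L]) / 2
}

poly_design <- function(xyz, order) {
  cols <- list(rep(1, nrow(xyz)))
  for (total in 1:order)
    for (i in 0:total) for (j in 0:(total - i)) {
      k <- total - i - j
      cols[[length(cols) + 1]] <- xyz[, 1]^i * xyz[, 2]^j * xyz[, 3]^k
    }
  do.call(cbind, cols)
}

# deepest smoothed-histogram valley between the two most prominent
# peaks (64 bins, Gaussian smoothing sigma = 2 bins); ties broken
# toward the lower threshold
histogram_valley_threshold <- function(arr, bins = 64L, sigma = 2) {
  v <- as.vector(arr)
  rng <- range(v)
  if (diff(rng) <= 0) stop("constant image has no histogram valley")
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, br, rightmost.closed = TRUE),
                          1L), bins), nbins = bins)
  k <- seq(-ceiling(3 * sigma), ceiling(3 * sigma))
  kern <- exp(-k^2 / (2 * sigma^2)); kern <- kern / sum(kern)
  hp <- c(rep(h[1], length(k) %/% 2), h, rep(h[bins], length(k) %/% 2))
  hs <- stats::filter(hp, kern, sides = 2)
  hs <- as.numeric(hs[seq_len(bins) + length(k) %/% 2])
  # local maxima of the smoothed histogram
  peaks <- which(diff(sign(diff(c(-Inf, hs, -Inf)))) == -2)
  if (length(peaks) < 2)
    stop("could not find two separable intensity modes")
  ord <- order(hs[peaks], decreasing = TRUE)
  p2 <- sort(peaks[ord[1:2]])
  seg <- hs[p2[1]:p2[2]]
  valley <- p2[1] + which.min(seg) - 1L  # which.min takes the first tie
  (br[valley] + br[valley + 1L]) / 2
}

#' Histogram-based brain extraction
#'
#' Segments the brain from a head image by (1) thresholding at the
#' histogram valley between the background and tissue modes (or at a
#' given fraction of the robust maximum, the 99th percentile), (2)
#' one-voxel morphological opening then closing, (3) keeping the
#' largest 6-connected component, and (4) filling internal holes
#' (which recovers dark ventricle-like structures). The approach
#' presumes the bright-skull / dark-gap / bright-brain contrast regime
#' of typical rodent head scans, so the brain forms its own connected
#' component.
#'
#' @param image `volume_image` with at least two separable intensity
#'   modes above background.
#' @param threshold `"auto"` (histogram valley) or a number in (0, 1):
#'   fraction of the 99th percentile.
#' @return a nonempty `mask_image`.
#' @export
extract_brain <- function(image, threshold = "auto") {
  arr <- image$data
  if (identical(threshold, "auto")) {
    thr <- histogram_valley_threshold(arr)
  } else {
    threshold <- as.numeric(threshold)
    robust_max <- stats::quantile(arr[arr > 0], 0.99, names = FALSE, type = 7)
    thr <- threshold * robust_max
  }
  m <- arr > thr
  # on strongly anisotropic grids the one-voxel opening would erode
  # away thin through-plane caps; restrict it to the fine axes
  vs <- voxel_sizes(image)
  axes <- which(vs <= 2 * min(vs))
  if (length(axes) < 1) axes <- 1:3
  m <- close6(open6(m, axes), axes)
  m <- largest_component6(m)
  if (!any(m))
    stop("brain extraction produced an empty mask at threshold ",
         signif(thr, 4))
  m <- fill_holes6(m)
  mask_image(array(as.integer(m), dim = dim(arr)), image$affine)
}

#' Mid-sagittal symmetry plane of a brain mask
#'
#' Estimates the near-x-normal plane that best mirrors the mask onto
#' itself. The plane is parameterised by an offset `x0` (mm) and two
#' small tilts (degrees, about the y and z world axes). A coarse grid
#' search (offsets over the central third of the field of view, tilts
#' within +-10 degrees in 2-degree steps) is refined by a local
#' Nelder-Mead search. The symmetry score is the sample Pearson
#' correlation between the mask and its reflection, computed over the
#' union of the two supports (whole-grid correlation would be inflated
#' by agreeing background).
#'
#' @param mask a nonempty `mask_image`.
#' @return list with `plane` (`x0` mm, `tilt_y`, `tilt_z` degrees) and
#'   `symmetry_r` in `[-1, 1]`.
#' @export
estimate_midsagittal_symmetry <- function(mask) {
  if (!any(mask$data == 1L)) stop("cannot estimate symmetry of an empty mask")
  sh <- grid_shape(mask)
  vs <- voxel_sizes(mask)
  ctr <- grid_center_world(mask)
  arr <- mask$data
  on_idx <- which(arr == 1L)
  pts <- voxel_to_world(mask$affine, arrayInd(on_idx, sh) - 1L)

  pts_full <- voxel_to_world(mask$affine, index_grid0(sh))
  score <- function(p) {
    refl <- reflect_mask_values(mask, p, ctr, pts_full)
    symmetry_corr(as.vector(arr == 1L), refl)
  }
  # coarse grid search on a x2-downsampled mask (cheap, same optimum
  # basin), refined on the full mask
  low <- downsample_volume(volume_image(arr + 0, mask$affine), 2L)
  low_mask <- mask_image(array(as.integer(low$data >= 0.5),
                               dim = dim(low$data)), low$affine)
  pts_low <- voxel_to_world(low_mask$affine, index_grid0(grid_shape(low_mask)))
  score_low <- function(p) {
    refl <- reflect_mask_values(low_mask, p, ctr, pts_low)
    symmetry_corr(as.vector(low_mask$data == 1L), refl)
  }
  fov_x <- sh[1] * vs[1]
  x0s <- ctr[1] + seq(-fov_x / 6, fov_x / 6, by = vs[1])
  tilts <- seq(-10, 10, by = 2)
  best <- c(ctr[1], 0, 0); best_s <- -Inf
  # coarse: offsets only (tilt 0), then tilts at the best offset
  for (x0 in x0s) {
    s <- score_low(c(x0, 0, 0))
    if (s > best_s) { best_s <- s; best <- c(x0, 0, 0) }
  }
  for (ty in tilts) for (tz in tilts) {
    if (ty == 0 && tz == 0) next
    s <- score_low(c(best[1], ty, tz))
    if (s > best_s) { best_s <- s; best <- c(best[1], ty, tz) }
  }
  # refine on the downsampled mask first, then briefly at full scale
  opt_low <- stats::optim(best, function(p) -score_low(p),
                          method = "Nelder-Mead",
                          control = list(maxit = 100,
                                         parscale = c(vs[1], 2, 2)))
  if (-opt_low$value > best_s) best <- opt_low$par
  opt <- stats::optim(best, function(p) -score(p), method = "Nelder-Mead",
                      control = list(maxit = 40,
                                     parscale = c(vs[1] / 2, 1, 1)))
  best_full <- score(best)
  if (-opt$value > best_full) best <- opt$par
  list(plane = list(x0 = best[1], tilt_y = best[2], tilt_z = best[3]),
       symmetry_r = score(best))
}

# reflect the mask across the plane and sample it back on the grid
# with trilinear (partial-volume) weights: the soft values make the
# symmetry score smooth in the plane parameters, where a binary
# nearest-neighbour reflection would be a lattice delta function
reflect_mask_values <- function(mask, p, ctr, pts = NULL) {
  sh <- grid_shape(mask)
  if (is.null(pts)) pts <- voxel_to_world(mask$affine, index_grid0(sh))
  n <- c(cos(p[2] * pi / 180) * cos(p[3] * pi / 180),
         sin(p[3] * pi / 180),
         sin(p[2] * pi / 180))
  n <- n / sqrt(sum(n^2))
  point <- c(p[1], ctr[2], ctr[3])
  d <- (pts[, 1] - point[1]) * n[1] + (pts[, 2] - point[2]) * n[2] +
       (pts[, 3] - point[3]) * n[3]
  refl <- pts - 2 * d %o% n
  vox <- world_to_voxel(mask$affine, refl)
  interpolate_at(mask$data + 0, vox, "trilinear")
}

# Pearson correlation over the union of the two supports (whole-grid
# correlation would be inflated by agreeing background)
symmetry_corr <- function(a, b) {
  u <- a | (b > 1e-9)
  if (!any(u)) return(0)
  av <- a[u] + 0; bv <- b[u]
  if (isTRUE(all.equal(av, bv, tolerance = 1e-12))) return(1)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(0)
  stats::cor(av, bv)
}

#' Mask-quality report over a set of extraction thresholds
#'
#' Runs [extract_brain()] at each threshold and summarises each mask
#' with five measures: total volume (mm^3), anteroposterior length,
#' right-left width and inferior-superior height (world-space bounding
#' box extents along +y, +x, +z of a RAS-oriented grid, in mm), and
#' the mid-sagittal symmetry correlation of
#' [estimate_midsagittal_symmetry()]. These let a set of candidate
#' thresholds be screened numerically instead of by repeated visual
#' inspection. Thresholds whose extraction fails yield a row of `NA`s
#' rather than an error.
#'
#' @param image `volume_image` as for [extract_brain()].
#' @param thresholds numeric vector of threshold fractions (each
#'   passed to `extract_brain`).
#' @return a `data.frame` with columns `threshold`, `volume_mm3`,
#'   `ap_mm`, `rl_mm`, `is_mm`, `symmetry_r`, one row per threshold in
#'   input order.
#' @export
brain_segmentation_report <- function(image, thresholds) {
  if (length(thresholds) < 1) stop("at least one threshold is required")
  rows <- lapply(thresholds, function(th) {
    mask <- tryCatch(extract_brain(image, th), error = function(e) NULL)
    if (is.null(mask))
      return(data.frame(threshold = th, volume_mm3 = NA_real_,
                        ap_mm = NA_real_, rl_mm = NA_real_,
                        is_mm = NA_real_, symmetry_r = NA_real_))
    mm <- mask_measures(mask)
    sym <- estimate_midsagittal_symmetry(mask)$symmetry_r
    data.frame(threshold = th, volume_mm3 = mm$volume, ap_mm = mm$ap,
               rl_mm = mm$rl, is_mm = mm$is, symmetry_r = sym)
  })
  do.call(rbind, rows)
}

#' Geometric measures of a binary mask
#'
#' Volume (voxel count x voxel volume) and world-space bounding-box
#' extents along the RAS axes, each extent including the width of the
#' bounding voxels.
#'
#' @param mask a `mask_image`.
#' @return list with `volume` (mm^3) and `rl`, `ap`, `is` extents (mm).
#' @export
mask_measures <- function(mask) {
  vs <- voxel_sizes(mask)
  on_idx <- which(mask$data == 1L)
  if (length(on_idx) == 0)
    return(list(volume = 0, rl = 0, ap = 0, is = 0))
  pts <- voxel_to_world(mask$affine, arrayInd(on_idx, grid_shape(mask)) - 1L)
  ext <- apply(pts, 2, function(x) diff(range(x))) + vs
  list(volume = length(on_idx) * prod(vs),
       rl = ext[1], ap = ext[2], is = ext[3])
}
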