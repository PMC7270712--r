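# Free-form deformation machinery: a lattice of control-point
# displacements, interpolated to a dense field with cubic B-splines
# (C^1-smooth piecewise polynomials). Control displacements are capped
# at 0.4 x spacing, a classical sufficient condition for the resulting
# mapping to stay diffeomorphic.

cubic_bspline <- function(s) {
  a <- abs(s)
  w <- numeric(length(s))
  i1 <- a < 1
  w[i1] <- (4 - 6 * a[i1]^2 + 3 * a[i1]^3) / 6
  i2 <- !i1 & a < 2
  w[i2] <- (2 - a[i2])^3 / 6
  w
}

# basis matrix (n x nc) for points at world coords x (1D), control
# spacing h, controls at wmin + (c - 2) * h for c = 1..nc
bspline_basis_1d <- function(x, wmin, h, nc) {
  t <- (x - wmin) / h
  B <- matrix(0, length(x), nc)
  for (c in seq_len(nc))
    B[, c] <- cubic_bspline(t - (c - 2))
  B
}

tensor3_mult <- function(A, M, d) {
  dm <- dim(A)
  if (d == 1L) {
    out <- M %*% matrix(A, dm[1])
    dim(out) <- c(nrow(M), dm[2], dm[3])
    out
  } else if (d == 2L) {
    Ap <- aperm(A, c(2, 1, 3))
    out <- M %*% matrix(Ap, dm[2])
    dim(out) <- c(nrow(M), dm[1], dm[3])
    aperm(out, c(2, 1, 3))
  } else {
    Ap <- aperm(A, c(3, 1, 2))
    out <- M %*% matrix(Ap, dm[3])
    dim(out) <- c(nrow(M), dm[1], dm[2])
    aperm(out, c(2, 3, 1))
  }
}

# trilinear interpolation returning the value and its exact partial
# derivatives with respect to the (fractional, 0-based) voxel
# coordinates; out-of-field points yield zeros
interp_trilinear_grad <- function(arr, vox) {
  dm <- dim(arr)
  eps <- 1e-9
  x <- vox[, 1]; y <- vox[, 2]; z <- vox[, 3]
  ok <- x >= -eps & x <= dm[1] - 1 + eps &
        y >= -eps & y <= dm[2] - 1 + eps &
        z >= -eps & z <= dm[3] - 1 + eps
  n <- nrow(vox)
  val <- numeric(n); gx <- numeric(n); gy <- numeric(n); gz <- numeric(n)
  if (!any(ok)) return(list(value = val, gx = gx, gy = gy, gz = gz))
  x <- pmin(pmax(x[ok], 0), dm[1] - 1); y <- pmin(pmax(y[ok], 0), dm[2] - 1)
  z <- pmin(pmax(z[ok], 0), dm[3] - 1)
  i0 <- pmin(floor(x), max(dm[1] - 2, 0)); fx <- x - i0
  j0 <- pmin(floor(y), max(dm[2] - 2, 0)); fy <- y - j0
  k0 <- pmin(floor(z), max(dm[3] - 2, 0)); fz <- z - k0
  i1 <- pmin(i0 + 1, dm[1] - 1); j1 <- pmin(j0 + 1, dm[2] - 1)
  k1 <- pmin(k0 + 1, dm[3] - 1)
  at <- function(i, j, k) arr[1 + i + dm[1] * (j + dm[2] * k)]
  c000 <- at(i0, j0, k0); c100 <- at(i1, j0, k0)
  c010 <- at(i0, j1, k0); c110 <- at(i1, j1, k0)
  c001 <- at(i0, j0, k1); c101 <- at(i1, j0, k1)
  c011 <- at(i0, j1, k1); c111 <- at(i1, j1, k1)
  # interpolate along x first
  a00 <- c000 + fx * (c100 - c000); a10 <- c010 + fx * (c110 - c010)
  a01 <- c001 + fx * (c101 - c001); a11 <- c011 + fx * (c111 - c011)
  b0 <- a00 + fy * (a10 - a00); b1 <- a01 + fy * (a11 - a01)
  val[ok] <- b0 + fz * (b1 - b0)
  # exact partials of the trilinear form
  d00 <- c100 - c000; d10 <- c110 - c010; d01 <- c101 - c001; d11 <- c111 - c011
  e0 <- d00 + fy * (d10 - d00); e1 <- d01 + fy * (d11 - d01)
  gx[ok] <- e0 + fz * (e1 - e0)
  gy[ok] <- (a10 - a00) + fz * ((a11 - a01) - (a10 - a00))
  gz[ok] <- b1 - b0
  list(value = val, gx = gx, gy = gy, gz = gz)
}

# central-difference spatial gradient in world mm units
volume_gradient <- function(arr, vs) {
  dm <- dim(arr)
  g <- list()
  for (d in 1:3) {
    gd <- array(0, dim = dm)
    n <- dm[d]
    if (n >= 3) {
      idx_p <- c(2:n, n); idx_m <- c(1, 1:(n - 1))
      gd <- (slice_axis(arr, d, idx_p) - slice_axis(arr, d, idx_m)) /
        (2 * vs[d])
      # one-sided at the borders uses spacing h not 2h
      gd <- fix_border_gradient(gd, arr, d, vs[d])
    }
    g[[d]] <- gd
  }
  g
}

slice_axis <- function(arr, d, idx) {
  switch(d, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

fix_border_gradient <- function(gd, arr, d, h) {
  n <- dim(arr)[d]
  first <- (slice_axis(arr, d, 2L) - slice_axis(arr, d, 1L)) / h
  last <- (slice_axis(arr, d, n) - slice_axis(arr, d, n - 1L)) / h
  if (d == 1) { gd[1, , ] <- first; gd[n, , ] <- last }
  else if (d == 2) { gd[, 1, ] <- first; gd[, n, ] <- last }
  else { gd[, , 1] <- first; gd[, , n] <- last }
  gd
}

normalise_intensity <- function(arr) {
  pos <- arr[arr > 0]
  if (length(pos) == 0) return(arr)
  s <- stats::quantile(pos, 0.99, names = FALSE, type = 7)
  if (s <= 0) return(arr)
  arr / s
}

#' Multi-level nonlinear (free-form deformation) registration
#'
#' Estimates a dense displacement field warping `source` onto
#' `target`. The field is parameterised by a cubic-B-spline lattice of
#' control-point displacements, optimised coarse-to-fine: the control
#' spacing starts at a quarter of the field of view and halves at each
#' of `max_level` levels. Within a level the control displacements are
#' fitted by a diagonally preconditioned Gauss-Newton iteration (exact
#' interpolant gradients, backtracking line search) on the sum of
#' squared intensity differences of 99th-percentile-normalised
#' images, and are capped at 0.4 x spacing so the mapping stays
#' diffeomorphic; levels are composed, not summed. The discrete
#' Jacobian determinant of the final field is verified to be positive
#' at every interior voxel.
#'
#' `source` is expected to be already affinely aligned to `target`
#' (both on comparable grids); the field is expressed on the target
#' grid and maps target world coordinates to source world coordinates.
#'
#' @param source,target `volume_image`s.
#' @param max_level number of refinement levels (>= 1).
#' @param iterations Gauss-Newton iterations per level.
#' @param mask optional `mask_image` on the target grid restricting
#'   the data term.
#' @return a `displacement_field` on the target grid, with
#'   `level_history` recording the control spacings used.
#' @export
register_nonlinear <- function(source, target, max_level = 2L,
                               iterations = 60L, mask = NULL) {
  if (max_level < 1L) stop("max_level must be >= 1")
  grid <- as_grid(target)
  sh <- grid$shape
  vs <- voxel_sizes(target)
  fov <- sh * vs
  tgt <- normalise_intensity(target$data)
  src_img <- volume_image(normalise_intensity(source$data), source$affine)
  w <- if (is.null(mask)) NULL else as.double(mask$data == 1L)

  pts <- voxel_to_world(grid$affine, index_grid0(sh))
  wmin <- apply(pts, 2, min)
  D <- array(0, dim = c(sh, 3L))
  history <- numeric(0)

  for (lev in seq_len(max_level)) {
    h <- fov / 4 / 2^(lev - 1)
    history <- c(history, mean(h))
    eff <- resample(src_img, grid, displacement_field(D, grid$affine))
    D_new <- ffd_fit(eff$data, tgt, grid, pts, wmin, h, iterations, w)
    # compose: x -> x + D_new(x) -> + D(x + D_new(x))
    D_samp <- sample_field(D, grid$affine, pts + matrix(D_new, ncol = 3))
    D <- array(matrix(D_new, ncol = 3) + D_samp, dim = c(sh, 3L))
  }
  field <- displacement_field(D, grid$affine, level_history = history)
  jd <- jacobian_determinants(field)
  if (any(jd <= 0))
    stop("nonlinear registration produced a non-diffeomorphic field (",
         sum(jd <= 0), " interior voxels with Jacobian <= 0)")
  field
}

# fit one FFD level on the (already warped) effective source.
# Returns a dense (prod(sh) x 3 flattened) displacement array.
ffd_fit <- function(eff, tgt, grid, pts, wmin, h, iterations, w) {
  sh <- grid$shape
  vs <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  nc <- ceiling(sh * vs / h) + 3L
  # grids are axis-aligned after RAS reorientation; build separable bases
  Bx <- bspline_basis_1d(seq(wmin[1], by = vs[1], length.out = sh[1]),
                         wmin[1], h[1], nc[1])
  By <- bspline_basis_1d(seq(wmin[2], by = vs[2], length.out = sh[2]),
                         wmin[2], h[2], nc[2])
  Bz <- bspline_basis_1d(seq(wmin[3], by = vs[3], length.out = sh[3]),
                         wmin[3], h[3], nc[3])
  C <- array(0, dim = c(nc, 3L))
  cap <- 0.4 * h

  dense <- function(C) {
    out <- matrix(0, prod(sh), 3)
    for (d in 1:3)
      out[, d] <- tensor3_mult(tensor3_mult(tensor3_mult(
        array(C[, , , d], dim = nc), Bx, 1), By, 2), Bz, 3)
    out
  }
  eval_at <- function(f) {
    vox <- world_to_voxel(grid$affine, pts + f)
    ig <- interp_trilinear_grad(eff, vox)
    r <- ig$value - as.vector(tgt)
    if (!is.null(w)) r <- r * w
    # exact world-space gradient of the sampled interpolant (the grid
    # is axis-aligned, so the chain rule is a per-axis 1/voxel-size)
    list(cost = sum(r * r), r = r,
         G = list(ig$gx / vs[1], ig$gy / vs[2], ig$gz / vs[3]))
  }

  Bx2 <- Bx^2; By2 <- By^2; Bz2 <- Bz^2
  step <- 1
  st <- eval_at(dense(C))
  for (it in seq_len(iterations)) {
    # diagonally preconditioned Gauss-Newton step: gradient of the
    # data term over an estimate of its per-control-point curvature
    gC <- array(0, dim = c(nc, 3L))
    for (d in 1:3) {
      Gd <- st$G[[d]]
      resid <- 2 * st$r * Gd
      curv <- 2 * Gd * Gd
      if (!is.null(w)) { resid <- resid * w; curv <- curv * w }
      g <- tensor3_mult(tensor3_mult(tensor3_mult(
        array(resid, dim = sh), t(Bx), 1), t(By), 2), t(Bz), 3)
      hdiag <- tensor3_mult(tensor3_mult(tensor3_mult(
        array(curv, dim = sh), t(Bx2), 1), t(By2), 2), t(Bz2), 3)
      gC[, , , d] <- g / (hdiag + 0.02 * max(hdiag) + 1e-12)
    }
    if (max(abs(gC)) == 0) break
    improved <- FALSE
    for (try in 1:6) {
      C_try <- C - step * gC
      C_try <- pmin(pmax(C_try, -rep(cap, each = prod(nc))),
                    rep(cap, each = prod(nc)))
      dim(C_try) <- c(nc, 3L)
      st_try <- eval_at(dense(C_try))
      if (st_try$cost < st$cost) {
        C <- C_try; st <- st_try
        step <- min(step * 1.4, 1)
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved && step < 1e-4) break
    if (improved && st$cost < 1e-12) break
  }
  dense(C)
}

#' Per-slice in-plane nonlinear registration (EPI distortion model)
#'
#' The EPI reference and the anatomical image (already resampled onto
#' the EPI grid) are split into 2D slices along z, and each EPI slice
#' is registered to the matching anatomical slice with a 2D version of
#' the free-form deformation of [register_nonlinear()]. In-plane EPI
#' distortion varies slice by slice, and a per-slice correction is
#' more conservative than a full 3D warp. Slices with less than 1%
#' nonzero voxels in either image keep an identity warp.
#'
#' The returned stack maps anatomical-space (corrected) coordinates to
#' distorted-EPI coordinates: `resample(epi, grid, stack)` is the
#' corrected EPI.
#'
#' @param epi_reference `volume_image`, the representative EPI volume.
#' @param anat_in_epi_space `volume_image` on the same grid.
#' @param max_level refinement levels per slice.
#' @param iterations Gauss-Newton iterations per level.
#' @return a `slice_warp_stack` on the EPI grid.
#' @export
register_slicewise <- function(epi_reference, anat_in_epi_space,
                               max_level = 2L, iterations = 30L) {
  sh <- grid_shape(epi_reference)
  if (!all(sh == grid_shape(anat_in_epi_space)))
    stop("register_slicewise requires both images on the same grid ",
         "(z slice geometry must match)")
  vs <- voxel_sizes(epi_reference)
  disp <- array(0, dim = c(sh, 2L))
  epi <- normalise_intensity(epi_reference$data)
  anat <- normalise_intensity(anat_in_epi_space$data)
  for (k in seq_len(sh[3])) {
    e <- epi[, , k]; a <- anat[, , k]
    if (mean(e != 0) <= 0.01 || mean(a != 0) <= 0.01) next
    disp[, , k, ] <- ffd_fit_2d(e, a, vs[1:2], max_level, iterations)
  }
  stack <- slice_warp_stack(disp, epi_reference$affine)
  jd <- jacobian_determinants(stack)
  if (any(jd <= 0))
    stop("slicewise registration produced a non-diffeomorphic warp")
  stack
}

# 2D FFD, registering slice `src` onto slice `tgt`, returning the
# in-plane displacement (nx x ny x 2) in mm such that the mapping
# x -> x + d(x) pulls tgt-space coordinates into src.
ffd_fit_2d <- function(src, tgt, vs, max_level, iterations) {
  sh <- dim(src)
  fov <- sh * vs
  D <- array(0, dim = c(sh, 2L))
  px <- (seq_len(sh[1]) - 1) * vs[1]
  py <- (seq_len(sh[2]) - 1) * vs[2]
  P1 <- rep(px, sh[2]); P2 <- rep(py, each = sh[1])
  tv <- as.vector(tgt)

  for (lev in seq_len(max_level)) {
    h <- fov / 4 / 2^(lev - 1)
    # effective source under the accumulated warp
    eff <- matrix(interp_bilinear_grad(src, (P1 + D[, , 1]) / vs[1],
                                       (P2 + D[, , 2]) / vs[2])$value,
                  sh[1], sh[2])
    nc <- ceiling(fov / h) + 3L
    Bx <- bspline_basis_1d(px, 0, h[1], nc[1])
    By <- bspline_basis_1d(py, 0, h[2], nc[2])
    Bx2 <- Bx^2; By2 <- By^2
    C <- array(0, dim = c(nc, 2L))
    cap <- 0.4 * h
    dense <- function(C) list(Bx %*% C[, , 1] %*% t(By),
                              Bx %*% C[, , 2] %*% t(By))
    eval_at <- function(f) {
      ig <- interp_bilinear_grad(eff, (P1 + as.vector(f[[1]])) / vs[1],
                                 (P2 + as.vector(f[[2]])) / vs[2])
      r <- ig$value - tv
      list(cost = sum(r * r), r = r,
           G = list(ig$gx / vs[1], ig$gy / vs[2]))
    }
    step <- 1
    st <- eval_at(dense(C))
    for (it in seq_len(iterations)) {
      gC <- array(0, dim = c(nc, 2L))
      for (d in 1:2) {
        Gd <- st$G[[d]]
        g <- t(Bx) %*% matrix(2 * st$r * Gd, sh[1]) %*% By
        hdiag <- t(Bx2) %*% matrix(2 * Gd * Gd, sh[1]) %*% By2
        gC[, , d] <- g / (hdiag + 0.02 * max(hdiag) + 1e-12)
      }
      if (max(abs(gC)) == 0) break
      improved <- FALSE
      for (try in 1:6) {
        C_try <- C
        C_try[, , 1] <- pmin(pmax(C[, , 1] - step * gC[, , 1], -cap[1]), cap[1])
        C_try[, , 2] <- pmin(pmax(C[, , 2] - step * gC[, , 2], -cap[2]), cap[2])
        st_try <- eval_at(dense(C_try))
        if (st_try$cost < st$cost) {
          C <- C_try; st <- st_try
          step <- min(step * 1.4, 1)
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved && step < 1e-4) break
      if (improved && st$cost < 1e-12) break
    }
    f <- dense(C)
    # compose onto the accumulated warp; clamp so the field's edge
    # values extend beyond the grid instead of dropping to zero
    wx <- pmin(pmax((P1 + as.vector(f[[1]])) / vs[1], 0), sh[1] - 1)
    wy <- pmin(pmax((P2 + as.vector(f[[2]])) / vs[2], 0), sh[2] - 1)
    Dx <- matrix(interp_bilinear_grad(D[, , 1], wx, wy)$value, sh[1], sh[2])
    Dy <- matrix(interp_bilinear_grad(D[, , 2], wx, wy)$value, sh[1], sh[2])
    D[, , 1] <- f[[1]] + Dx
    D[, , 2] <- f[[2]] + Dy
  }
  D
}

# bilinear interpolation of a matrix at fractional 0-based (x, y)
# with exact partials; zero outside the field
interp_bilinear_grad <- function(arr, x, y) {
  sh <- dim(arr)
  eps <- 1e-9
  ok <- x >= -eps & x <= sh[1] - 1 + eps & y >= -eps & y <= sh[2] - 1 + eps
  n <- length(x)
  val <- numeric(n); gx <- numeric(n); gy <- numeric(n)
  if (!any(ok)) return(list(value = val, gx = gx, gy = gy))
  xi <- pmin(pmax(x[ok], 0), sh[1] - 1); yi <- pmin(pmax(y[ok], 0), sh[2] - 1)
  i0 <- pmin(floor(xi), max(sh[1] - 2, 0)); fx <- xi - i0
  j0 <- pmin(floor(yi), max(sh[2] - 2, 0)); fy <- yi - j0
  i1 <- pmin(i0 + 1, sh[1] - 1); j1 <- pmin(j0 + 1, sh[2] - 1)
  at <- function(i, j) arr[1 + i + sh[1] * j]
  c00 <- at(i0, j0); c10 <- at(i1, j0); c01 <- at(i0, j1); c11 <- at(i1, j1)
  a0 <- c00 + fx * (c10 - c00); a1 <- c01 + fx * (c11 - c01)
  val[ok] <- a0 + fy * (a1 - a0)
  gx[ok] <- (c10 - c00) + fy * ((c11 - c01) - (c10 - c00))
  gy[ok] <- a1 - a0
  list(value = val, gx = gx, gy = gy)
}
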