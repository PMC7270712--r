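#' Slice-timing correction
#'
#' Shifts each voxel's time course to the acquisition time of the
#' reference slice (the slice acquired in the middle of the volume's
#' acquisition) by linear temporal interpolation; the first and last
#' frames are clamped. Linear interpolation is exact for signals that
#' are linear in time.
#'
#' @param bold a `series_image` with >= 2 frames.
#' @param slice_order integer permutation of `1:nz` giving the
#'   acquisition order (slice_order\[p\] = index of the slice acquired
#'   at position p).
#' @param repetition_time TR in seconds (> 0).
#' @return the corrected `series_image`.
#' @export
slice_timing_correct <- function(bold, slice_order, repetition_time) {
  stopifnot(inherits(bold, "series_image"))
  nz <- dim(bold$frames)[3]
  if (repetition_time <= 0) stop("repetition_time must be positive")
  if (length(slice_order) != nz || !setequal(slice_order, seq_len(nz)))
    stop("slice_order must be a permutation of 1:", nz)
  nt <- dim(bold$frames)[4]
  # acquisition time (fraction of TR) of each slice
  t_acq <- numeric(nz)
  t_acq[slice_order] <- (seq_len(nz) - 1) / nz
  ref <- t_acq[slice_order[ceiling((nz + 1) / 2)]]
  out <- bold$frames
  for (z in seq_len(nz)) {
    shift <- t_acq[z] - ref    # frames: sample at t + shift is desired? no:
    # signal was sampled at frame times t + t_acq[z]; we want its value
    # at t + ref, i.e. evaluate the sampled series at t - (t_acq - ref)
    if (shift == 0) next
    src <- seq_len(nt) - shift
    src <- pmin(pmax(src, 1), nt)
    lo <- floor(src); hi <- pmin(lo + 1, nt); f <- src - lo
    sl <- bold$frames[, , z, , drop = FALSE]
    dm <- dim(sl)
    m <- matrix(sl, prod(dm[1:3]), nt)
    out[, , z, ] <- m[, lo] * rep(1 - f, each = nrow(m)) +
      m[, hi] * rep(f, each = nrow(m))
  }
  series_image(out, bold$affine, bold$frame_metadata)
}

#' Rigid realignment of a 4D series to its first frame
#'
#' Each frame is rigid-registered to frame 1 over a 2-level pyramid
#' and resampled; frame 1 is the reference and its parameters are
#' exactly zero. The metric is evaluated on lightly smoothed (1-2-1
#' per axis) copies of the frames: interpolation of a moved frame
#' attenuates the highest spatial frequencies, and matching it
#' unsmoothed against the sharp reference biases the optimum toward
#' whole-voxel shifts (grid locking). NMI is the default metric; SSD
#' is available and faster but more sensitive to that residual blur
#' mismatch.
#'
#' @param bold a `series_image` with >= 2 frames.
#' @param metric `"nmi"` (default) or `"ssd"`.
#' @return list with `series` (realigned `series_image`) and
#'   `motion_table`, a `data.frame` of per-frame parameters
#'   (rotations deg, translations mm).
#' @export
realign <- function(bold, metric = c("nmi", "ssd")) {
  metric <- match.arg(metric)
  stopifnot(inherits(bold, "series_image"))
  nt <- dim(bold$frames)[4]
  if (nt < 2) stop("realignment needs at least 2 frames")
  ref <- series_frame(bold, 1)
  grid <- as_grid(ref)
  ctr <- grid_center_world(ref)
  out <- bold$frames
  params <- matrix(0, nt, 6)
  for (t in 2:nt) {
    frame <- series_frame(bold, t)
    tf <- tryCatch(
      register_rigid(frame, ref, metric = metric, pyramid = c(2L, 1L),
                     sweeps = c(6L, 4L)),
      error = function(e) stop("realignment failed at frame ", t, ": ",
                               conditionMessage(e)))
    # express about the grid centre for reporting
    params[t, ] <- params_from_affine(tf, ctr, 6L)
    out[, , , t] <- resample(frame, grid, tf, "trilinear")$data
  }
  motion <- as.data.frame(params)
  names(motion) <- c("rot_x_deg", "rot_y_deg", "rot_z_deg",
                     "trans_x_mm", "trans_y_mm", "trans_z_mm")
  list(series = series_image(out, bold$affine, bold$frame_metadata),
       motion_table = motion)
}

#' Temporal mean of a 4D series
#'
#' @param bold a `series_image` with >= 1 frame.
#' @return a `volume_image`, the voxelwise arithmetic mean over time.
#' @export
temporal_mean <- function(bold) {
  stopifnot(inherits(bold, "series_image"))
  nt <- dim(bold$frames)[4]
  acc <- bold$frames[, , , 1, drop = TRUE]
  if (nt > 1) for (t in 2:nt) acc <- acc + bold$frames[, , , t, drop = TRUE]
  volume_image(acc / nt, bold$affine)
}

# separable 1-2-1 smoothing, one pass per axis
smooth121 <- function(a) {
  for (d in 1:3) {
    n <- dim(a)[d]
    if (n < 2) next
    idx_p <- c(2:n, n); idx_m <- c(1, 1:(n - 1))
    a <- (slice_axis(a, d, idx_m) + 2 * a + slice_axis(a, d, idx_p)) / 4
  }
  a
}
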