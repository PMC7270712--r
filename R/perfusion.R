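# FAIR ASL quantification: per-voxel magnitude inversion-recovery
# fitting of the selective and nonselective series, M0 extraction and
# CBF mapping.

#' Tag a 4D series as a FAIR acquisition
#'
#' @param series a `series_image` whose `frame_metadata` are inversion
#'   times in seconds (strictly increasing, >= 3 frames).
#' @param labeling_tag `"selective"` or `"nonselective"`.
#' @return a `fair_series`.
#' @export
fair_series <- function(series, labeling_tag = c("selective", "nonselective")) {
  labeling_tag <- match.arg(labeling_tag)
  stopifnot(inherits(series, "series_image"))
  tis <- unlist(series$frame_metadata)
  if (length(tis) < 3 || any(diff(tis) <= 0) || any(tis <= 0))
    stop("a FAIR series needs >= 3 strictly increasing positive ",
         "inversion times")
  series$labeling_tag <- labeling_tag
  if (!inherits(series, "fair_series"))
    class(series) <- c("fair_series", class(series))
  series
}

#' Per-voxel inversion-recovery fitting of a FAIR series
#'
#' Fits the magnitude inversion-recovery model
#' `|M0 (1 - 2 alpha exp(-TI / T1))|` to every voxel's TI series by
#' nonlinear least squares. Fitting the magnitude directly is robust
#' to the polarity flip near the null point of MR magnitude data.
#' Initialisation is a grid search over T1 candidates (0.2-3.0 s, 13
#' points, crossed with a few alpha candidates) with the closed-form
#' least-squares M0 for each candidate; refinement is a damped
#' Gauss-Newton iteration with box constraints (`T1 > 0`,
#' `alpha` in `[0.5, 1]`, `M0 >= 0`). The fit runs in two passes:
#' after a per-voxel first pass, the inversion efficiency — a property
#' of the inversion pulse rather than of the voxel — is fixed at the
#' median fitted alpha and T1/M0 are refitted per voxel. (A per-voxel
#' alpha bounded at 1 can only err downward under noise, and its
#' coupling with T1 would bias T1 and hence CBF upward.) Voxels with
#' relative fit residual above `residual_threshold` (or with no
#' signal) are excluded from the fit mask.
#'
#' @param series a `fair_series` (or `series_image` with TIs as frame
#'   metadata) of >= 3 inversion times.
#' @param fit_mask optional `mask_image`; defaults to automatic
#'   extraction on the last-TI frame.
#' @param residual_threshold relative RMS residual above which a voxel
#'   is excluded (QC default 0.2).
#' @param iterations Gauss-Newton iterations.
#' @param alpha `NULL` (default: estimate the global efficiency from
#'   the data as described above) or a fixed numeric value in
#'   `[0.5, 1]` — e.g. the common efficiency of a FAIR pair, since the
#'   selective and nonselective acquisitions share one inversion
#'   pulse.
#' @return a `fair_fit_result` list of `t1_map` (s), `m0_map` (signal
#'   units), `alpha_map`, `residual_map` (RMS, same units as the
#'   signal) and `fit_mask`; map voxels outside the fit mask carry
#'   `NA`.
#' @export
fit_inversion_recovery <- function(series, fit_mask = NULL,
                                   residual_threshold = 0.2,
                                   iterations = 25L, alpha = NULL) {
  tis <- as.numeric(unlist(series$frame_metadata))
  if (length(tis) < 3) stop("inversion-recovery fitting needs >= 3 TIs")
  if (any(diff(tis) <= 0) || any(tis <= 0))
    stop("inversion times must be strictly increasing and positive")
  sh <- dim(series$frames)[1:3]
  nt <- length(tis)
  if (is.null(fit_mask)) {
    last <- volume_image(series$frames[, , , nt, drop = TRUE], series$affine)
    fit_mask <- tryCatch(extract_brain(last), error = function(e) {
      arr <- last$data
      thr <- 0.1 * stats::quantile(arr[arr > 0], 0.99, names = FALSE, type = 7)
      if (!is.finite(thr) || !any(arr > thr))
        stop("could not derive a fit mask from the last-TI frame")
      mask_image(array(as.integer(arr > thr), dim = sh), series$affine)
    })
  }
  vox <- which(fit_mask$data == 1L)
  if (length(vox) == 0) stop("fit mask is empty")
  Y <- matrix(0, length(vox), nt)
  for (f in seq_len(nt)) Y[, f] <- series$frames[, , , f][vox]

  mean_abs <- rowMeans(abs(Y))
  live <- mean_abs > 0
  if (!any(live)) stop("all voxels in the fit mask have zero signal")

  # two-pass fit: the inversion efficiency is a property of the pulse,
  # not of the voxel. A per-voxel alpha bounded at 1 can only err
  # downward under noise, and its coupling with T1 inflates T1 (and
  # biases CBF); fixing alpha at the cohort median of a first pass
  # removes that bias while keeping a data-driven efficiency.
  if (is.null(alpha)) {
    first <- ir_fit_voxels(Y[live, , drop = FALSE], tis, iterations)
    alpha <- stats::median(first$alpha)
  } else if (alpha < 0.5 || alpha > 1) {
    stop("alpha must lie in [0.5, 1]")
  }
  fit <- ir_fit_voxels(Y[live, , drop = FALSE], tis, iterations,
                       fixed_alpha = alpha)
  rel_resid <- fit$rms / pmax(mean_abs[live], .Machine$double.eps)
  ok <- rel_resid <= residual_threshold & fit$t1 > 0
  if (!any(ok)) stop("inversion-recovery fitting failed for every voxel")

  full <- function(values) {
    arr <- array(NA_real_, dim = sh)
    idx <- vox[live][ok]
    arr[idx] <- values[ok]
    arr
  }
  final_mask <- array(0L, dim = sh)
  final_mask[vox[live][ok]] <- 1L
  structure(list(
    t1_map = volume_image_na(full(fit$t1), series$affine),
    m0_map = volume_image_na(full(fit$m0), series$affine),
    alpha_map = volume_image_na(full(fit$alpha), series$affine),
    residual_map = volume_image_na(full(fit$rms), series$affine),
    fit_mask = mask_image(final_mask, series$affine),
    inversion_times = tis),
    class = "fair_fit_result")
}

# internal constructor permitting NA as the designated missing value
volume_image_na <- function(data, affine) {
  if (any(is.infinite(data))) stop("image data contains infinite values")
  storage.mode(data) <- "double"
  structure(list(data = data, affine = check_affine(affine)),
            class = c("volume_image", "rodentmri_image"))
}

# vectorised magnitude-IR fit over a matrix of voxels (rows) x TIs;
# when fixed_alpha is given, alpha is held there and only M0 and T1
# are estimated
ir_fit_voxels <- function(Y, tis, iterations, fixed_alpha = NULL) {
  nv <- nrow(Y); nt <- length(tis)
  t1_cand <- seq(0.2, 3.0, length.out = 13)
  a_cand <- if (is.null(fixed_alpha)) c(0.75, 0.9, 1.0) else fixed_alpha
  sy2 <- rowSums(Y * Y)
  best <- list(sse = rep(Inf, nv), t1 = rep(1, nv), a = rep(1, nv),
               m0 = rep(0, nv))
  for (t1 in t1_cand) for (a in a_cand) {
    s <- 1 - 2 * a * exp(-tis / t1)
    sa <- abs(s)
    denom <- sum(s * s)
    m0 <- pmax(drop(Y %*% sa) / denom, 0)
    sse <- sy2 - 2 * m0 * drop(Y %*% sa) + m0^2 * denom
    better <- sse < best$sse
    best$sse[better] <- sse[better]
    best$t1[better] <- t1
    best$a[better] <- a
    best$m0[better] <- m0[better]
  }
  m0 <- best$m0; t1 <- best$t1; alpha <- best$a
  sse <- best$sse
  for (it in seq_len(iterations)) {
    E <- exp(outer(-1 / t1, tis))          # nv x nt
    S <- 1 - 2 * alpha * E
    sgn <- sign(S); sgn[sgn == 0] <- 1
    M <- m0 * abs(S)
    R <- M - Y
    # partials of |M0 S| (columns j over TIs)
    J1 <- abs(S)                            # d/dM0
    J2 <- (m0 * sgn) * (-2 * alpha) * E * rep(tis, each = nv) / t1^2  # d/dT1
    J3 <- if (is.null(fixed_alpha)) (m0 * sgn) * (-2) * E else 0 * E
    a11 <- rowSums(J1 * J1); a12 <- rowSums(J1 * J2); a13 <- rowSums(J1 * J3)
    a22 <- rowSums(J2 * J2); a23 <- rowSums(J2 * J3); a33 <- rowSums(J3 * J3)
    b1 <- -rowSums(J1 * R); b2 <- -rowSums(J2 * R); b3 <- -rowSums(J3 * R)
    lam <- 1e-8 * (a11 + a22 + a33) + 1e-300
    a11 <- a11 + lam; a22 <- a22 + lam; a33 <- a33 + lam
    det <- a11 * (a22 * a33 - a23 * a23) - a12 * (a12 * a33 - a23 * a13) +
      a13 * (a12 * a23 - a22 * a13)
    det[det == 0] <- 1e-300
    d1 <- (b1 * (a22 * a33 - a23 * a23) - a12 * (b2 * a33 - a23 * b3) +
             a13 * (b2 * a23 - a22 * b3)) / det
    d2 <- (a11 * (b2 * a33 - b3 * a23) - b1 * (a12 * a33 - a23 * a13) +
             a13 * (a12 * b3 - b2 * a13)) / det
    d3 <- (a11 * (a22 * b3 - a23 * b2) - a12 * (a12 * b3 - b2 * a13) +
             b1 * (a12 * a23 - a22 * a13)) / det
    step <- rep(1, nv)
    for (half in 1:6) {
      m0_n <- pmax(m0 + step * d1, 0)
      t1_n <- pmin(pmax(t1 + step * d2, 0.05), 10)
      a_n <- if (is.null(fixed_alpha))
        pmin(pmax(alpha + step * d3, 0.5), 1) else alpha
      S_n <- 1 - 2 * a_n * exp(outer(-1 / t1_n, tis))
      sse_n <- rowSums((m0_n * abs(S_n) - Y)^2)
      acc <- sse_n <= sse
      m0[acc] <- m0_n[acc]; t1[acc] <- t1_n[acc]; alpha[acc] <- a_n[acc]
      sse[acc] <- sse_n[acc]
      step[!acc] <- step[!acc] / 2
      if (all(acc)) break
    }
  }
  list(t1 = t1, m0 = m0, alpha = alpha, rms = sqrt(sse / nt))
}

#' Equilibrium-magnetisation (M0) map of a FAIR fit
#'
#' The fitted M0 volume, used as the representative perfusion volume
#' for registration. Voxels excluded from the fit carry `NA`.
#'
#' @param fit_nonselective a `fair_fit_result`.
#' @return a `volume_image`.
#' @export
m0_map <- function(fit_nonselective) {
  stopifnot(inherits(fit_nonselective, "fair_fit_result"))
  fit_nonselective$m0_map
}

#' Cerebral blood flow from paired FAIR fits
#'
#' The FAIR difference-of-rates model:
#' `CBF = 6000 * lambda * (1 / T1_sel - 1 / T1_ns)` in ml/100g/min,
#' with `lambda` the blood-brain partition coefficient (ml/g).
#' Computed over the intersection of the two fit masks; `NA`
#' elsewhere. Negative values (noise-driven) are retained but counted
#' in the QC field `n_negative`.
#'
#' @param fit_selective,fit_nonselective `fair_fit_result`s on the
#'   same grid.
#' @param lambda_ml_per_g partition coefficient, default 0.9 ml/g.
#' @param rate_constant unit constant (s to min x 100 g scaling),
#'   default 6000.
#' @return a `cbf_map`: a `volume_image` with fields `lambda_used`,
#'   `n_negative` and `fit_mask`.
#' @export
compute_cbf <- function(fit_selective, fit_nonselective,
                        lambda_ml_per_g = 0.9, rate_constant = 6000) {
  stopifnot(inherits(fit_selective, "fair_fit_result"),
            inherits(fit_nonselective, "fair_fit_result"))
  if (lambda_ml_per_g <= 0) stop("lambda must be positive")
  if (!all(grid_shape(fit_selective$t1_map) ==
             grid_shape(fit_nonselective$t1_map)) ||
      max(abs(fit_selective$t1_map$affine -
                fit_nonselective$t1_map$affine)) > 1e-6)
    stop("the two fits must share one grid")
  both <- fit_selective$fit_mask$data == 1L &
    fit_nonselective$fit_mask$data == 1L
  cbf <- array(NA_real_, dim = dim(both))
  cbf[both] <- rate_constant * lambda_ml_per_g *
    (1 / fit_selective$t1_map$data[both] -
       1 / fit_nonselective$t1_map$data[both])
  out <- volume_image_na(cbf, fit_selective$t1_map$affine)
  out$lambda_used <- lambda_ml_per_g
  out$n_negative <- sum(cbf[both] < 0)
  out$fit_mask <- mask_image(array(as.integer(both), dim = dim(both)),
                             fit_selective$t1_map$affine)
  class(out) <- c("cbf_map", class(out))
  out
}

#' Regional summary of a parameter map over an atlas
#'
#' For every label id (background 0 excluded) present in the label
#' image: voxel count, median, quartiles, Tukey lower/upper adjacent
#' values (the most extreme observations within 1.5 IQR of the
#' quartiles), mean and SD of the map values, `NA` voxels excluded.
#'
#' @param map a `volume_image` (e.g. a CBF map; `NA` = missing).
#' @param labels a `label_image` on the same grid.
#' @return a `data.frame`, one row per label.
#' @export
regional_summary <- function(map, labels) {
  stopifnot(inherits(labels, "label_image"))
  if (!all(grid_shape(map) == grid_shape(labels)))
    stop("map and labels must share one grid")
  ids <- sort(setdiff(unique(as.vector(labels$data)), 0L))
  if (length(ids) == 0) stop("label image contains no foreground labels")
  if (!any(!is.na(map$data[labels$data > 0L])))
    stop("no overlap between the labels and the map's valid voxels")
  rows <- lapply(ids, function(id) {
    v <- map$data[labels$data == id]
    v <- v[!is.na(v)]
    if (length(v) == 0)
      stop("label ", id, " has no valid voxels in the map")
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    name <- if (!is.null(labels$label_names))
      labels$label_names[[as.character(id)]] else NA_character_
    data.frame(label = id, name = if (is.null(name)) NA_character_ else name,
               n_voxels = length(v), median = q[2], q1 = q[1], q3 = q[3],
               lower_adjacent = lo, upper_adjacent = hi,
               mean = mean(v), sd = stats::sd(v))
  })
  do.call(rbind, rows)
}
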