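# Small two-region T1/M0 maps used across the perfusion tests
fair_maps <- function(sh = c(10L, 10L, 6L)) {
  aff <- diag(c(0.4, 0.4, 1, 1))
  brain <- array(0L, dim = sh)
  brain[3:8, 3:8, 2:5] <- 1L
  region2 <- array(FALSE, dim = sh)
  region2[3:8, 6:8, 2:5] <- TRUE
  t1_sel <- array(0, dim = sh); t1_ns <- array(0, dim = sh)
  t1_ns[brain == 1L] <- 1.5
  t1_sel[brain == 1L] <- 1.35
  t1_sel[region2 & brain == 1L] <- 1.42   # second, lower-flow region
  m0 <- array(0, dim = sh); m0[brain == 1L] <- 1000
  list(t1_sel = volume_image(t1_sel, aff),
       t1_ns = volume_image(t1_ns, aff),
       m0 = volume_image(m0, aff),
       brain = mask_image(brain, aff),
       region2 = region2,
       aff = aff, sh = sh)
}

tis_default <- c(0.05, 0.1, 0.3, 0.6, 1.0, 1.7, 2.6, 5.0)

test_that("noiseless simulator/fitter round trip recovers T1 and M0 to 1e-3", {
  mp <- fair_maps()
  fs <- simulate_fair_series(mp$t1_sel, mp$t1_ns, mp$m0, tis_default,
                             inversion_efficiency = 1, noise_sigma = 0)
  fit <- fit_inversion_recovery(fs$nonselective, fit_mask = mp$brain)
  on <- fit$fit_mask$data == 1L
  expect_true(any(on))
  expect_lt(max(abs(fit$t1_map$data[on] - 1.5) / 1.5), 1e-3)
  expect_lt(max(abs(fit$m0_map$data[on] - 1000) / 1000), 1e-3)
  expect_true(all(fit$alpha_map$data[on] >= 0.5 & fit$alpha_map$data[on] <= 1))
  # selective series carries two T1 regions; both recovered
  fit_s <- fit_inversion_recovery(fs$selective, fit_mask = mp$brain)
  on_s <- fit_s$fit_mask$data == 1L
  truth <- mp$t1_sel$data
  expect_lt(max(abs(fit_s$t1_map$data[on_s] - truth[on_s]) / truth[on_s]),
            1e-3)
})

test_that("fitting matches an independent per-voxel nls oracle", {
  skip_if_not_installed("minpack.lm")
  mp <- fair_maps()
  fs <- simulate_fair_series(mp$t1_sel, mp$t1_ns, mp$m0, tis_default,
                             inversion_efficiency = 0.92, noise_sigma = 5,
                             seed = 21)
  fit <- fit_inversion_recovery(fs$nonselective, fit_mask = mp$brain)
  vox <- which(fit$fit_mask$data == 1L)[c(3, 17, 40)]
  for (v in vox) {
    y <- vapply(seq_along(tis_default),
                function(f) fs$nonselective$frames[, , , f][v], 0)
    od <- data.frame(ti = tis_default, y = y)
    ora <- minpack.lm::nlsLM(
      y ~ abs(m0 * (1 - 2 * a * exp(-ti / t1))), data = od,
      start = list(m0 = max(y), t1 = 1, a = 0.9),
      lower = c(0, 0.05, 0.5), upper = c(Inf, 10, 1),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(ora)
    expect_lt(abs(fit$t1_map$data[v] - co[["t1"]]) / co[["t1"]], 0.02)
    expect_lt(abs(fit$m0_map$data[v] - co[["m0"]]) / co[["m0"]], 0.02)
  }
})

test_that("voxels without signal are excluded and degenerate input errors", {
  mp <- fair_maps()
  fs <- simulate_fair_series(mp$t1_sel, mp$t1_ns, mp$m0, tis_default)
  # widen the mask into the background: zero-signal voxels get dropped
  wide <- array(1L, dim = mp$sh)
  fit <- fit_inversion_recovery(fs$nonselective,
                                fit_mask = mask_image(wide, mp$aff))
  bg <- mp$brain$data == 0L
  expect_true(all(fit$fit_mask$data[bg] == 0L))
  expect_true(all(is.na(fit$t1_map$data[bg])))
  short <- fs$nonselective
  short$frames <- short$frames[, , , 1:2, drop = FALSE]
  short$frame_metadata <- short$frame_metadata[1:2]
  expect_error(fit_inversion_recovery(short), ">= 3")
})

test_that("CBF follows the difference-of-rates formula and its symmetries", {
  mp <- fair_maps()
  fs <- simulate_fair_series(mp$t1_sel, mp$t1_ns, mp$m0, tis_default)
  fit_sel <- fit_inversion_recovery(fs$selective, fit_mask = mp$brain)
  fit_ns <- fit_inversion_recovery(fs$nonselective, fit_mask = mp$brain)
  cbf <- compute_cbf(fit_sel, fit_ns, lambda_ml_per_g = 0.9)
  on <- cbf$fit_mask$data == 1L & !mp$region2
  # hand-evaluated: 6000 * 0.9 * (1/1.35 - 1/1.5) = 400.0
  expect_lt(max(abs(cbf$data[on] - 400)), 1)
  # antisymmetry under swapping the fits
  rev <- compute_cbf(fit_ns, fit_sel, lambda_ml_per_g = 0.9)
  both <- cbf$fit_mask$data == 1L
  expect_identical(cbf$data[both], -rev$data[both])
  # linear in lambda
  dbl <- compute_cbf(fit_sel, fit_ns, lambda_ml_per_g = 1.8)
  expect_identical(dbl$data[both], 2 * cbf$data[both])
  # equal T1s -> identically zero
  zero <- compute_cbf(fit_ns, fit_ns)
  expect_true(all(zero$data[zero$fit_mask$data == 1L] == 0))
})

test_that("M0 map and regional summaries expose the fit faithfully", {
  mp <- fair_maps()
  fs <- simulate_fair_series(mp$t1_sel, mp$t1_ns, mp$m0, tis_default)
  fit <- fit_inversion_recovery(fs$nonselective, fit_mask = mp$brain)
  m0 <- m0_map(fit)
  expect_equal(m0$affine, fs$nonselective$affine)
  expect_true(all(is.na(m0$data[fit$fit_mask$data == 0L])))

  labs <- label_image(array(mp$brain$data * 1L, dim = mp$sh), mp$aff)
  labs$data[mp$region2] <- 2L
  const <- volume_image(array(150, dim = mp$sh), mp$aff)
  tab <- regional_summary(const, labs)
  expect_equal(tab$median, c(150, 150))
  expect_equal(tab$mean, c(150, 150))
  expect_equal(tab$q3 - tab$q1, c(0, 0))
  # a label with no valid voxels errors
  namap <- volume_image(array(1, dim = mp$sh), mp$aff)
  namap$data[labs$data == 2L] <- NA_real_
  class(namap) <- class(const)
  expect_error(regional_summary(namap, labs), "label 2")
})

test_that("noisy fits stay within the declared accuracy envelope", {
  # ~1000 voxels at 2% of M0 noise: median T1 error under 3%
  sh <- c(12L, 12L, 8L)
  aff <- diag(4)
  brain <- array(1L, dim = sh)
  t1 <- volume_image(array(1.5, dim = sh), aff)
  m0 <- volume_image(array(1000, dim = sh), aff)
  fs <- simulate_fair_series(t1, t1, m0, tis_default,
                             inversion_efficiency = 1,
                             noise_sigma = 20, seed = 77)
  fit <- fit_inversion_recovery(fs$nonselective,
                                fit_mask = mask_image(brain, aff))
  on <- fit$fit_mask$data == 1L
  expect_gt(sum(on), 900)
  relerr <- abs(fit$t1_map$data[on] - 1.5) / 1.5
  expect_lt(stats::median(relerr), 0.03)
})
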