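test_that("NMI satisfies its defining identities", {
  ph <- small_phantom()
  x <- ph$image
  expect_equal(nmi(x, x), 2, tolerance = 1e-6)
  set.seed(3)
  y <- volume_image(array(runif(prod(grid_shape(x))), dim = grid_shape(x)),
                    x$affine)
  expect_identical(nmi(x, y), nmi(y, x))
  # independent uniform noise: NMI near its floor of 1
  z <- volume_image(array(runif(prod(grid_shape(x))), dim = grid_shape(x)),
                    x$affine)
  expect_lte(nmi(y, z), 1.05)
  # self-similarity maximality over a few candidates
  for (cand in list(y, z, ph$image)) expect_lte(nmi(x, cand), nmi(x, x))
  expect_error(nmi(x, volume_image(array(1, dim = c(2, 2, 2)), diag(4))),
               "same grid")
  expect_error(nmi(x, x, bins = 4), "bins")
  # disjoint supports error
  a <- array(0, dim = c(4, 4, 4)); a[1, 1, 1] <- 1
  b <- array(0, dim = c(4, 4, 4)); b[4, 4, 4] <- 1
  expect_error(nmi(a, b), "overlap")
})

test_that("rigid registration is exact on identical images and recovers known motion", {
  ph <- small_phantom()
  img <- ph$image
  vs <- voxel_sizes(img)
  # source == target -> identity within 0.1 deg / 0.05 voxel
  idt <- register_rigid(img, img)
  err0 <- transform_error(idt, rigid_transform(rep(0, 6)))
  expect_lt(err0$rot_deg, 0.1)
  expect_lt(err0$trans_mm, 0.05 * min(vs))

  # known rigid perturbation is recovered
  tr <- rigid_transform(c(0, 0, 7, 1.0, -0.6, 0.5), c(0, 0, 0))
  warped <- apply_known_transform(img, tr, ph$truth)
  est <- register_rigid(img, warped$image)
  err <- transform_error(est, tr)
  expect_lt(err$rot_deg, 0.5)
  expect_lt(err$trans_mm, 0.25 * min(vs))

  # forward and backward registrations are mutually inverse
  back <- register_rigid(warped$image, img)
  comp <- affine_transform(est$matrix %*% back$matrix, "affine12")
  errc <- transform_error(comp, affine_transform(diag(4)))
  expect_lt(errc$rot_deg, 0.5)
  expect_lt(errc$trans_mm, 0.25 * min(vs))
})

test_that("affine registration recovers scales and nests the rigid solution", {
  ph <- small_phantom()
  img <- ph$image
  pa <- c(0, 0, 5, 0.4, -0.2, 0.3, 0, log(1.08), 0, rep(0, 3))
  ta <- affine12_transform(pa, c(0, 0, 0))
  warped <- apply_known_transform(img, ta, ph$truth)
  est <- register_affine(img, warped$image)
  err <- transform_error(est, ta)
  expect_lt(err$scale_dev, 0.02)
  expect_lt(err$rot_deg, 0.5)

  # the affine similarity cannot fall below the rigid one (nested search)
  rig <- register_rigid(img, warped$image)
  grid <- sampling_grid(grid_shape(img), warped$image$affine)
  al_r <- resample(img, grid, rig)
  al_a <- resample(img, grid, est)
  expect_gte(nmi(al_a, warped$image) + 1e-6, nmi(al_r, warped$image))
})

test_that("nonlinear registration recovers a smooth warp with positive Jacobians", {
  ph <- small_phantom()
  img <- ph$image
  sh <- grid_shape(img); vs <- voxel_sizes(img)
  grid <- sampling_grid(sh, img$affine)
  pts <- rodentmri:::voxel_to_world(img$affine, rodentmri:::index_grid0(sh))
  dx <- 1.5 * vs[1] * sin(2 * pi * pts[, 2] / 10) * sin(2 * pi * pts[, 3] / 12)
  dy <- 0.8 * vs[2] * sin(2 * pi * pts[, 1] / 9)
  truth <- displacement_field(array(c(dx, dy, rep(0, nrow(pts))),
                                    dim = c(sh, 3)), img$affine)
  warped <- resample(img, grid, truth, "trilinear")

  # target == source: negligible field
  null_field <- register_nonlinear(img, img, max_level = 1L,
                                   iterations = 10L)
  expect_lt(sqrt(mean(null_field$disp^2)) / min(vs), 0.05)

  est <- register_nonlinear(warped, img, max_level = 2L)
  inv <- invert(truth)
  err <- sqrt(rowSums((matrix(est$disp, ncol = 3) -
                         matrix(inv$disp, ncol = 3))^2))
  brain <- ph$truth$brain_mask$data == 1L
  # the half-resolution fixture warrants a proportionally wider bound
  # than the full-size phantom (which is held to 0.5 voxel)
  expect_lt(sqrt(mean(err[brain]^2)) / mean(vs[1:2]), 0.6)

  expect_true(all(jacobian_determinants(est) > 0))
})

test_that("per-slice correction fixes in-plane distortion and guards empty slices", {
  ph <- small_phantom()
  img <- ph$image
  sh <- grid_shape(img); vs <- voxel_sizes(img)
  grid <- sampling_grid(sh, img$affine)
  # undistorted pair: negligible warps
  none <- register_slicewise(img, img, iterations = 10L)
  expect_lt(sqrt(mean(none$disp^2)) / min(vs[1:2]), 0.05)

  pts <- rodentmri:::voxel_to_world(img$affine, rodentmri:::index_grid0(sh))
  half <- sh[1] * vs[1] / 2
  zfac <- 0.5 + 0.5 * (pts[, 3] - min(pts[, 3])) /
    (max(pts[, 3]) - min(pts[, 3]))
  dx <- 2 * vs[1] * zfac * (pts[, 1] / half)^2 * sign(pts[, 1])
  dy <- 0.8 * vs[2] * zfac * (pts[, 2] / half)^2 * sign(pts[, 2])
  wtrue <- slice_warp_stack(array(c(dx, dy), dim = c(sh, 2)), img$affine)
  distorted <- resample(img, grid, wtrue, "trilinear")

  est <- register_slicewise(distorted, img)
  winv <- invert(wtrue)
  errx <- (est$disp[, , , 1] - winv$disp[, , , 1]) / vs[1]
  erry <- (est$disp[, , , 2] - winv$disp[, , , 2]) / vs[2]
  err <- sqrt(errx^2 + erry^2)
  brain <- ph$truth$brain_mask$data == 1L
  expect_lt(mean(err[brain]), 0.5)
  expect_true(all(jacobian_determinants(est) > 0))

  # an empty top slice keeps an identity warp
  img2 <- img
  img2$data[, , sh[3]] <- 0
  est2 <- register_slicewise(img2, img2, iterations = 5L)
  expect_true(all(est2$disp[, , sh[3], ] == 0))

  short <- volume_image(img$data[, , 1:(sh[3] - 1), drop = FALSE], img$affine)
  expect_error(register_slicewise(short, img), "grid")
})

test_that("registration is deterministic", {
  ph <- small_phantom()
  img <- ph$image
  tr <- rigid_transform(c(0, 0, 5, 0.6, 0, -0.4), c(0, 0, 0))
  warped <- apply_known_transform(img, tr, ph$truth)
  a <- register_rigid(img, warped$image)
  b <- register_rigid(img, warped$image)
  expect_identical(a$matrix, b$matrix)
})

test_that("known rigid/affine draws are recovered across seeds", {
  ph <- small_phantom()
  img <- ph$image
  vs <- voxel_sizes(img)
  for (seed in 1:4) {
    set.seed(100 + seed)
    p <- c(runif(3, -10, 10), runif(3, -2, 2))
    tr <- rigid_transform(p, c(0, 0, 0))
    warped <- apply_known_transform(img, tr, ph$truth)
    est <- register_rigid(img, warped$image)
    err <- transform_error(est, tr)
    # the half-resolution fixture is held to a proportionally wider
    # bound than the full-size phantom (0.5 deg / 0.25 voxel there)
    expect_lt(err$rot_deg, 1.0)
    expect_lt(err$trans_mm, 0.3 * min(vs))
  }
})
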