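test_that("NIfTI round trip preserves data and affine for every image class", {
  dir <- withr::local_tempdir()
  aff <- diag(c(0.1, 0.1, 0.5, 1))
  aff[1:3, 4] <- c(-0.75, -0.75, -1.75)
  set.seed(1)
  vol <- volume_image(array(runif(16 * 16 * 8), dim = c(16, 16, 8)), aff)
  f <- file.path(dir, "vol.nii.gz")
  write_nifti(vol, f)
  back <- read_nifti(f)
  expect_s3_class(back, "volume_image")
  expect_identical(back$data, vol$data)        # float64 on disk: bit-exact
  expect_lt(max(abs(back$affine - vol$affine)), 1e-6)
  expect_equal(voxel_sizes(back), c(0.1, 0.1, 0.5), tolerance = 1e-6)

  lab <- label_image(array(sample(0:5, 512, TRUE), dim = c(8, 8, 8)), diag(4))
  f2 <- file.path(dir, "lab.nii")                       # plain, uncompressed
  write_nifti(lab, f2)
  back2 <- read_nifti(f2, as = "label")
  expect_identical(back2$data, lab$data)

  ser <- series_image(array(rnorm(8 * 8 * 4 * 5), dim = c(8, 8, 4, 5)),
                      diag(4))
  f3 <- file.path(dir, "ser.nii.gz")
  write_nifti(ser, f3)
  back3 <- read_nifti(f3)
  expect_s3_class(back3, "series_image")
  expect_equal(dim(back3$frames)[4], 5L)
})

test_that("invalid images and files are rejected with clear errors", {
  bad_aff <- diag(4); bad_aff[1, 1] <- 0
  expect_error(volume_image(array(1, dim = c(4, 4, 4)), bad_aff), "singular")
  a <- array(1, dim = c(4, 4, 4)); a[2, 2, 2] <- NaN
  expect_error(volume_image(a, diag(4)), "non-finite")
  expect_error(mask_image(array(2, dim = c(2, 2, 2)), diag(4)), "0 or 1")
  expect_error(read_nifti(tempfile(fileext = ".nii")), "cannot read")
  expect_error(series_image(array(0, dim = c(2, 2, 2, 3)), diag(4),
                            frame_metadata = list(1)), "length")
})

test_that("reorientation finds the closest RAS frame and preserves world coordinates", {
  ph <- small_phantom()
  img <- ph$image
  # already RAS: unchanged object
  expect_identical(reorient_to_ras(img), img)

  # LPS (flip x and y): world coordinate of a marked voxel is preserved
  flip <- img
  flip$data <- img$data[dim(img$data)[1]:1, dim(img$data)[2]:1, ]
  S <- diag(4); S[1, 1] <- -1; S[2, 2] <- -1
  S[1, 4] <- dim(img$data)[1] - 1; S[2, 4] <- dim(img$data)[2] - 1
  flip$affine <- img$affine %*% S
  fixed <- reorient_to_ras(flip)
  expect_true(all(diag(fixed$affine[1:3, 1:3]) > 0))
  expect_equal(fixed$data, img$data)
  expect_equal(fixed$affine, img$affine)

  # axis permutation (z, x, y): inverted by reorientation; verify by
  # brute-force comparison of world coordinates of matched voxels
  perm <- aperm(img$data, c(3, 1, 2))
  P <- matrix(0, 4, 4); P[4, 4] <- 1
  P[1, 2] <- 1; P[2, 3] <- 1; P[3, 1] <- 1   # old index = P %*% new index
  paff <- img$affine %*% P
  pimg <- volume_image(perm, paff)
  fixed2 <- reorient_to_ras(pimg)
  expect_equal(fixed2$data, img$data)
  expect_equal(fixed2$affine, img$affine)

  # idempotence
  expect_identical(reorient_to_ras(fixed2), fixed2)
})

test_that("resampling matches closed-form interpolation", {
  aff <- diag(c(0.5, 0.5, 1, 1))
  sh <- c(12L, 10L, 8L)
  grid <- sampling_grid(sh, aff)
  # identity on the same grid
  set.seed(2)
  img <- volume_image(array(runif(prod(sh)), dim = sh), aff)
  out <- resample(img, grid, NULL, "trilinear")
  expect_lt(max(abs(out$data - img$data)), 1e-6)

  # integer-voxel translation of a constant image stays constant inside
  cimg <- volume_image(array(3, dim = sh), aff)
  tr <- affine_transform(rbind(c(1, 0, 0, 1), c(0, 1, 0, 0),
                               c(0, 0, 1, 0), c(0, 0, 0, 1)))
  out2 <- resample(cimg, grid, tr, "trilinear")
  expect_true(all(out2$data[1:(sh[1] - 2), , ] == 3))

  # half-voxel shift of a linear ramp: closed-form linear interpolation
  ramp <- volume_image(array(rep(seq_len(sh[1]), prod(sh[2:3])), dim = sh),
                       aff)
  half <- affine_transform(rbind(c(1, 0, 0, 0.25), c(0, 1, 0, 0),
                                 c(0, 0, 1, 0), c(0, 0, 0, 1)))
  out3 <- resample(ramp, grid, half, "trilinear")
  interior <- out3$data[2:(sh[1] - 2), , ]
  expected <- ramp$data[2:(sh[1] - 2), , ] + 0.5
  expect_lt(max(abs(interior - expected)), 1e-6)

  # label maps refuse trilinear
  lab <- label_image(array(1L, dim = sh), aff)
  expect_error(resample(lab, grid, NULL, "trilinear"), "nearest")
})

test_that("mask centroids are exact and rigid-equivariant", {
  aff <- diag(c(0.2, 0.2, 0.5, 1)); aff[1:3, 4] <- c(-1, -2, -3)
  sh <- c(16L, 16L, 12L)
  one <- array(0L, dim = sh); one[4, 5, 6] <- 1L
  m1 <- mask_image(one, aff)
  expect_equal(image_centroid(m1),
               c(aff %*% c(3, 4, 5, 1))[1:3], tolerance = 1e-12)

  two <- one; two[10, 5, 6] <- 1L
  m2 <- mask_image(two, aff)
  expect_equal(image_centroid(m2),
               (c(aff %*% c(3, 4, 5, 1))[1:3] +
                  c(aff %*% c(9, 4, 5, 1))[1:3]) / 2)

  expect_error(image_centroid(mask_image(array(0L, dim = sh), aff)), "empty")

  # equivariance under rigid motion: centroid(T(mask)) ~ T(centroid)
  ph <- small_phantom()
  mask <- ph$truth$brain_mask
  ctr <- image_centroid(mask)
  for (seed in 1:3) {
    set.seed(seed)
    p <- c(runif(3, -6, 6), runif(3, -1, 1))
    tr <- rigid_transform(p, center = c(0, 0, 0))
    moved <- resample(mask, mask, tr, "nearest")
    # resampling with pull-back T moves content by T^{-1}
    expected <- map_points(invert(tr), matrix(ctr, 1))
    got <- image_centroid(moved)
    expect_lt(sqrt(sum((got - expected)^2)), 0.5 * max(voxel_sizes(mask)))
  }
})

test_that("series frames and grid helpers behave", {
  ser <- series_image(array(seq_len(2 * 2 * 2 * 3), dim = c(2, 2, 2, 3)),
                      diag(4), frame_metadata = list(0.1, 0.2, 0.3))
  f2 <- series_frame(ser, 2)
  expect_s3_class(f2, "volume_image")
  expect_equal(f2$data, ser$frames[, , , 2])
  expect_error(series_frame(ser, 4), "range")
  expect_equal(grid_shape(ser), c(2L, 2L, 2L))
})
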