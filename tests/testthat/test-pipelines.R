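test_that("BOLD coregistration on an undistorted pair is self-consistent", {
  ph <- small_phantom()
  anat <- ph$image
  # the modality is the anatomical phantom itself seen as a short series
  series <- simulate_bold_series(anat, matrix(0, 3, 6))$series
  res <- coregister(anat, series, modality = "bold",
                    rigid_mode = "reorient_only")
  vs <- voxel_sizes(series)
  expect_lt(sqrt(mean(res$slice_warps$disp^2)) / min(vs[1:2]), 0.1)
  anat_mask <- extract_brain(res$anat_in_modality_space)
  mod_mask <- extract_brain(res$modality_mean)
  expect_gte(dice(anat_mask, mod_mask), 0.95)
  expect_null(res$rigid)

  # with rigid estimation on a motionless pair the result matches
  res_r <- coregister(anat, series, modality = "bold", rigid_mode = "rigid")
  expect_s3_class(res_r$rigid, "affine_transform")
  err <- transform_error(res_r$rigid, affine_transform(diag(4)))
  expect_lt(err$trans_mm, 0.25 * min(vs))
  expect_lt(mean(abs(res_r$anat_in_modality_space$data -
                       res$anat_in_modality_space$data)), 0.02)
})

test_that("perfusion coregistration uses the fitted M0 as representative", {
  ph <- small_phantom()
  anat <- ph$image
  sh <- grid_shape(anat)
  brain <- ph$truth$brain_mask$data
  t1 <- volume_image(array(1.4 * brain, dim = sh), anat$affine)
  m0 <- volume_image(array(1000 * brain, dim = sh), anat$affine)
  fs <- simulate_fair_series(t1, t1, m0, c(0.05, 0.1, 0.3, 0.6, 1, 1.7, 2.6, 5))
  res <- coregister(anat, fs$nonselective, modality = "perfusion",
                    rigid_mode = "reorient_only")
  on <- brain == 1L
  expect_lt(stats::median(abs(res$modality_mean$data[on] - 1000)) / 1000,
            0.01)
})

test_that("one-big-step equals the explicit chain and round-trips labels", {
  ph <- small_phantom()
  anat <- ph$image
  grid <- sampling_grid(grid_shape(anat), anat$affine)
  series <- simulate_bold_series(anat, matrix(0, 2, 6))$series
  coreg <- coregister(anat, series, modality = "bold",
                      rigid_mode = "rigid")
  # a mock anatomical-to-template chain
  anat_chain <- transform_chain(
    rigid_transform(c(0, 0, 3, 0.4, -0.2, 0), c(0, 0, 0)))
  mod_img <- temporal_mean(series)

  one <- transform_modality_to_template(mod_img, coreg, anat_chain, grid)
  explicit <- apply_chain(mod_img, modality_chain(coreg, anat_chain), grid)
  expect_identical(one$data, explicit$data)

  # labels carried template -> modality with nearest interpolation
  # never gain labels
  labs <- ph$truth$tissue_labels
  back <- inverse_transform_towards_modality(labs, coreg, anat_chain,
                                             interpolation = "nearest")
  expect_true(all(unique(as.vector(back$data)) %in%
                    unique(as.vector(labs$data))))

  # smooth image round trip template -> modality -> template stays close
  smooth <- volume_image(array(exp(-(rodentmri:::voxel_to_world(
    anat$affine, rodentmri:::index_grid0(grid_shape(anat)))[, 1]^2) / 8),
    dim = grid_shape(anat)), anat$affine)
  fwd <- inverse_transform_towards_modality(smooth, coreg, anat_chain)
  backf <- transform_modality_to_template(fwd, coreg, anat_chain, grid)
  brain <- ph$truth$brain_mask$data == 1L
  rng <- diff(range(smooth$data))
  expect_lt(mean(abs(backf$data - smooth$data)[brain]) / rng, 0.02)
})

test_that("pipelines are deterministic and memoisation matches recomputation", {
  ph <- small_phantom()
  anat <- ph$image
  mp <- rbind(rep(0, 6), c(0, 0, 0.4, 0.3, -0.2, 0.2))
  series <- simulate_bold_series(anat, mp, noise_sigma = 0.01, seed = 4)$series

  a <- coregister(anat, series, modality = "bold", rigid_mode = "rigid")
  b <- coregister(anat, series, modality = "bold", rigid_mode = "rigid")
  expect_identical(a$anat_in_modality_space$data,
                   b$anat_in_modality_space$data)
  expect_identical(a$slice_warps$disp, b$slice_warps$disp)

  wd <- withr::local_tempdir()
  c1 <- coregister(anat, series, modality = "bold", rigid_mode = "rigid",
                   workdir = wd)
  expect_gt(length(list.files(wd)), 0)       # cache populated
  c2 <- coregister(anat, series, modality = "bold", rigid_mode = "rigid",
                   workdir = wd)             # cache hit
  expect_identical(c1$slice_warps$disp, a$slice_warps$disp)
  expect_identical(c2$slice_warps$disp, a$slice_warps$disp)
  expect_identical(c2$modality_mean$data, a$modality_mean$data)
})

test_that("template registration chains anat into template space", {
  ph <- full_phantom()
  img <- ph$image
  # anat == template: near-identity chain
  ch <- register_to_template(img, img, ph$truth$brain_mask,
                             ph$truth$brain_mask, max_level = 1L)
  vs <- voxel_sizes(img)
  aff_err <- transform_error(ch$elements[[2]], affine_transform(diag(4)))
  expect_lt(aff_err$trans_mm, 0.25 * min(vs))
  expect_lt(sqrt(mean(ch$elements[[1]]$disp^2)) / min(vs), 0.1)

  # known affine perturbation is recovered by the affine stage
  pa <- c(0, 0, 4, 0.5, 0, -0.4, 0, log(1.06), 0, rep(0, 3))
  ta <- affine12_transform(pa, c(0, 0, 0))
  moved <- apply_known_transform(img, ta, ph$truth)
  ch2 <- register_to_template(moved$image, img, moved$truth$brain_mask,
                              ph$truth$brain_mask, max_level = 1L)
  # the chain maps template world into the subject's world, so the
  # affine element estimates the *inverse* of the applied perturbation
  err <- transform_error(ch2$elements[[2]], invert(ta))
  # wider than the affine op's direct contract (0.02 / 0.5 deg): here
  # the moving image is itself a resampled (blurred) copy and the
  # metric is brain-masked, both of which add a small scale bias
  expect_lt(err$scale_dev, 0.05)
  expect_lt(err$rot_deg, 0.6)

  # applying the chain aligns the auto-masks with the template mask
  grid <- sampling_grid(grid_shape(img), img$affine)
  aligned <- apply_chain(moved$image, ch2, grid)
  expect_gte(dice(extract_brain(aligned), ph$truth$brain_mask), 0.92)
})
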