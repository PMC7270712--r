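#' Specification of a synthetic rodent-head phantom
#'
#' The phantom emulates the contrast regime of a T2-weighted rodent
#' head scan: a bright scalp/skull shell separated from the brain by a
#' dark gap, a brain ellipsoid with a bright cortex-like shell, a
#' mid-intensity interior and dark ventricle-like inclusions, on a
#' near-zero background. The default grid (64 x 64 x 32 voxels of
#' 0.2 x 0.2 x 0.5 mm) mimics the in-plane/through-plane anisotropy of
#' typical rodent acquisitions.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param voxel_sizes voxel edge lengths in mm.
#' @param brain_semiaxes brain ellipsoid semi-axes in mm (x, y, z).
#' @param skull_thickness thickness of the scalp/skull shell (mm).
#' @param skull_gap dark gap between brain surface and skull (mm).
#'   The default stays above twice the through-plane voxel size so the
#'   shell never touches the brain in a 6-connected sense, even after
#'   the interpolation blur of inter-subject averaging.
#' @param ventricle_fraction fraction (0-1) of brain volume occupied by
#'   the two ventricle-like inclusions.
#' @param asymmetry 0-1 left-right intensity skew (0 = exactly
#'   mirror-symmetric).
#' @param noise_sigma Gaussian noise SD as a fraction of the cortex
#'   intensity.
#' @param seed integer seed; identical spec (including seed) yields
#'   bit-identical phantoms.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 32L),
                         voxel_sizes = c(0.2, 0.2, 0.5),
                         brain_semiaxes = c(4.2, 4.8, 3.2),
                         skull_thickness = 0.5,
                         skull_gap = 1.0,
                         ventricle_fraction = 0.05,
                         asymmetry = 0,
                         noise_sigma = 0,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_sizes = as.numeric(voxel_sizes),
               brain_semiaxes = as.numeric(brain_semiaxes),
               skull_thickness = skull_thickness,
               skull_gap = skull_gap,
               ventricle_fraction = ventricle_fraction,
               asymmetry = asymmetry,
               noise_sigma = noise_sigma,
               seed = as.integer(seed))
  fov <- spec$grid_shape * spec$voxel_sizes
  outer <- spec$brain_semiaxes + spec$skull_gap + spec$skull_thickness
  if (any(2 * outer > fov))
    stop("phantom does not fit: outer semi-axes ",
         paste(signif(outer, 3), collapse = "x"),
         " mm exceed half the field of view ",
         paste(signif(fov / 2, 3), collapse = "x"), " mm")
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (spec$ventricle_fraction < 0 || spec$ventricle_fraction > 1)
    stop("ventricle_fraction must be in [0, 1]")
  structure(spec, class = "phantom_spec")
}

# tissue intensity levels (cortex == 1 is the reference)
.phantom_levels <- c(background = 0, gap = 0.02, ventricle = 0.15,
                     interior = 0.6, cortex = 1.0, skull = 1.3)

#' Generate a synthetic head phantom with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return a list with `image` (a `volume_image`) and `truth`, a
#'   ground-truth list carrying `brain_mask` (a `mask_image`) and
#'   `tissue_labels` (a `label_image`: 1 skull/scalp shell, 2
#'   cortex-like shell, 3 interior, 4 ventricle-like inclusions).
#' @export
make_head_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$grid_shape; vs <- spec$voxel_sizes
  affine <- diag(c(vs, 1))
  affine[1:3, 4] <- -vs * (sh - 1) / 2   # world origin at grid centre
  idx <- index_grid0(sh)
  xyz <- voxel_to_world(affine, idx)     # centred world coords

  a <- spec$brain_semiaxes
  rho2 <- (xyz[, 1] / a[1])^2 + (xyz[, 2] / a[2])^2 + (xyz[, 3] / a[3])^2
  brain <- rho2 <= 1

  # radially layered brain: cortex-like shell is the outer 15% of radius
  r_int <- 0.85
  interior <- rho2 <= r_int^2

  # two ventricle-like lobes offset left/right of the midline
  vent <- rep(FALSE, nrow(xyz))
  if (spec$ventricle_fraction > 0) {
    vscale <- (spec$ventricle_fraction / 2)^(1 / 3)
    for (s in c(-1, 1)) {
      cx <- s * 0.25 * a[1]
      v2 <- ((xyz[, 1] - cx) / (vscale * a[1]))^2 +
            (xyz[, 2] / (vscale * a[2]))^2 +
            (xyz[, 3] / (vscale * a[3]))^2
      vent <- vent | (v2 <= 1 & interior)
    }
  }

  ao <- a + spec$skull_gap
  skull_in <- (xyz[, 1] / ao[1])^2 + (xyz[, 2] / ao[2])^2 +
              (xyz[, 3] / ao[3])^2 <= 1
  as2 <- ao + spec$skull_thickness
  skull_out <- (xyz[, 1] / as2[1])^2 + (xyz[, 2] / as2[2])^2 +
               (xyz[, 3] / as2[3])^2 <= 1
  skull <- skull_out & !skull_in

  lv <- .phantom_levels
  img <- rep(lv[["background"]], nrow(xyz))
  img[skull_out & !skull & !brain] <- lv[["gap"]]
  img[skull] <- lv[["skull"]]
  img[brain] <- lv[["cortex"]]
  img[interior] <- lv[["interior"]]
  img[vent] <- lv[["ventricle"]]

  # smooth intra-tissue modulation (fixed, mirror-symmetric in x):
  # real brain tissue is not piecewise-constant, and a purely
  # concentric phantom would leave orientation nearly unidentifiable
  # to intensity-based registration
  tex <- 1 + 0.08 * cos(2 * pi * xyz[, 1] / 2.8) *
               cos(2 * pi * xyz[, 2] / 3.4) +
             0.06 * cos(2 * pi * xyz[, 1] / 1.9) *
               cos(2 * pi * xyz[, 3] / 2.6)
  tissue <- brain & !vent
  img[tissue] <- img[tissue] * tex[tissue]

  if (spec$asymmetry > 0) {
    half_fov <- sh[1] * vs[1] / 2
    img <- img * (1 + 0.3 * spec$asymmetry * xyz[, 1] / half_fov)
  }
  if (spec$noise_sigma > 0) {
    old <- local_seed(spec$seed)
    img <- img + stats::rnorm(length(img), 0,
                              spec$noise_sigma * lv[["cortex"]])
    restore_seed(old)
  }

  labels <- integer(nrow(xyz))
  labels[skull] <- 1L
  labels[brain & !interior] <- 2L
  labels[interior] <- 3L
  labels[vent] <- 4L

  list(image = volume_image(array(img, dim = sh), affine),
       truth = list(brain_mask = mask_image(array(as.integer(brain), dim = sh),
                                            affine),
                    tissue_labels = label_image(array(labels, dim = sh), affine,
                                                label_names = c(`1` = "skull",
                                                                `2` = "cortex",
                                                                `3` = "interior",
                                                                `4` = "ventricle")),
                    spec = spec))
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Smooth multiplicative bias field with known ground truth
#'
#' A low-order (quadratic) spatial polynomial with seeded coefficients,
#' shifted and scaled so that the field has mean exactly 1 over the
#' grid and range within `[1 - amplitude, 1 + amplitude]`.
#'
#' @param spec a [phantom_spec()] (provides grid and seed).
#' @param amplitude peak deviation from 1; must satisfy
#'   `0 <= amplitude < 1` so the field stays strictly positive.
#' @return a `volume_image` on the phantom grid.
#' @export
make_bias_field <- function(spec = phantom_spec(), amplitude = 0.3) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (amplitude < 0 || amplitude >= 1)
    stop("bias amplitude must be in [0, 1)")
  sh <- spec$grid_shape; vs <- spec$voxel_sizes
  affine <- diag(c(vs, 1)); affine[1:3, 4] <- -vs * (sh - 1) / 2
  if (amplitude == 0)
    return(volume_image(array(1, dim = sh), affine))
  xyz <- voxel_to_world(affine, index_grid0(sh))
  xyz <- sweep(xyz, 2, sh * vs / 2, "/")   # normalised to ~[-1, 1]
  terms <- cbind(xyz, xyz^2, xyz[, 1] * xyz[, 2], xyz[, 1] * xyz[, 3],
                 xyz[, 2] * xyz[, 3])
  old <- local_seed(spec$seed + 1000L)
  coef <- stats::rnorm(ncol(terms))
  restore_seed(old)
  g <- drop(terms %*% coef)
  g <- g - mean(g)
  g <- g * (amplitude / max(abs(g)))
  g <- g - mean(g)                          # mean exactly 1 after shift
  g <- g * (amplitude / max(abs(g)))        # rescale in case the re-centre grew it
  g <- g - mean(g)
  volume_image(array(1 + g, dim = sh), affine)
}

#' Warp a phantom and its ground truth by a known transform
#'
#' The image is resampled trilinearly and the ground-truth mask and
#' labels with nearest-neighbour interpolation, all through the same
#' pull-back transform, onto the input grid. The applied transform is
#' recorded in the returned ground truth; if more than 10% of the
#' brain leaves the field of view, `truth$out_of_view` is set.
#'
#' @param image a `volume_image`.
#' @param transform any rodentmri transform (finite parameters).
#' @param ground_truth ground-truth list from [make_head_phantom()].
#' @return list `(image, truth)` with `truth$applied_transform` set.
#' @export
apply_known_transform <- function(image, transform, ground_truth) {
  grid <- as_grid(image)
  warped <- resample(image, grid, transform, "trilinear")
  truth <- ground_truth
  if (!is.null(truth$brain_mask)) {
    before <- sum(truth$brain_mask$data)
    truth$brain_mask <- resample(truth$brain_mask, grid, transform, "nearest")
    after <- sum(truth$brain_mask$data)
    if (after < 0.9 * before) truth$out_of_view <- TRUE
  }
  if (!is.null(truth$tissue_labels))
    truth$tissue_labels <- resample(truth$tissue_labels, grid, transform,
                                    "nearest")
  truth$applied_transform <- transform
  list(image = warped, truth = truth)
}

#' Simulate paired FAIR inversion-recovery series
#'
#' Magnitude inversion-recovery signal
#' `|M0 (1 - 2 alpha exp(-TI / T1))|` per voxel and inversion time,
#' with optional additive Gaussian noise, for the slice-selective and
#' non-selective acquisitions of a FAIR experiment (each with its own
#' T1 map).
#'
#' @param t1_sel_map,t1_ns_map `volume_image` T1 maps (s) for the
#'   selective and non-selective series; must be positive wherever
#'   `m0_map` is positive.
#' @param m0_map `volume_image` equilibrium magnetisation (signal
#'   units); non-positive voxels are treated as background.
#' @param inversion_times strictly increasing positive TIs (s).
#' @param inversion_efficiency alpha in `[0.5, 1]`.
#' @param noise_sigma additive Gaussian noise SD (signal units).
#' @param seed integer seed for the noise.
#' @return list of two `fair_series` objects (`selective`,
#'   `nonselective`), each a `series_image` with TIs in
#'   `frame_metadata` and a `labeling_tag`.
#' @export
simulate_fair_series <- function(t1_sel_map, t1_ns_map, m0_map,
                                 inversion_times,
                                 inversion_efficiency = 1,
                                 noise_sigma = 0, seed = 1L) {
  tis <- as.numeric(inversion_times)
  if (length(tis) < 3 || any(diff(tis) <= 0) || any(tis <= 0))
    stop("inversion_times must be >= 3 strictly increasing positive values")
  brain <- m0_map$data > 0
  for (t1 in list(t1_sel_map, t1_ns_map))
    if (any(t1$data[brain] <= 0))
      stop("T1 must be positive wherever M0 is positive")
  sh <- grid_shape(m0_map)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  build <- function(t1_map, tag, sub) {
    frames <- array(0, dim = c(sh, length(tis)))
    t1 <- t1_map$data
    t1[!brain] <- 1  # placeholder outside brain; signal stays 0 via M0
    m0 <- m0_map$data * brain
    for (f in seq_along(tis)) {
      s <- abs(m0 * (1 - 2 * inversion_efficiency * exp(-tis[f] / t1)))
      if (noise_sigma > 0)
        s <- s + stats::rnorm(length(s), 0, noise_sigma)
      frames[, , , f] <- s
    }
    fs <- series_image(frames, m0_map$affine, as.list(tis))
    fs$labeling_tag <- tag
    class(fs) <- c("fair_series", class(fs))
    fs
  }
  list(selective = build(t1_sel_map, "selective"),
       nonselective = build(t1_ns_map, "nonselective"))
}

#' Simulate a motion-corrupted BOLD series
#'
#' Frame `t` is the base volume resampled under the rigid motion
#' `motion_params[t, ]` (3 rotations in degrees, 3 translations in mm,
#' about the grid centre) plus optional Gaussian noise. Frame 1 must
#' have all-zero motion (it is the realignment reference).
#'
#' @param base_volume a `volume_image`.
#' @param motion_params n_frames x 6 matrix; row 1 must be zero.
#' @param noise_sigma additive Gaussian noise SD.
#' @param seed integer noise seed.
#' @return list `(series, truth)`; `truth$motion_params` records the
#'   applied parameters.
#' @export
simulate_bold_series <- function(base_volume, motion_params,
                                 noise_sigma = 0, seed = 1L) {
  motion_params <- as.matrix(motion_params)
  if (ncol(motion_params) != 6L)
    stop("motion_params must have 6 columns")
  if (any(motion_params[1, ] != 0))
    stop("frame-1 motion parameters must be exactly zero")
  sh <- grid_shape(base_volume)
  ctr <- grid_center_world(base_volume)
  nt <- nrow(motion_params)
  frames <- array(0, dim = c(sh, nt))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (t in seq_len(nt)) {
    if (all(motion_params[t, ] == 0)) {
      vol <- base_volume
    } else {
      tr <- rigid_transform(motion_params[t, ], center = ctr)
      vol <- resample(base_volume, base_volume, tr, "trilinear")
    }
    fr <- vol$data
    if (noise_sigma > 0) fr <- fr + stats::rnorm(length(fr), 0, noise_sigma)
    frames[, , , t] <- fr
  }
  series <- series_image(frames, base_volume$affine,
                         as.list(seq_len(nt) - 1L))
  list(series = series, truth = list(motion_params = motion_params))
}
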