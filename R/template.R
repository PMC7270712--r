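#' Median-normalise an image's intensity
#'
#' Scales the image so that the median intensity within the mask is 1;
#' a scale-invariant normalisation used before averaging subjects into
#' a template.
#'
#' @param image a `volume_image`.
#' @param mask a nonempty `mask_image` on the same grid.
#' @return the scaled `volume_image`.
#' @export
intensity_normalize <- function(image, mask) {
  m <- mask$data == 1L
  if (!any(m)) stop("intensity_normalize: mask is empty")
  med <- stats::median(image$data[m])
  if (med == 0) stop("intensity_normalize: median intensity within the mask is zero")
  volume_image(image$data / med, image$affine)
}

#' Centroid-aligned initial template
#'
#' Each (median-normalised) head image is translated so that its brain
#' mask centroid sits at the centre of the reference grid, then the
#' images are averaged voxelwise — the rough starting template of the
#' iterative group-wise scheme.
#'
#' @param images list of >= 2 bias-corrected `volume_image`s.
#' @param masks list of matching nonempty `mask_image`s.
#' @param reference_grid grid of the output (default: first subject).
#' @return a `volume_image` on `reference_grid`.
#' @export
initialize_template <- function(images, masks, reference_grid = NULL) {
  if (length(images) < 2) stop("at least 2 subjects are required")
  if (length(masks) != length(images))
    stop("one mask per image is required")
  grid <- as_grid(if (is.null(reference_grid)) images[[1]] else reference_grid)
  ctr <- grid_center_world(grid)
  acc <- array(0, dim = grid$shape)
  for (s in seq_along(images)) {
    img <- intensity_normalize(images[[s]], masks[[s]])
    shift <- image_centroid(masks[[s]]) - ctr
    tf <- affine_transform(translation_matrix(shift), "rigid6")
    acc <- acc + resample(img, grid, tf, "trilinear")$data
  }
  volume_image(acc / length(images), grid$affine)
}

translation_matrix <- function(t) {
  M <- diag(4); M[1:3, 4] <- t; M
}

#' Schedule for iterative template construction
#'
#' Stages run in order, each registering every subject to the current
#' template with the stated transform kind and re-averaging. Degrees
#' of freedom must be non-decreasing along the schedule (centroid <
#' rigid6 < affine12 < nonlinear).
#'
#' @param stages list of stages, each a list with `kind` in
#'   `c("centroid", "rigid6", "affine12", "nonlinear")`, `iterations`
#'   (>= 1) and, for nonlinear stages, `max_level`.
#' @param convergence_tol mean voxelwise relative template change
#'   below which a stage stops early.
#' @return a `template_schedule`.
#' @export
template_schedule <- function(stages = list(
                                list(kind = "centroid", iterations = 1L),
                                list(kind = "rigid6", iterations = 2L),
                                list(kind = "affine12", iterations = 2L),
                                list(kind = "nonlinear", iterations = 1L,
                                     max_level = 1L),
                                list(kind = "nonlinear", iterations = 1L,
                                     max_level = 2L)),
                              convergence_tol = 1e-4) {
  dof_rank <- c(centroid = 0, rigid6 = 1, affine12 = 2, nonlinear = 3)
  kinds <- vapply(stages, function(s) s$kind, "")
  if (kinds[1] != "centroid")
    stop("the first stage of a template schedule must be 'centroid'")
  if (any(!kinds %in% names(dof_rank)))
    stop("unknown stage kind")
  if (any(diff(dof_rank[kinds]) < 0))
    stop("degrees of freedom must not decrease along the schedule")
  if (any(vapply(stages, function(s) s$iterations, 0) < 1))
    stop("every stage needs iterations >= 1")
  structure(list(stages = stages, convergence_tol = convergence_tol),
            class = "template_schedule")
}

#' Iterative group-wise template construction
#'
#' Builds a study template by the multi-level scheme: start from the
#' centroid-aligned average ([initialize_template()]), then repeatedly
#' register every subject to the current template — with the transform
#' family of the active stage, composing onto the subject's chain —
#' resample, and re-average the median-normalised images. Later stages
#' add degrees of freedom (rigid, then affine, then nonlinear). A
#' stage stops early when the mean relative template change falls
#' below the schedule tolerance.
#'
#' Subjects are expected to be bias-corrected head images.
#'
#' @param images list of >= 2 `volume_image`s.
#' @param masks matching brain `mask_image`s (gate the metric for
#'   linear stages and provide centroids).
#' @param schedule a [template_schedule()].
#' @param average `"mean"` or `"trimmed"` (drops the voxelwise min and
#'   max across subjects before averaging; needs >= 4 subjects).
#' @return a `template_result` list: `template` (`volume_image`),
#'   `per_subject_chains` (list of `transform_chain`s mapping template
#'   world coordinates into each subject's world), and
#'   `convergence_log` (`data.frame` of stage, iteration, mean
#'   relative change, mean pairwise NMI).
#' @export
build_template <- function(images, masks, schedule = template_schedule(),
                           average = c("mean", "trimmed")) {
  average <- match.arg(average)
  if (length(images) < 2) stop("at least 2 subjects are required")
  stopifnot(inherits(schedule, "template_schedule"))
  n <- length(images)
  grid <- as_grid(images[[1]])
  ctr <- grid_center_world(grid)

  norm_imgs <- lapply(seq_len(n), function(s)
    intensity_normalize(images[[s]], masks[[s]]))

  # linear part of each chain (template world -> subject world) and an
  # optional per-subject nonlinear field on the template grid
  lin <- lapply(seq_len(n), function(s)
    affine_transform(translation_matrix(image_centroid(masks[[s]]) - ctr),
                     "rigid6"))
  nlf <- vector("list", n)

  chain_of <- function(s) {
    if (is.null(nlf[[s]])) transform_chain(list(lin[[s]]))
    else transform_chain(list(nlf[[s]], lin[[s]]))
  }
  # consensus brain mask on the template grid: majority vote of the
  # resampled subject masks. The metric domain of the linear stages is
  # restricted to this mask on the *target* side only: it keeps the
  # smeared skull ring of an early blurry average out of the metric
  # (an unmasked pair locks onto it), while the moving subject keeps
  # its whole-head intensities — a hard mask edge on the moving image
  # costs an order of magnitude in rotational accuracy.
  consensus_mask <- function() {
    acc <- array(0, dim = grid$shape)
    for (s in seq_len(n))
      acc <- acc + resample(masks[[s]], grid, chain_of(s), "nearest")$data
    m <- array(as.integer(acc >= n / 2), dim = grid$shape)
    if (!any(m == 1L)) m[which.max(acc)] <- 1L
    mask_image(m, grid$affine)
  }
  resampled <- function(s, interpolation = "trilinear") {
    resample(norm_imgs[[s]], grid, chain_of(s), interpolation)
  }
  average_subjects <- function() {
    stack <- vapply(seq_len(n), function(s) resampled(s)$data,
                    array(0, dim = grid$shape))
    dim(stack) <- c(prod(grid$shape), n)
    v <- if (average == "trimmed" && n >= 4)
      (rowSums(stack) - apply(stack, 1, max) - apply(stack, 1, min)) / (n - 2)
    else rowMeans(stack)
    volume_image(array(v, dim = grid$shape), grid$affine)
  }
  pairwise_nmi <- function() {
    arrs <- lapply(seq_len(n), function(s) resampled(s)$data)
    vals <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      vals <- c(vals, nmi(arrs[[i]], arrs[[j]]))
    mean(vals)
  }

  template <- average_subjects()
  log_rows <- list()
  for (st_i in seq_along(schedule$stages)) {
    stage <- schedule$stages[[st_i]]
    if (stage$kind == "centroid") {
      log_rows[[length(log_rows) + 1]] <-
        data.frame(stage = st_i, kind = stage$kind, iteration = 1L,
                   mean_rel_change = NA_real_,
                   mean_pairwise_nmi = pairwise_nmi())
      next
    }
    first_linear <- stage$kind == "rigid6" &&
      !any(vapply(schedule$stages[seq_len(st_i - 1)],
                  function(x) x$kind %in% c("rigid6", "affine12"), TRUE))
    for (it in seq_len(stage$iterations)) {
      old <- template$data
      # The centroid average is blurry wherever subjects disagree, and
      # registering against it can settle into a blurry fixed point
      # (subjects misaligned because the target is blurred, target
      # blurred because subjects are misaligned). The very first rigid
      # pass therefore targets a sharp reference — the centred first
      # subject — after which the evolving average is sharp enough to
      # take over as the symmetric target.
      target_img <- if (first_linear && it == 1L)
        resample(norm_imgs[[1]], grid, lin[[1]], "trilinear")
      else template
      tmask <- if (stage$kind %in% c("rigid6", "affine12"))
        consensus_mask() else NULL
      for (s in seq_len(n)) {
        res <- tryCatch({
          if (stage$kind %in% c("rigid6", "affine12")) {
            old_lin <- lin[[s]]
            cand <- if (stage$kind == "rigid6")
              register_rigid(norm_imgs[[s]], target_img,
                             target_mask = tmask, init = lin[[s]])
            else
              register_affine(norm_imgs[[s]], target_img,
                              target_mask = tmask, init = lin[[s]])
            # monotone acceptance: never let a stage degrade a
            # subject's whole-image similarity to the template
            lin[[s]] <- cand
            if (nmi(resampled(s), target_img) <
                  nmi(resample(norm_imgs[[s]], grid, old_lin), target_img))
              lin[[s]] <- old_lin
          } else {
            aligned <- resample(norm_imgs[[s]], grid, lin[[s]], "trilinear")
            nlf[[s]] <- register_nonlinear(aligned, template,
                                           max_level = stage$max_level)
          }
          NULL
        }, error = function(e) e)
        if (!is.null(res))
          stop("registration failed for subject ", s, " at stage ", st_i,
               " (", stage$kind, "): ", conditionMessage(res))
      }
      template <- average_subjects()
      rel <- mean(abs(template$data - old)) / mean(abs(old))
      log_rows[[length(log_rows) + 1]] <-
        data.frame(stage = st_i, kind = stage$kind, iteration = it,
                   mean_rel_change = rel,
                   mean_pairwise_nmi = pairwise_nmi())
      if (rel < schedule$convergence_tol) break
    }
  }
  structure(list(template = template,
                 per_subject_chains = lapply(seq_len(n), chain_of),
                 convergence_log = do.call(rbind, log_rows)),
            class = "template_result")
}
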