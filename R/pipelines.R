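# Ready-to-use workflows: anatomical <-> EPI/M0 coregistration in
# individual space, and registration of everything into template
# space with one-big-step resampling.

#' Coregister an anatomical image with a BOLD or perfusion series
#'
#' The modality series is reduced to a representative volume — for
#' BOLD: optional slice-timing correction, realignment to the first
#' volume and the temporal mean; for perfusion (FAIR): the fitted
#' equilibrium-magnetisation (M0) map. The anatomical image is
#' reoriented to the modality axes; in `"rigid"` mode a rigid
#' modality-to-structural transform is estimated (on the
#' representative volume) and its inverse applied to the structural
#' image, while `"reorient_only"` assumes negligible head motion
#' between the scans. Finally each EPI slice is nonlinearly registered
#' in-plane to the matching anatomical slice, correcting EPI
#' distortion ([register_slicewise()]).
#'
#' @param anat bias-corrected anatomical `volume_image`.
#' @param modality_series a `series_image`; for `modality =
#'   "perfusion"` this must be the nonselective FAIR series (a
#'   `fair_series` with inversion times as frame metadata).
#' @param modality `"bold"` or `"perfusion"`.
#' @param rigid_mode `"rigid"` or `"reorient_only"`.
#' @param slice_order,repetition_time optional slice-timing inputs
#'   (BOLD only; slice timing is skipped when `slice_order` is NULL).
#' @param workdir optional memoisation directory: stage results are
#'   cached by content hash and reused on identical reruns.
#' @return a `coreg_result` list: `anat_in_modality_space`
#'   (`volume_image` on the modality grid), `rigid` (the estimated
#'   modality-to-structural `affine_transform`, or NULL in
#'   reorient-only mode), `slice_warps` (a `slice_warp_stack`),
#'   `modality_mean` (the representative volume) and, for BOLD,
#'   `motion_table`.
#' @export
coregister <- function(anat, modality_series,
                       modality = c("bold", "perfusion"),
                       rigid_mode = c("rigid", "reorient_only"),
                       slice_order = NULL, repetition_time = NULL,
                       workdir = NULL) {
  modality <- match.arg(modality)
  rigid_mode <- match.arg(rigid_mode)
  stopifnot(inherits(anat, "volume_image"),
            inherits(modality_series, "series_image"))

  motion_table <- NULL
  if (modality == "bold") {
    series <- modality_series
    if (!is.null(slice_order)) {
      if (is.null(repetition_time))
        stop("slice timing correction requires repetition_time")
      series <- memo_call(workdir, "slice_timing",
                          list(series, slice_order, repetition_time),
                          function() slice_timing_correct(series, slice_order,
                                                          repetition_time))
    }
    re <- memo_call(workdir, "realign", list(series),
                    function() realign(series))
    motion_table <- re$motion_table
    representative <- temporal_mean(re$series)
  } else {
    fit <- memo_call(workdir, "fair_fit", list(modality_series),
                     function() fit_inversion_recovery(modality_series))
    representative <- m0_map(fit)
    # background voxels carry NA outside the fit mask; zero them for
    # registration
    rep_data <- representative$data
    rep_data[is.na(rep_data)] <- 0
    representative <- volume_image(rep_data, representative$affine)
  }

  anat_r <- reorient_to_ras(anat)
  representative <- reorient_to_ras(representative)
  grid <- as_grid(representative)

  rigid <- NULL
  if (rigid_mode == "rigid") {
    # modality-to-structural transform; its inverse carries the
    # structural image into the modality space
    rigid <- memo_call(workdir, "coreg_rigid", list(representative, anat_r),
                       function() register_rigid(representative, anat_r))
    anat_in_mod <- resample(anat_r, grid, invert(rigid), "trilinear")
  } else {
    anat_in_mod <- resample(anat_r, grid, NULL, "trilinear")
  }

  slice_warps <- memo_call(workdir, "slice_warps",
                           list(representative, anat_in_mod),
                           function() register_slicewise(representative,
                                                         anat_in_mod))
  structure(list(anat_in_modality_space = anat_in_mod,
                 rigid = rigid,
                 slice_warps = slice_warps,
                 modality_mean = representative,
                 motion_table = motion_table),
            class = "coreg_result")
}

#' Register an anatomical image to a template
#'
#' Rigid, then affine (metric gated by the brain masks when
#' available), then nonlinear registration onto the template grid, in
#' the standard whole-head configuration for the nonlinear stage.
#'
#' @param anat bias-corrected anatomical `volume_image`.
#' @param template template `volume_image`.
#' @param anat_mask,template_mask optional brain `mask_image`s; when
#'   absent they are derived with [extract_brain()].
#' @param max_level nonlinear refinement levels.
#' @return a `transform_chain` mapping template world coordinates to
#'   anatomical world coordinates (elements: displacement field, then
#'   affine).
#' @export
register_to_template <- function(anat, template, anat_mask = NULL,
                                 template_mask = NULL, max_level = 2L) {
  if (is.null(anat_mask))
    anat_mask <- tryCatch(extract_brain(anat), error = function(e) NULL)
  if (is.null(template_mask))
    template_mask <- tryCatch(extract_brain(template), error = function(e) NULL)
  aff <- register_affine(anat, template, source_mask = anat_mask,
                         target_mask = template_mask)
  aligned <- resample(anat, template, aff, "trilinear")
  field <- register_nonlinear(aligned, template, max_level = max_level)
  transform_chain(list(field, aff))
}

#' One-big-step transformation of a modality image into template space
#'
#' Concatenates the per-slice distortion warps, the
#' modality-to-structural rigid transform and the
#' structural-to-template chain and applies them with a single
#' interpolation, minimising the blurring that sequential resampling
#' accumulates.
#'
#' @param modality_image image in the (distorted) modality space.
#' @param coreg a `coreg_result`.
#' @param anat_chain `transform_chain` from [register_to_template()].
#' @param template_grid target grid (a `sampling_grid` or image).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return the image resampled on the template grid.
#' @export
transform_modality_to_template <- function(modality_image, coreg, anat_chain,
                                           template_grid,
                                           interpolation = "trilinear") {
  chain <- modality_chain(coreg, anat_chain)
  apply_chain(modality_image, chain, template_grid, interpolation)
}

#' @rdname transform_modality_to_template
#' @export
modality_chain <- function(coreg, anat_chain) {
  elems <- flatten_chain(anat_chain)
  if (!is.null(coreg$rigid)) elems <- c(elems, list(coreg$rigid))
  elems <- c(elems, list(coreg$slice_warps))
  transform_chain(elems)
}

#' Carry a template-space image back to the modality space
#'
#' Inverts every element of the composite template-to-modality chain
#' and applies them in reverse order with a single interpolation —
#' e.g. to carry a template-space atlas onto the distorted EPI frames.
#'
#' @param image_in_template image on the template grid.
#' @param coreg a `coreg_result`.
#' @param anat_chain chain from [register_to_template()].
#' @param modality_grid target grid (defaults to the coregistration's
#'   modality grid).
#' @param interpolation `"trilinear"`, or `"nearest"` for labels.
#' @return the image resampled on the modality grid.
#' @export
inverse_transform_towards_modality <- function(image_in_template, coreg,
                                               anat_chain,
                                               modality_grid = NULL,
                                               interpolation = "trilinear") {
  if (is.null(modality_grid)) modality_grid <- as_grid(coreg$modality_mean)
  chain <- invert(modality_chain(coreg, anat_chain))
  apply_chain(image_in_template, chain, modality_grid, interpolation)
}

# --- memoisation -----------------------------------------------------

# content-hash keyed cache replacing workflow-engine caching: results
# of expensive stages are stored as RDS under the work directory and
# reused when inputs and parameters are identical
memo_call <- function(workdir, tag, key_objects, compute) {
  if (is.null(workdir)) return(compute())
  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  key <- content_hash(list(tag = tag, key = key_objects))
  path <- file.path(workdir, paste0(tag, "_", key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  value <- compute()
  saveRDS(value, path)
  value
}

content_hash <- function(object) {
  raw <- serialize(object, NULL, version = 3)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(raw, f)
  unname(tools::md5sum(f))
}
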