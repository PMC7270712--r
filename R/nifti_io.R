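#' Read a NIfTI-1 file
#'
#' Reads plain or gzip-compressed NIfTI-1. 3D files become a
#' [volume_image()] (or [mask_image()] / [label_image()] when requested
#' through `as`); 4D files become a [series_image()]. Data are promoted
#' to doubles (integers for masks/labels) and the sform affine is used,
#' falling back to the qform.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as requested role: `"auto"` (3D volume / 4D series),
#'   `"volume"`, `"mask"`, `"label"`, or `"series"`.
#' @param frame_metadata optional per-frame metadata for 4D reads
#'   (e.g. inversion times).
#' @return a rodentmri image of the requested class.
#' @export
read_nifti <- function(path, as = c("auto", "volume", "mask", "label", "series"),
                       frame_metadata = NULL) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  nii <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file ", path,
                                           ": ", conditionMessage(e)))
  dm <- dim(nii)
  if (length(dm) == 4L && dm[4] == 1L) {
    nii <- array(as.vector(nii)[seq_len(prod(dm[1:3]))], dim = dm[1:3],
                 dimnames = NULL)
    dm <- dim(nii)
  }
  affine <- structure(RNifti::xform(nii), imagedim = NULL, code = NULL)
  affine <- matrix(as.double(affine), 4, 4)
  if (abs(det(affine[1:3, 1:3])) <= .Machine$double.eps * 100)
    stop("NIfTI file ", path, " has a singular affine")
  arr <- array(as.double(nii), dim = dm)
  if (!all(is.finite(arr)))
    stop("NIfTI file ", path, " contains non-finite voxels")
  if (length(dm) == 3L) {
    switch(as,
           auto = , volume = volume_image(arr, affine),
           mask = mask_image(arr, affine),
           label = label_image(arr, affine),
           series = stop("file ", path, " is 3D; cannot read as a series"))
  } else if (length(dm) == 4L) {
    if (as %in% c("volume", "mask", "label"))
      stop("file ", path, " is 4D; cannot read as a 3D ", as)
    series_image(arr, affine, frame_metadata = frame_metadata)
  } else {
    stop("NIfTI file ", path, " has unsupported dimensionality ", length(dm))
  }
}

#' Write an image to NIfTI-1
#'
#' Volumes and series are stored as float64, masks as int16 and label
#' maps as int32, with the affine recorded in the sform (code 2). A
#' written file re-reads to an equal image: data bit-exact at the
#' stored precision, affine within 1e-6.
#'
#' @param image any rodentmri image.
#' @param path output path; `.nii.gz` compresses, `.nii` does not.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(image, path) {
  stopifnot(inherits(image, "rodentmri_image"))
  arr <- if (inherits(image, "series_image")) image$frames else image$data
  if (!all(is.finite(arr))) stop("refusing to write non-finite voxel values")
  datatype <- if (inherits(image, "mask_image")) "int16"
              else if (inherits(image, "label_image")) "int32"
              else "double"
  nii <- RNifti::asNifti(arr, datatype = datatype)
  nii <- RNifti::`sform<-`(nii, structure(image$affine, code = 2L))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write NIfTI file, no such directory: ", dir)
  tryCatch(RNifti::writeNifti(nii, path),
           error = function(e) stop("failed to write NIfTI file ", path,
                                    ": ", conditionMessage(e)))
  invisible(path)
}
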