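#' Image containers
#'
#' All images in rodentmri share one geometric model: a dense array of
#' voxel values plus a 4x4 affine mapping 0-based voxel indices
#' `(i, j, k, 1)` to world coordinates in millimetres. After
#' [reorient_to_ras()] the world frame is RAS+ (+x right, +y anterior,
#' +z superior). Intensities are held as doubles; masks and label maps
#' as integers.
#'
#' Four classes share this model:
#' \describe{
#'   \item{`volume_image`}{a 3D scalar volume (anatomical, template,
#'     EPI mean, fitted parameter map, ...).}
#'   \item{`mask_image`}{a binary (0/1) volume.}
#'   \item{`label_image`}{a non-negative integer region map, 0 being
#'     background; an optional `label_names` map attaches names to ids.}
#'   \item{`series_image`}{a 4D series (x, y, z, t) with one shared
#'     affine and a per-frame metadata list (frame index, inversion
#'     time, ...).}
#' }
#'
#' @param data 3D numeric array (`volume_image`, `mask_image`,
#'   `label_image`) of finite values.
#' @param affine 4x4 numeric matrix, invertible in its 3x3 block,
#'   mapping 0-based voxel indices to world mm.
#' @param frames 4D numeric array for `series_image`.
#' @param frame_metadata list with one element per frame (any scalar
#'   tag; FAIR series store inversion times in seconds here).
#' @param label_names optional named character vector or list mapping
#'   label id (as name) to region name.
#'
#' @return An object of the corresponding class. All classes carry
#'   `$data` (or `$frames`) and `$affine`.
#' @seealso [voxel_sizes()], [read_nifti()], [write_nifti()]
#' @export
volume_image <- function(data, affine) {
  obj <- structure(list(data = check_volume_data(data),
                        affine = check_affine(affine)),
                   class = c("volume_image", "rodentmri_image"))
  obj
}

#' @rdname volume_image
#' @export
mask_image <- function(data, affine) {
  data <- check_volume_data(data)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask_image values must be exactly 0 or 1")
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = check_affine(affine)),
            class = c("mask_image", "rodentmri_image"))
}

#' @rdname volume_image
#' @export
label_image <- function(data, affine, label_names = NULL) {
  data <- check_volume_data(data)
  if (any(data < 0) || any(data != round(data)))
    stop("label_image values must be non-negative integers")
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = check_affine(affine),
                 label_names = label_names),
            class = c("label_image", "rodentmri_image"))
}

#' @rdname volume_image
#' @export
series_image <- function(frames, affine, frame_metadata = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 4L)
    stop("series_image requires a 4D array")
  if (!all(is.finite(frames)))
    stop("series_image frames contain non-finite values")
  storage.mode(frames) <- "double"
  nt <- dim(frames)[4]
  if (is.null(frame_metadata)) frame_metadata <- as.list(seq_len(nt) - 1L)
  if (length(frame_metadata) != nt)
    stop("frame_metadata length (", length(frame_metadata),
         ") must equal the number of frames (", nt, ")")
  structure(list(frames = frames, affine = check_affine(affine),
                 frame_metadata = frame_metadata),
            class = c("series_image", "rodentmri_image"))
}

check_volume_data <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("image data must be a 3D array")
  if (!all(is.finite(data)))
    stop("image data contains non-finite values")
  if (is.double(data)) data else {storage.mode(data) <- "double"; data}
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) <= .Machine$double.eps * 100)
    stop("affine 3x3 block is singular")
  storage.mode(affine) <- "double"
  affine
}

#' Voxel sizes of an image
#'
#' Column norms of the 3x3 block of the affine, in mm.
#'
#' @param image any rodentmri image.
#' @return numeric length-3 vector of strictly positive voxel edge
#'   lengths (mm).
#' @export
voxel_sizes <- function(image) {
  sqrt(colSums(image$affine[1:3, 1:3]^2))
}

#' Grid shape of an image
#' @param image any rodentmri image.
#' @return integer vector of spatial dimensions (length 3).
#' @export
grid_shape <- function(image) {
  d <- if (inherits(image, "series_image")) dim(image$frames)[1:3] else dim(image$data)
  as.integer(d)
}

#' Extract one frame of a 4D series as a volume
#' @param series a `series_image`.
#' @param t frame index (1-based).
#' @return `volume_image` on the series grid.
#' @export
series_frame <- function(series, t) {
  stopifnot(inherits(series, "series_image"))
  nt <- dim(series$frames)[4]
  if (t < 1 || t > nt) stop("frame index out of range")
  volume_image(series$frames[, , , t, drop = TRUE], series$affine)
}

#' A reference sampling grid
#'
#' A grid is a shape plus an affine; every resampling operation targets
#' one. Any image can stand in for a grid.
#'
#' @param shape integer length-3 spatial dimensions.
#' @param affine 4x4 voxel-to-world matrix.
#' @return a `sampling_grid` object.
#' @export
sampling_grid <- function(shape, affine) {
  structure(list(shape = as.integer(shape), affine = check_affine(affine)),
            class = "sampling_grid")
}

as_grid <- function(x) {
  if (inherits(x, "sampling_grid")) return(x)
  if (inherits(x, "rodentmri_image")) return(sampling_grid(grid_shape(x), x$affine))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a sampling grid")
}

#' @export
print.rodentmri_image <- function(x, ...) {
  kind <- class(x)[1]
  sh <- grid_shape(x)
  vs <- voxel_sizes(x)
  cat(sprintf("<%s> %s voxels, %s mm", kind,
              paste(sh, collapse = "x"),
              paste(signif(vs, 3), collapse = "x")))
  if (inherits(x, "series_image"))
    cat(sprintf(", %d frames", dim(x$frames)[4]))
  cat("\n")
  invisible(x)
}

#' World coordinates of voxel indices
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @param idx0 n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates (mm).
#' @keywords internal
voxel_to_world <- function(affine, idx0) {
  idx0 <- rbind(t(idx0), 1)
  t(affine %*% idx0)[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param world n x 3 matrix of world coordinates.
#' @keywords internal
world_to_voxel <- function(affine, world) {
  inv <- solve(affine)
  world <- rbind(t(world), 1)
  t(inv %*% world)[, 1:3, drop = FALSE]
}

# 0-based index grid of a shape, as an n x 3 matrix in array order
index_grid0 <- function(shape) {
  cbind(rep.int(seq_len(shape[1]) - 1L, shape[2] * shape[3]),
        rep.int(rep(seq_len(shape[2]) - 1L, each = shape[1]), shape[3]),
        rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2]))
}

# world mm coordinate of the geometric grid centre (0-based index (n-1)/2)
grid_center_world <- function(grid) {
  grid <- as_grid(grid)
  c(voxel_to_world(grid$affine, matrix((grid$shape - 1) / 2, 1)))
}
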