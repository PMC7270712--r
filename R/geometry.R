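#' Reorient an image to the closest RAS+ axis alignment
#'
#' Finds the axis permutation and flips that bring the affine's 3x3
#' block closest to a positive diagonal (+x right, +y anterior,
#' +z superior), permutes/flips the data accordingly, and updates the
#' affine so that the world coordinate of every piece of tissue is
#' unchanged. This is a lossless relabelling: no resampling occurs.
#' Oblique affines (off-axis direction cosines) are reoriented to the
#' nearest axis frame and left oblique, with a warning.
#'
#' Idempotent: reorienting an already-RAS image returns it unchanged.
#'
#' @param image any rodentmri image.
#' @return an image of the same class on the reoriented grid.
#' @export
reorient_to_ras <- function(image) {
  A <- image$affine
  R <- A[1:3, 1:3]
  # normalised direction cosines of each voxel axis
  dirs <- sweep(R, 2, sqrt(colSums(R^2)), "/")
  # greedy assignment: voxel axis -> world axis with the largest |cosine|
  perm <- integer(3)   # perm[world_axis] = voxel_axis
  sign <- integer(3)
  work <- abs(dirs)
  for (n in 1:3) {
    ij <- arrayInd(which.max(work), c(3L, 3L))
    w <- ij[1]; v <- ij[2]
    perm[w] <- v
    sign[w] <- if (dirs[w, v] >= 0) 1L else -1L
    work[w, ] <- -1; work[, v] <- -1
  }
  # obliquity check: worst-aligned axis
  cosines <- vapply(1:3, function(w) abs(dirs[w, perm[w]]), 0)
  if (min(cosines) < cos(20 * pi / 180))
    warning("affine is oblique (worst axis cosine ",
            signif(min(cosines), 3), "); reoriented to nearest axes, ",
            "obliquity preserved")
  if (identical(perm, 1:3) && all(sign == 1L)) return(image)

  apply_reorient <- function(arr) {
    arr <- aperm(arr, perm)
    for (w in 1:3) if (sign[w] < 0) {
      idx <- rev(seq_len(dim(arr)[w]))
      arr <- switch(w, arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE],
                    arr[, , idx, drop = FALSE])
    }
    arr
  }
  old_shape <- grid_shape(image)
  # S maps new 0-based indices to old 0-based indices
  S <- matrix(0, 4, 4); S[4, 4] <- 1
  for (w in 1:3) {
    v <- perm[w]
    if (sign[w] > 0) S[v, w] <- 1
    else { S[v, w] <- -1; S[v, 4] <- old_shape[v] - 1 }
  }
  new_affine <- A %*% S

  if (inherits(image, "series_image")) {
    nt <- dim(image$frames)[4]
    frames <- array(0, dim = c(old_shape[perm], nt))
    for (t in seq_len(nt)) frames[, , , t] <- apply_reorient(image$frames[, , , t])
    return(series_image(frames, new_affine, image$frame_metadata))
  }
  data <- apply_reorient(image$data)
  rebuild_image(image, data, new_affine)
}

rebuild_image <- function(proto, data, affine) {
  if (inherits(proto, "mask_image")) mask_image(data, affine)
  else if (inherits(proto, "label_image")) label_image(data, affine, proto$label_names)
  else volume_image(data, affine)
}

#' Resample an image onto a reference grid through a spatial transform
#'
#' For each voxel of `reference_grid`, its world coordinate is mapped
#' through `transform` (which must map reference-space world mm into
#' the image's world mm; identity when `NULL`) and the image is
#' interpolated once at the mapped point. Points falling outside the
#' image's field of view yield 0.
#'
#' @param image a `volume_image`, `mask_image` or `label_image`.
#' @param reference_grid a `sampling_grid` or any image to copy the
#'   grid from.
#' @param transform `NULL` (identity), an [affine_transform()], a
#'   [displacement_field()], a [slice_warp_stack()], or a
#'   [transform_chain()] applied first-to-last.
#' @param interpolation `"trilinear"` or `"nearest"`. Masks and label
#'   maps require `"nearest"`.
#' @return an image of the same class on `reference_grid`.
#' @export
resample <- function(image, reference_grid, transform = NULL,
                     interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (inherits(image, c("mask_image", "label_image")) &&
      interpolation != "nearest")
    stop("masks and label maps must be resampled with nearest-neighbour ",
         "interpolation")
  grid <- as_grid(reference_grid)
  pts <- voxel_to_world(grid$affine, index_grid0(grid$shape))
  pts <- map_points(transform, pts)
  vox <- world_to_voxel(image$affine, pts)
  vals <- interpolate_at(image$data, vox, interpolation)
  data <- array(vals, dim = grid$shape)
  rebuild_image(image, data, grid$affine)
}

# vox: n x 3 fractional 0-based voxel coordinates.
# "trilinear"/"nearest" yield 0 outside the array; "trilinear_clamp"
# extends edge values (used for sampling displacement fields, where a
# hard zero at the field border would fabricate a discontinuity)
interpolate_at <- function(arr, vox, interpolation) {
  dm <- dim(arr)
  if (interpolation == "trilinear_clamp") {
    vox <- cbind(pmin(pmax(vox[, 1], 0), dm[1] - 1),
                 pmin(pmax(vox[, 2], 0), dm[2] - 1),
                 pmin(pmax(vox[, 3], 0), dm[3] - 1))
    interpolation <- "trilinear"
  }
  if (interpolation == "nearest") {
    i <- round(vox[, 1]); j <- round(vox[, 2]); k <- round(vox[, 3])
    ok <- i >= 0 & i <= dm[1] - 1 & j >= 0 & j <= dm[2] - 1 &
          k >= 0 & k <= dm[3] - 1
    out <- numeric(nrow(vox))
    idx <- 1 + i[ok] + dm[1] * (j[ok] + dm[2] * k[ok])
    out[ok] <- arr[idx]
    return(out)
  }
  eps <- 1e-9
  x <- vox[, 1]; y <- vox[, 2]; z <- vox[, 3]
  ok <- x >= -eps & x <= dm[1] - 1 + eps &
        y >= -eps & y <= dm[2] - 1 + eps &
        z >= -eps & z <= dm[3] - 1 + eps
  out <- numeric(nrow(vox))
  if (!any(ok)) return(out)
  x <- pmin(pmax(x[ok], 0), dm[1] - 1); y <- pmin(pmax(y[ok], 0), dm[2] - 1)
  z <- pmin(pmax(z[ok], 0), dm[3] - 1)
  i0 <- pmin(floor(x), max(dm[1] - 2, 0)); fx <- x - i0
  j0 <- pmin(floor(y), max(dm[2] - 2, 0)); fy <- y - j0
  k0 <- pmin(floor(z), max(dm[3] - 2, 0)); fz <- z - k0
  i1 <- pmin(i0 + 1, dm[1] - 1); j1 <- pmin(j0 + 1, dm[2] - 1)
  k1 <- pmin(k0 + 1, dm[3] - 1)
  at <- function(i, j, k) arr[1 + i + dm[1] * (j + dm[2] * k)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(i0, j0, k0) +
       fx       * (1 - fy) * (1 - fz) * at(i1, j0, k0) +
       (1 - fx) * fy       * (1 - fz) * at(i0, j1, k0) +
       fx       * fy       * (1 - fz) * at(i1, j1, k0) +
       (1 - fx) * (1 - fy) * fz       * at(i0, j0, k1) +
       fx       * (1 - fy) * fz       * at(i1, j0, k1) +
       (1 - fx) * fy       * fz       * at(i0, j1, k1) +
       fx       * fy       * fz       * at(i1, j1, k1)
  out[ok] <- v
  out
}

#' Centroid of a binary mask in world coordinates
#'
#' @param mask a nonempty `mask_image`.
#' @return length-3 numeric, the mean world coordinate (mm) of the
#'   voxels with value 1.
#' @export
image_centroid <- function(mask) {
  stopifnot(inherits(mask, "mask_image"))
  on <- which(mask$data == 1L)
  if (length(on) == 0L) stop("cannot compute the centroid of an empty mask")
  idx <- arrayInd(on, dim(mask$data)) - 1L
  colMeans(voxel_to_world(mask$affine, idx))
}

# Integer-factor block-mean downsampling (antialiasing by averaging).
# The new affine places each coarse voxel at the centre of its block.
downsample_volume <- function(image, factor) {
  if (factor == 1L) return(image)
  arr <- image$data
  dm <- dim(arr)
  nd <- pmax(dm %/% factor, 1L)
  keep <- nd * factor
  # truncate trailing voxels that do not fill a block
  arr <- arr[seq_len(min(keep[1], dm[1])), seq_len(min(keep[2], dm[2])),
             seq_len(min(keep[3], dm[3])), drop = FALSE]
  dm <- dim(arr)
  blk <- function(a, axis) {
    d <- dim(a)
    n <- d[axis] %/% factor
    if (axis == 1) {
      dim(a) <- c(factor, n, d[2], d[3])
      a <- colMeans(a)            # n x d2 x d3
    } else if (axis == 2) {
      a <- aperm(a, c(2, 1, 3))
      dim(a) <- c(factor, n, d[1], d[3])
      a <- aperm(colMeans(a), c(2, 1, 3))
    } else {
      a <- aperm(a, c(3, 1, 2))
      dim(a) <- c(factor, n, d[1], d[2])
      a <- aperm(colMeans(a), c(2, 3, 1))
    }
    a
  }
  arr <- blk(blk(blk(arr, 1), 2), 3)
  M <- diag(4)
  diag(M)[1:3] <- factor
  M[1:3, 4] <- (factor - 1) / 2
  volume_image(arr, image$affine %*% M)
}
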