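#' Spatial transforms
#'
#' All transforms map world coordinates (mm) of a *reference* (target)
#' space into world coordinates of a *source* space — the pull-back
#' convention used by [resample()]: to draw an image onto a reference
#' grid, each reference voxel's world coordinate is pushed through the
#' transform and the source image is interpolated there.
#'
#' @param matrix 4x4 world-to-world matrix.
#' @param dof_tag one of `"rigid6"`, `"similarity7"`, `"affine12"`.
#' @return an `affine_transform` object.
#' @export
affine_transform <- function(matrix, dof_tag = "affine12") {
  matrix <- check_affine(matrix)
  dof_tag <- match.arg(dof_tag, c("rigid6", "similarity7", "affine12"))
  if (dof_tag == "rigid6") {
    R <- matrix[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
      stop("rigid6 transform must have an orthonormal, proper 3x3 block")
  }
  structure(list(matrix = matrix, dof_tag = dof_tag),
            class = c("affine_transform", "rodentmri_transform"))
}

#' Dense displacement field
#'
#' Per-voxel 3-vector world-mm displacements defined on a stated grid.
#' The mapping is `x -> x + d(x)` with `d` sampled trilinearly on the
#' field's grid (zero outside it). Emitted fields satisfy the
#' diffeomorphism contract: the discrete Jacobian determinant of the
#' mapping is strictly positive at every interior voxel.
#'
#' @param disp 4D array `(nx, ny, nz, 3)` of displacements in mm.
#' @param affine 4x4 voxel-to-world matrix of the field's grid.
#' @param level_history numeric vector of control-grid spacings (mm)
#'   used to build the field, coarse to fine.
#' @return a `displacement_field` object.
#' @export
displacement_field <- function(disp, affine, level_history = numeric()) {
  if (!is.array(disp) || length(dim(disp)) != 4L || dim(disp)[4] != 3L)
    stop("displacement field must be an (nx, ny, nz, 3) array")
  if (!all(is.finite(disp))) stop("displacement field contains non-finite values")
  storage.mode(disp) <- "double"
  structure(list(disp = disp, affine = check_affine(affine),
                 level_history = level_history),
            class = c("displacement_field", "rodentmri_transform"))
}

#' Per-slice in-plane warp stack
#'
#' One 2D in-plane displacement field per z-slice on a shared in-plane
#' grid, with zero out-of-plane displacement — the output of
#' [register_slicewise()]. Stored as an `(nx, ny, nz, 2)` array of
#' (x, y) world-mm displacements.
#'
#' @param disp 4D array `(nx, ny, nz, 2)` of in-plane displacements mm.
#' @param affine 4x4 voxel-to-world matrix of the stack's grid.
#' @return a `slice_warp_stack` object.
#' @export
slice_warp_stack <- function(disp, affine) {
  if (!is.array(disp) || length(dim(disp)) != 4L || dim(disp)[4] != 2L)
    stop("slice warp stack must be an (nx, ny, nz, 2) array")
  if (!all(is.finite(disp))) stop("slice warps contain non-finite values")
  storage.mode(disp) <- "double"
  structure(list(disp = disp, affine = check_affine(affine)),
            class = c("slice_warp_stack", "rodentmri_transform"))
}

#' Ordered chain of transforms
#'
#' Elements are applied first-to-last to reference-space points:
#' `x_source = T_n(...T_2(T_1(x_ref)))`. Used to express composite
#' mappings (e.g. template -> anatomical -> EPI -> distorted EPI) that
#' are applied with a single interpolation.
#'
#' @param ... transforms, or a single list of transforms.
#' @return a `transform_chain`.
#' @export
transform_chain <- function(...) {
  elts <- list(...)
  if (length(elts) == 1L && is.list(elts[[1]]) &&
      !inherits(elts[[1]], "rodentmri_transform"))
    elts <- elts[[1]]
  for (e in elts)
    if (!inherits(e, "rodentmri_transform"))
      stop("transform_chain elements must be transforms")
  structure(list(elements = elts),
            class = c("transform_chain", "rodentmri_transform"))
}

#' Flatten a chain of transforms into a single composable mapping
#'
#' Nested chains are flattened and adjacent affine elements are
#' multiplied into one matrix; the result maps points exactly as the
#' original chain does but with the fewest elements.
#'
#' @param chain a `transform_chain` (or any single transform).
#' @return a `transform_chain` (possibly of one element).
#' @export
compose <- function(chain) {
  elts <- flatten_chain(chain)
  out <- list()
  for (e in elts) {
    n <- length(out)
    if (n > 0 && inherits(e, "affine_transform") &&
        inherits(out[[n]], "affine_transform")) {
      # out[[n]] applied first, then e: x -> e(out[[n]](x))
      m <- e$matrix %*% out[[n]]$matrix
      tag <- if (e$dof_tag == "rigid6" && out[[n]]$dof_tag == "rigid6")
        "rigid6" else "affine12"
      out[[n]] <- affine_transform(m, tag)
    } else out[[n + 1]] <- e
  }
  transform_chain(out)
}

flatten_chain <- function(x) {
  if (is.null(x)) return(list())
  if (inherits(x, "transform_chain"))
    return(do.call(c, c(lapply(x$elements, flatten_chain), list(list()))))
  list(x)
}

#' Map world-space points through a transform
#'
#' @param transform `NULL` (identity) or any rodentmri transform.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
map_points <- function(transform, pts) {
  if (is.null(transform)) return(pts)
  UseMethod("map_points")
}

#' @export
map_points.affine_transform <- function(transform, pts) {
  t(transform$matrix %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
}

#' @export
map_points.displacement_field <- function(transform, pts) {
  pts + sample_field(transform$disp, transform$affine, pts)
}

#' @export
map_points.slice_warp_stack <- function(transform, pts) {
  d <- sample_field(transform$disp, transform$affine, pts)
  pts + cbind(d, 0)
}

#' @export
map_points.transform_chain <- function(transform, pts) {
  for (e in transform$elements) pts <- map_points(e, pts)
  pts
}

# sample each component of a vector field at world points; edge values
# are extended outside the field's grid (a zero there would be a jump)
sample_field <- function(disp, affine, pts) {
  vox <- world_to_voxel(affine, pts)
  nc <- dim(disp)[4]
  out <- matrix(0, nrow(pts), nc)
  for (c in seq_len(nc))
    out[, c] <- interpolate_at(disp[, , , c, drop = TRUE], vox,
                               "trilinear_clamp")
  out
}

#' Apply a transform chain to an image with a single interpolation
#'
#' The "one-big-step" application: every reference voxel is mapped
#' through the whole chain and the source image is interpolated once,
#' avoiding the blurring that repeated resampling accumulates.
#'
#' @param image image to resample.
#' @param chain a `transform_chain` (or single transform, or `NULL`).
#' @param reference_grid target grid.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return image of the same class on `reference_grid`.
#' @export
apply_chain <- function(image, chain, reference_grid,
                        interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  resample(image, reference_grid, chain, interpolation)
}

#' Invert a transform
#'
#' Affines are inverted exactly. Displacement fields are inverted by
#' fixed-point iteration `e_{k+1}(x) = -d(x + e_k(x))`; the iteration
#' converges for the capped fields this package emits. Chains are
#' inverted element-wise in reverse order.
#'
#' @param transform a transform.
#' @param max_iter,tol fixed-point iteration controls (displacement
#'   fields): iteration stops when the mean update falls below `tol`
#'   mm; failure to converge within `max_iter` iterations is an error
#'   reporting the residual.
#' @return the inverse transform (same class; chains stay chains).
#' @export
invert <- function(transform, max_iter = 50L, tol = 1e-4) {
  UseMethod("invert")
}

#' @export
invert.affine_transform <- function(transform, max_iter = 50L, tol = 1e-4) {
  affine_transform(solve(transform$matrix), transform$dof_tag)
}

#' @export
invert.displacement_field <- function(transform, max_iter = 50L, tol = 1e-4) {
  inv_disp <- invert_field_array(transform$disp, transform$affine,
                                 zpad = TRUE, max_iter = max_iter, tol = tol)
  displacement_field(inv_disp, transform$affine, transform$level_history)
}

#' @export
invert.slice_warp_stack <- function(transform, max_iter = 50L, tol = 1e-4) {
  disp3 <- array(0, dim = c(dim(transform$disp)[1:3], 3L))
  disp3[, , , 1:2] <- transform$disp
  inv3 <- invert_field_array(disp3, transform$affine, zpad = TRUE,
                             max_iter = max_iter, tol = tol)
  slice_warp_stack(inv3[, , , 1:2, drop = FALSE], transform$affine)
}

#' @export
invert.transform_chain <- function(transform, max_iter = 50L, tol = 1e-4) {
  transform_chain(lapply(rev(transform$elements), invert,
                         max_iter = max_iter, tol = tol))
}

invert_field_array <- function(disp, affine, zpad, max_iter, tol) {
  shape <- dim(disp)[1:3]
  pts <- voxel_to_world(affine, index_grid0(shape))
  e <- matrix(0, nrow(pts), 3)
  field <- displacement_field(disp, affine)
  last <- Inf
  for (it in seq_len(max_iter)) {
    e_new <- -sample_field(disp, affine, pts + e)
    upd <- mean(sqrt(rowSums((e_new - e)^2)))
    e <- e_new
    if (upd < tol) { last <- upd; break }
    last <- upd
  }
  if (last >= tol * 10 && last > 0.01)
    stop("displacement field inversion did not converge: mean update ",
         signif(last, 3), " mm after ", max_iter, " iterations")
  inv <- array(e, dim = c(shape, 3L))
  inv
}

#' Discrete Jacobian determinants of a displacement field
#'
#' Central-difference Jacobian of the mapping `x + d(x)` at interior
#' voxels, in world coordinates.
#'
#' @param field a `displacement_field` or `slice_warp_stack` (the
#'   latter is evaluated per-slice in 2D).
#' @return numeric array of determinants on the interior grid.
#' @export
jacobian_determinants <- function(field) {
  if (inherits(field, "slice_warp_stack")) {
    disp <- array(0, dim = c(dim(field$disp)[1:3], 3L))
    disp[, , , 1:2] <- field$disp
    return(jac_det_2d(disp, field$affine))
  }
  jac_det_3d(field$disp, field$affine)
}

jac_det_3d <- function(disp, affine) {
  dm <- dim(disp)[1:3]
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  ii <- 2:(dm[1] - 1); jj <- 2:(dm[2] - 1); kk <- 2:(dm[3] - 1)
  g <- function(c, axis) {
    a <- disp[, , , c, drop = TRUE]
    switch(axis,
      (a[ii + 1, jj, kk] - a[ii - 1, jj, kk]) / (2 * vs[1]),
      (a[ii, jj + 1, kk] - a[ii, jj - 1, kk]) / (2 * vs[2]),
      (a[ii, jj, kk + 1] - a[ii, jj, kk - 1]) / (2 * vs[3]))
  }
  J11 <- 1 + g(1, 1); J12 <- g(1, 2); J13 <- g(1, 3)
  J21 <- g(2, 1); J22 <- 1 + g(2, 2); J23 <- g(2, 3)
  J31 <- g(3, 1); J32 <- g(3, 2); J33 <- 1 + g(3, 3)
  J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
}

jac_det_2d <- function(disp, affine) {
  dm <- dim(disp)[1:3]
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  ii <- 2:(dm[1] - 1); jj <- 2:(dm[2] - 1)
  out <- array(0, dim = c(dm[1] - 2, dm[2] - 2, dm[3]))
  for (k in seq_len(dm[3])) {
    ax <- disp[, , k, 1]; ay <- disp[, , k, 2]
    J11 <- 1 + (ax[ii + 1, jj] - ax[ii - 1, jj]) / (2 * vs[1])
    J12 <- (ax[ii, jj + 1] - ax[ii, jj - 1]) / (2 * vs[2])
    J21 <- (ay[ii + 1, jj] - ay[ii - 1, jj]) / (2 * vs[1])
    J22 <- 1 + (ay[ii, jj + 1] - ay[ii, jj - 1]) / (2 * vs[2])
    out[, , k] <- J11 * J22 - J12 * J21
  }
  out
}

#' Build a rigid transform from six parameters
#'
#' Rotations (degrees, applied as Rz Ry Rx) about a world-space
#' `center`, then translation: `T(x) = R (x - c) + c + t`.
#'
#' @param params length-6 numeric `(rx, ry, rz, tx, ty, tz)`; degrees
#'   and mm.
#' @param center world-space rotation centre (mm).
#' @return an `affine_transform` tagged `rigid6`.
#' @export
rigid_transform <- function(params, center = c(0, 0, 0)) {
  R <- rotation_matrix(params[1:3])
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- center - R %*% center + params[4:6]
  affine_transform(M, "rigid6")
}

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Build a 12-parameter affine transform
#'
#' Parameters are rotations (deg), translations (mm), log-scales and
#' shears: `T(x) = R G S (x - c) + c + t` with `S = diag(exp(ls))` and
#' `G` the unit upper-triangular shear matrix.
#'
#' @param params length-12 numeric
#'   `(rx, ry, rz, tx, ty, tz, lsx, lsy, lsz, hxy, hxz, hyz)`.
#' @param center world-space centre (mm).
#' @return an `affine_transform` tagged `affine12`.
#' @export
affine12_transform <- function(params, center = c(0, 0, 0)) {
  R <- rotation_matrix(params[1:3])
  S <- diag(exp(params[7:9]))
  G <- diag(3); G[1, 2] <- params[10]; G[1, 3] <- params[11]; G[2, 3] <- params[12]
  A <- R %*% G %*% S
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- center - A %*% center + params[4:6]
  affine_transform(M, "affine12")
}

#' Write / read transforms as plain-text artifacts
#'
#' Affines are stored as 4x4 row-major text matrices; displacement
#' fields and slice-warp stacks as 5D NIfTI-1 vector images (singleton
#' 4th dimension, components along the 5th); chains as JSON manifests
#' listing element files in application order.
#'
#' @param transform the transform to write.
#' @param path output path. Chains write the manifest at `path` and
#'   elements alongside it (suffix `_1`, `_2`, ...).
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  if (inherits(transform, "affine_transform")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste("#", transform$dof_tag),
                 apply(transform$matrix, 1, function(r)
                   paste(formatC(r, format = "g", digits = 17),
                         collapse = " "))), con)
  } else if (inherits(transform, c("displacement_field", "slice_warp_stack"))) {
    dm <- dim(transform$disp)
    arr <- array(transform$disp, dim = c(dm[1:3], 1L, dm[4]))
    nii <- RNifti::asNifti(arr, datatype = "double")
    nii <- RNifti::`sform<-`(nii, structure(transform$affine, code = 2L))
    RNifti::writeNifti(nii, path)
  } else if (inherits(transform, "transform_chain")) {
    stem <- sub("\\.json$", "", path)
    files <- character(0); kinds <- character(0)
    for (i in seq_along(transform$elements)) {
      e <- transform$elements[[i]]
      ext <- if (inherits(e, "affine_transform")) ".mat" else ".nii.gz"
      f <- paste0(stem, "_", i, ext)
      write_transform(e, f)
      files <- c(files, basename(f))
      kinds <- c(kinds, class(e)[1])
    }
    jsonlite::write_json(list(kind = "transform_chain",
                              elements = files, classes = kinds),
                         path, auto_unbox = TRUE, pretty = TRUE)
  } else stop("unsupported transform class")
  invisible(path)
}

#' @rdname write_transform
#' @param kind for non-chain files: `"affine"`, `"displacement_field"`
#'   or `"slice_warp_stack"`; chains are JSON and self-describing.
#' @export
read_transform <- function(path, kind = c("auto", "affine",
                                          "displacement_field",
                                          "slice_warp_stack", "chain")) {
  kind <- match.arg(kind)
  if (kind == "auto") {
    kind <- if (grepl("\\.json$", path)) "chain"
            else if (grepl("\\.mat$|\\.txt$", path)) "affine"
            else "displacement_field"
  }
  if (kind == "affine") {
    lines <- readLines(path)
    tag <- if (grepl("^#", lines[1])) sub("^#\\s*", "", lines[1]) else "affine12"
    rows <- lines[!grepl("^#", lines)]
    M <- do.call(rbind, lapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    return(affine_transform(M, tag))
  }
  if (kind == "chain") {
    man <- jsonlite::read_json(path)
    dir <- dirname(path)
    elts <- mapply(function(f, cl) {
      k <- switch(cl, affine_transform = "affine",
                  displacement_field = "displacement_field",
                  slice_warp_stack = "slice_warp_stack")
      read_transform(file.path(dir, f), k)
    }, man$elements, man$classes, SIMPLIFY = FALSE)
    return(transform_chain(unname(elts)))
  }
  nii <- RNifti::readNifti(path)
  dm <- dim(nii)
  if (length(dm) != 5L) stop("expected a 5D vector NIfTI at ", path)
  aff <- matrix(as.double(RNifti::xform(nii)), 4, 4)
  disp <- array(as.double(nii), dim = c(dm[1:3], dm[5]))
  if (kind == "slice_warp_stack") slice_warp_stack(disp, aff)
  else displacement_field(disp, aff)
}
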