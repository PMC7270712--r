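#' Dice similarity coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)` by exact voxel counting. Both
#' masks empty is defined as 1 (perfect trivial agreement); exactly
#' one empty gives 0.
#'
#' @param mask_a,mask_b `mask_image`s (or bare 0/1 arrays) on the same
#'   grid.
#' @return a number in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  a <- if (is.list(mask_a)) mask_a$data else mask_a
  b <- if (is.list(mask_b)) mask_b$data else mask_b
  if (!all(dim(a) == dim(b)))
    stop("dice requires masks on the same grid")
  na <- sum(a == 1L); nb <- sum(b == 1L)
  if (na + nb == 0) return(1)
  2 * sum(a == 1L & b == 1L) / (na + nb)
}

#' Per-region Dice table for two label images
#'
#' One row per label present in either image (background 0 excluded),
#' with the Dice coefficient of that label's binary masks and the two
#' region sizes.
#'
#' @param labels_a,labels_b `label_image`s on the same grid.
#' @return a `data.frame` with columns `label`, `name`, `dice`,
#'   `n_voxels_a`, `n_voxels_b`.
#' @export
regional_dice <- function(labels_a, labels_b) {
  a <- labels_a$data; b <- labels_b$data
  if (!all(dim(a) == dim(b)))
    stop("regional_dice requires label images on the same grid")
  ids <- sort(setdiff(union(unique(as.vector(a)), unique(as.vector(b))), 0L))
  names_map <- labels_a$label_names
  if (is.null(names_map)) names_map <- labels_b$label_names
  rows <- lapply(ids, function(id) {
    na <- sum(a == id); nb <- sum(b == id)
    d <- if (na + nb == 0) 1 else 2 * sum(a == id & b == id) / (na + nb)
    nm <- if (!is.null(names_map)) names_map[[as.character(id)]]
          else NA_character_
    data.frame(label = id, name = if (is.null(nm)) NA_character_ else nm,
               dice = d, n_voxels_a = na, n_voxels_b = nb)
  })
  do.call(rbind, rows)
}
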