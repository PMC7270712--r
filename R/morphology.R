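# Binary morphology on 3D logical arrays with the 6-connected
# (face-neighbour) structuring element, implemented with array shifts.

shift3 <- function(arr, d, by) {
  dm <- dim(arr)
  n <- dm[d]
  out <- array(FALSE, dim = dm)
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  if (d == 1) out[dst, , ] <- arr[src, , ]
  else if (d == 2) out[, dst, ] <- arr[, src, ]
  else out[, , dst] <- arr[, , src]
  out
}

dilate6 <- function(arr, axes = 1:3) {
  out <- arr
  for (d in axes) out <- out | shift3(arr, d, 1L) | shift3(arr, d, -1L)
  out
}

erode6 <- function(arr, axes = 1:3) {
  out <- arr
  for (d in axes) out <- out & shift3_pad(arr, d, 1L) & shift3_pad(arr, d, -1L)
  out
}

# shift treating out-of-volume as FALSE would erode the borders away;
# for erosion, out-of-volume counts as background (FALSE), which is
# the conservative choice for head images inside the field of view
shift3_pad <- function(arr, d, by) shift3(arr, d, by)

open6 <- function(arr, axes = 1:3) dilate6(erode6(arr, axes), axes)
close6 <- function(arr, axes = 1:3) erode6(dilate6(arr, axes), axes)

# label 6-connected components by iterative minimum-label propagation
label_components6 <- function(arr) {
  lab <- array(0, dim = dim(arr))
  lab[arr] <- seq_len(sum(arr))
  # use linear-index seeds and propagate the minimum until stable
  full <- array(Inf, dim = dim(arr))
  full[arr] <- which(arr)
  repeat {
    nb <- full
    for (d in 1:3) for (s in c(-1L, 1L)) {
      sh <- shift3_num(full, d, s)
      nb <- pmin(nb, sh)
    }
    nb[!arr] <- Inf
    if (all(nb[arr] == full[arr])) break
    full <- nb
  }
  comp <- array(0L, dim = dim(arr))
  ids <- full[arr]
  comp[arr] <- as.integer(factor(ids))
  comp
}

shift3_num <- function(arr, d, by) {
  dm <- dim(arr)
  n <- dm[d]
  out <- array(Inf, dim = dm)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  if (d == 1) out[dst, , ] <- arr[src, , ]
  else if (d == 2) out[, dst, ] <- arr[, src, ]
  else out[, , dst] <- arr[, , src]
  out
}

largest_component6 <- function(arr) {
  comp <- label_components6(arr)
  if (max(comp) == 0L) return(array(FALSE, dim = dim(arr)))
  sizes <- tabulate(comp[comp > 0L])
  comp == which.max(sizes)
}

# fill internal holes: background 6-connected to the volume border is
# kept; everything else becomes foreground
fill_holes6 <- function(arr) {
  bg <- !arr
  border <- array(FALSE, dim = dim(arr))
  border[c(1, dim(arr)[1]), , ] <- TRUE
  border[, c(1, dim(arr)[2]), ] <- TRUE
  border[, , c(1, dim(arr)[3])] <- TRUE
  seed <- bg & border
  reach <- seed
  repeat {
    grown <- dilate6(reach) & bg
    if (all(grown == reach)) break
    reach <- grown
  }
  arr | (bg & !reach)
}
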