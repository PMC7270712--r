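# Shared fixtures, built in code. The small spec halves resolution but
# keeps the physical field of view, so geometry-dependent behaviour
# (extraction, registration basins) matches the full-size phantom.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 32L, 16L),
               voxel_sizes = c(0.4, 0.4, 1.0), ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_phantom <- function() cached("small_phantom",
                                   make_head_phantom(small_spec()))
full_phantom <- function() cached("full_phantom",
                                  make_head_phantom(phantom_spec()))

# rotation angle (deg) and translation norm (mm) of the deviation of
# an estimated world transform from a ground-truth one
transform_error <- function(est, truth) {
  M <- est$matrix %*% solve(truth$matrix)
  P <- M[1:3, 1:3]
  s <- svd(P)
  R <- s$u %*% t(s$v)
  ang <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  list(rot_deg = ang, trans_mm = sqrt(sum(M[1:3, 4]^2)),
       scale_dev = max(abs(s$d - 1)))
}

# brute-force Dice from explicit voxel index sets
dice_bruteforce <- function(a, b) {
  ia <- which(a == 1L); ib <- which(b == 1L)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}
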