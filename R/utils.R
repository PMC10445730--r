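# internal helpers shared across modules

# run `expr` under a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

check_len3 <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 3L || anyNA(x))
    abort(sprintf("`%s` must be a numeric vector of length 3 (z, y, x)", name))
  if (positive && any(x <= 0))
    abort(sprintf("`%s` must be positive", name))
  invisible(as.numeric(x))
}

check_odd3 <- function(x, name) {
  x <- check_len3(x, name)
  if (any(x != round(x)) || any(x %% 2 != 1))
    abort(sprintf("`%s` must be odd integers per axis", name))
  invisible(as.integer(x))
}

is_volume <- function(x) is.array(x) && length(dim(x)) == 3L

check_volume <- function(x, name = "volume") {
  if (!is_volume(x))
    abort(sprintf("`%s` must be a 3D array indexed (z, y, x)", name))
  invisible(x)
}

# voxel-centre physical coordinate of 1-based voxel indices (vector or n x 3)
voxel_to_um <- function(idx_zyx, voxel_size_zyx) {
  if (is.matrix(idx_zyx)) {
    sweep(idx_zyx - 1, 2, voxel_size_zyx, `*`)
  } else {
    (idx_zyx - 1) * voxel_size_zyx
  }
}
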