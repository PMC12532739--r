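# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-block child seed from a master seed; kept within 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483563) + 1L
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

check_3d_numeric <- function(x, name) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop(sprintf("'%s' must be a 3D array", name), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' contains non-finite voxels", name), call. = FALSE)
  }
  invisible(x)
}

# Accept a 2D matrix as a single-slice stack.
as_slice_stack <- function(mask) {
  if (is.matrix(mask)) {
    array(mask, c(dim(mask), 1L))
  } else {
    mask
  }
}
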