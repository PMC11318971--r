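# internal helpers shared across modules

# Half-open binning: index of x in bins [left + (j-1)*width, left + j*width),
# j = 1..n; NA outside. findInterval on a single shared edge grid keeps the
# edge convention identical for every event (a value exactly on an edge falls
# into the bin that edge opens).
bin_index <- function(x, left, width, n) {
  edges <- left + width * (0:n)
  idx <- findInterval(x, edges)
  idx[idx < 1L | idx > n] <- NA_integer_
  # findInterval puts x == last edge into bin n; the grid is half-open
  idx[x >= edges[n + 1L]] <- NA_integer_
  idx
}

# Deterministic expansion of one root seed into per-entity streams, so entity
# k of a dataset is reproducible in isolation. Plain 32-bit-safe congruential
# mix done in doubles (exact below 2^53).
derive_seed <- function(root, counter) {
  m <- 2147483647 # 2^31 - 1
  x <- (as.double(root) %% m) + 1
  for (c in as.double(counter)) {
    x <- (x * 48271 + (c %% m) * 69621 + 1) %% m
  }
  as.integer(x %% (m - 1)) + 1L
}

# run code under a local RNG state when a seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# near-equality for bin-grid alignment checks
is_multiple_of <- function(x, step, tol = 1e-9) {
  abs(x / step - round(x / step)) < tol
}
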