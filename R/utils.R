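# Internal helpers shared across modules.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generator calls are pure functions of (spec, seed).
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed stream: exact in double arithmetic, always in
# [1, 2^31 - 2] so it is a valid R integer seed.
.subSeed <- function(seed, k) {
  m <- 2147483629
  as.integer((abs(seed) %% m * 48271 + k * 1299721) %% m + 1)
}

.assertScalar <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop(name, " must be > 0", call. = FALSE)
  invisible(x)
}

# Pixel-center grids for footprint rasterization, 0-based (x = col, y = row).
.pixelGrid <- function(width, height) {
  list(x = matrix(rep(seq_len(width) - 1L, each = height), height, width),
       y = matrix(rep(seq_len(height) - 1L, times = width), height, width))
}
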