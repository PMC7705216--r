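# Internal helpers shared across modules.

# Run `code` with the RNG seeded by `seed`, restoring the caller's RNG
# state afterwards so package functions never disturb the global stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# x * log2(x) with the 0 log 0 = 0 convention.
xlog2x <- function(x) {
  out <- x * log2(x)
  out[x <= 0] <- 0
  out
}

# sample() without the scalar-x surprise.
sample_one <- function(x, prob = NULL) {
  x[sample.int(length(x), 1L, prob = prob)]
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Snap a level to the nearest multiple of `step`.
snap_to_grid <- function(level, step = 5) {
  round(level / step) * step
}

# 5-dB candidate grid between two limits (inclusive, aligned to multiples
# of `step` within [0, 110]).
level_grid <- function(lower, upper, step = 5) {
  full <- seq(0, 110, by = step)
  full[full >= lower - 1e-9 & full <= upper + 1e-9]
}
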