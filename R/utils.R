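# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers the session stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a 32-bit sub-seed from a base seed and stream indices; keeps every
# derived seed in [0, 2^31 - 2] regardless of the base seed's size.
derive_seed <- function(seed, ...) {
  ix <- c(...)
  x <- as.numeric(seed) %% 2147483647
  for (i in seq_along(ix)) {
    x <- (x * 48271 + as.numeric(ix[i]) * 131071 + 1) %% 2147483647
  }
  as.integer(x)
}

# log() that treats non-positive intensities as missing instead of warning.
safe_log <- function(x) {
  out <- suppressWarnings(log(x))
  out[!is.na(x) & x <= 0] <- NA_real_
  out
}

# Full-precision numeric formatting for TSV round-trips ("%.17g" preserves
# every double exactly); NA -> "NA".
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
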