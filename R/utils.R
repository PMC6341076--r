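# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All exported stochastic functions route their
# randomness through this so runs are reproducible under a single seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed for a named substream of a master seed,
# kept below 2^31 so it is always a valid R integer.
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_granges <- function(x, arg = deparse(substitute(x))) {
  if (!is(x, "GRanges")) stopf("'%s' must be a GRanges object", arg)
  invisible(x)
}

# Population (1/n) standard deviation, the convention used when
# z-scoring stage profiles.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

geometric_mean <- function(x) exp(mean(log(x)))
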