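# Internal helpers shared across modules.

# Run code with a temporary RNG state so package functions are reproducible
# without clobbering the caller's stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a sub-stream seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647 + as.numeric(offset) * 1000003) %% 2147483647)
}

# Population (1/N) central moments; skewness m3/m2^1.5, Pearson kurtosis m4/m2^2.
pop_moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- sum(d^2) / n
  list(m2 = m2, m3 = sum(d^3) / n, m4 = sum(d^4) / n)
}

pop_skewness <- function(x) {
  mo <- pop_moments(x)
  if (mo$m2 <= 0) return(NA_real_)
  mo$m3 / mo$m2^1.5
}

pop_kurtosis <- function(x) {
  mo <- pop_moments(x)
  if (mo$m2 <= 0) return(NA_real_)
  mo$m4 / mo$m2^2
}

# Fixed-width discretization of intensities into `levels` bins over the
# sample's own [min, max]; constant input collapses into bin 1.
discretize_intensities <- function(x, levels) {
  mn <- min(x)
  mx <- max(x)
  if (mx <= mn) return(rep(1L, length(x)))
  pmin(levels, as.integer(floor((x - mn) / (mx - mn) * levels)) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
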