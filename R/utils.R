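# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL evaluates unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-animal RNG stream: hash (cohort seed, animal index) into
# a 32-bit seed so every animal is reproducible on its own and cohorts are
# reproducible as concatenations.
stream_seed <- function(seed, animal_index) {
  s <- as.double(seed) %% 2147483647
  x <- (s * 48271 + as.double(animal_index) * 1664525 + 1013904223) %% 2147483647
  as.integer(x)
}

clip01 <- function(x) pmin(1, pmax(0, x))

is_count <- function(x) {
  is.numeric(x) & is.finite(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

is_prob <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard error of the mean; NA for a single observation
sem <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
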