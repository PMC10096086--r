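# Seed handling shared by every stochastic stage.
#
# local_rng() seeds R's RNG for the calling function only: the caller's
# random draws are reproducible for a fixed seed, and the user's global RNG
# stream is restored when the caller exits.
local_rng <- function(seed, env = parent.frame()) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  set.seed(seed)
  invisible(seed)
}

# One master seed fans out to per-stage seeds by a fixed, collision-averse
# derivation (kept below 2^31 - 1 so it is always a valid R integer).
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483647)
}

# Column-wise variance without the overhead of apply().
col_vars <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2L) return(rep(NA_real_, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}
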