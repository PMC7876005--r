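# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded generators do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Lognormal multiplicative noise factors with unit mean and a given
# coefficient of variation. cv = 0 returns exact ones.
lognormal_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Moving-average smoother with partial windows at the edges.
moving_average <- function(y, window = 3L) {
  n <- length(y)
  if (window <= 1L || n < 2L) return(y)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(y[lo:hi])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, e) {
  stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
}
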