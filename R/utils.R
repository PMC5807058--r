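#' @importFrom rlang %||% abort warn .data
#' @importFrom stats qnorm pnorm qbeta rnorm runif rlnorm quantile sd median
#'   cor cov mahalanobis qchisq pchisq qf pf pt optim nlminb complete.cases
#'   rbinom setNames plogis qlogis optimHess
#' @importFrom utils modifyList write.csv read.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Spawn `n` reproducible child seeds from one master seed.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Truncated-normal quantile function (lower truncation only).
qtnorm <- function(p, mean, sd, lower = 0) {
  p0 <- pnorm((lower - mean) / sd)
  qnorm(p0 + p * (1 - p0)) * sd + mean
}

check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}
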