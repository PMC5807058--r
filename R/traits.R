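#' Default cross-trait correlation structure
#'
#' Correlation matrix of the six latent subject traits used by the Gaussian
#' copula in [gen_population()]. The matrix is expressed on the latent
#' (Gaussian) scale, with the metacognition axis oriented as *efficiency*
#' (higher = better confidence calibration, i.e. lower metacognitive noise).
#'
#' Defaults: efficiency correlates +0.29 with control strength (the
#' structural path of interest), +0.15 with detection ability, -0.15 with
#' mind-wandering propensity; control strength correlates -0.15 with
#' mind-wandering propensity. All remaining pairs are 0.
#'
#' @return A symmetric 6 x 6 correlation matrix with dimnames
#'   `mw_propensity`, `detection_ability`, `metacog_efficiency`,
#'   `control_strength`, `base_speed`, `lapse_rate`.
#' @export
#' @examples
#' trait_covariance_default()
trait_covariance_default <- function() {
  nm <- c("mw_propensity", "detection_ability", "metacog_efficiency",
          "control_strength", "base_speed", "lapse_rate")
  R <- diag(6)
  dimnames(R) <- list(nm, nm)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set2("metacog_efficiency", "control_strength", 0.29)
  set2("metacog_efficiency", "detection_ability", 0.15)
  set2("metacog_efficiency", "mw_propensity", -0.15)
  set2("control_strength", "mw_propensity", -0.15)
  R
}

# Marginal trait distributions (native scales). Means are chosen so that
# cohort-level task summaries land near published norms for these paradigms:
# mind-wandering propensity ~ Beta(4, 16) gives ~2/3 off-task occupancy under
# the default Markov chain; metacognitive noise is truncated-normal(0.80,
# 0.30) in evidence-SD units; control strength is the per-subject congruency
# sequence effect in ms, Normal(20, 40).
trait_marginals <- function() {
  list(
    mw_propensity     = function(u) qbeta(u, 4, 16),
    detection_ability = function(u) qbeta(u, 2, 2),
    # noise decreases in the efficiency latent
    metacog_noise     = function(u) qtnorm(1 - u, mean = 0.80, sd = 0.30, lower = 0),
    control_strength  = function(u) qnorm(u, mean = 20, sd = 40),
    base_speed        = function(u) qtnorm(u, mean = 370, sd = 45, lower = 200),
    lapse_rate        = function(u) qbeta(u, 2, 98)
  )
}

#' Generate a synthetic subject population
#'
#' Draws per-subject latent traits from a Gaussian copula with the requested
#' latent correlation structure, then maps each trait to its native scale
#' through a fixed marginal quantile function. The traits drive all three
#' task simulators ([gen_sart_session()], [gen_dot_session()],
#' [gen_conflict_session()]).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param trait_covariance Symmetric positive semi-definite latent
#'   correlation matrix over the six traits; see [trait_covariance_default()].
#' @param seed Integer seed; identical seeds yield identical cohorts.
#' @return A tibble with one row per subject and columns `subject_id`,
#'   `mw_propensity`, `detection_ability`, `metacog_noise`,
#'   `control_strength`, `base_speed`, `lapse_rate`, plus
#'   `metacog_efficiency` (the expected meta-d'/d' ratio implied by the
#'   subject's metacognitive noise, `1/sqrt(1 + sigma_m^2)`). The latent
#'   Gaussian scores are attached as attribute `"latent"` for audit.
#' @export
#' @examples
#' gen_population(5, seed = 1)
gen_population <- function(n_subjects,
                           trait_covariance = trait_covariance_default(),
                           seed) {
  stopifnot(n_subjects >= 1)
  R <- as.matrix(trait_covariance)
  if (!isSymmetric(unname(R), tol = 1e-8)) {
    abort("`trait_covariance` must be symmetric.")
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    abort(sprintf(
      "`trait_covariance` is not positive semi-definite (smallest eigenvalue %.3g).",
      min(ev$values)
    ))
  }
  d <- nrow(R)
  marg <- trait_marginals()
  stopifnot(d == length(marg))
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  Z <- with_seed(seed, matrix(rnorm(n_subjects * d), n_subjects, d) %*% rt)
  colnames(Z) <- colnames(trait_covariance_default())
  U <- pnorm(Z)
  out <- tibble::tibble(
    subject_id        = seq_len(n_subjects),
    mw_propensity     = marg$mw_propensity(U[, 1]),
    detection_ability = marg$detection_ability(U[, 2]),
    metacog_noise     = marg$metacog_noise(U[, 3]),
    control_strength  = marg$control_strength(U[, 4]),
    base_speed        = marg$base_speed(U[, 5]),
    lapse_rate        = marg$lapse_rate(U[, 6])
  )
  out$metacog_efficiency <- 1 / sqrt(1 + out$metacog_noise^2)
  attr(out, "latent") <- Z
  out
}
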