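#' Type-1 signal detection measures
#'
#' Computes d' and the criterion c from a 2x2 table of counts, treating
#' "left is correct" as the signal class by convention: the hit rate is
#' P(choice = left | correct side = left), the false-alarm rate is
#' P(choice = left | correct side = right). Extreme rates (0 or 1) are
#' padded by 1/(2N) of the relevant class so the quantiles stay finite.
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative counts;
#'   each stimulus class needs at least one trial.
#' @return A one-row tibble: `d_prime`, `criterion_c`, `hit_rate`,
#'   `fa_rate`.
#' @export
#' @examples
#' type1_sdt(75, 25, 25, 75)  # d' = 1.349, c = 0
type1_sdt <- function(hits, misses, false_alarms, correct_rejections) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0)) abort("Counts must be non-negative.")
  n_sig <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_sig == 0) abort("Empty signal class: no trials with the signal stimulus.")
  if (n_noise == 0) abort("Empty noise class: no trials with the noise stimulus.")
  pad_rate <- function(k, n) {
    r <- k / n
    if (r == 0) r <- 1 / (2 * n)
    if (r == 1) r <- 1 - 1 / (2 * n)
    r
  }
  H <- pad_rate(hits, n_sig)
  FA <- pad_rate(false_alarms, n_noise)
  tibble::tibble(
    d_prime = qnorm(H) - qnorm(FA),
    criterion_c = -(qnorm(H) + qnorm(FA)) / 2,
    hit_rate = H,
    fa_rate = FA
  )
}

#' Bin continuous confidence ratings into type-2 counts
#'
#' Splits the raw confidence values of a dot-discrimination session into `K`
#' per-subject quantile bins (ties broken toward the lower bin; duplicated
#' quantile edges are collapsed with a warning, reducing `K`). Builds the
#' stimulus x response x confidence-bin count table that enters the meta-d'
#' likelihood, along with the type-1 counts (left-correct as signal).
#'
#' @param session A `dot_session` tibble (columns `correct_side`, `choice`,
#'   `confidence`).
#' @param K Number of confidence bins (default 4, >= 2).
#' @return An object of class `type2_counts`: list with `K`, `edges`,
#'   `counts` (a `stim x resp x bin` array), `type1` (hits, misses,
#'   false_alarms, correct_rejections) and `n_trials`.
#' @export
bin_confidence <- function(session, K = 4) {
  stopifnot(K >= 2)
  conf <- session$confidence
  if (length(unique(conf)) < 2) {
    abort("All confidence ratings are identical; binning is impossible (use fewer bins).")
  }
  if (length(unique(conf)) < K) {
    abort(sprintf("Fewer than K = %d distinct confidence values; use fewer bins.", K))
  }
  edges <- unname(quantile(conf, probs = seq(0, 1, length.out = K + 1), type = 7))
  if (anyDuplicated(signif(edges, 12))) {
    warn("Duplicated quantile edges; collapsing degenerate confidence bins.")
    edges <- unique(signif(edges, 12))
  }
  K_eff <- length(edges) - 1L
  bin <- cut(conf, breaks = edges, include.lowest = TRUE, right = TRUE, labels = FALSE)
  stim <- factor(session$correct_side, levels = c("left", "right"))
  resp <- factor(session$choice, levels = c("left", "right"))
  counts <- table(stim = stim, resp = resp, bin = factor(bin, levels = seq_len(K_eff)))
  counts <- array(as.integer(counts), dim = dim(counts), dimnames = dimnames(counts))
  t1 <- list(
    hits = sum(stim == "left" & resp == "left"),
    misses = sum(stim == "left" & resp == "right"),
    false_alarms = sum(stim == "right" & resp == "left"),
    correct_rejections = sum(stim == "right" & resp == "right")
  )
  structure(
    list(K = K_eff, edges = edges, counts = counts, type1 = t1,
         n_trials = length(conf)),
    class = "type2_counts"
  )
}

# Response-conditional bin probabilities implied by an SDT observer with
# sensitivity meta_d whose type-1 criterion sits at the fixed relative
# position c' = c/d'. Evidence: left-correct ~ N(+meta_d/2, 1), right-correct
# ~ N(-meta_d/2, 1); "left" responses are x > c1. crit_left are the K-1
# type-2 criteria above c1 (increasing), crit_right below c1 (decreasing).
meta_d_cell_probs <- function(meta_d, c_rel, crit_left, crit_right, K) {
  c1 <- c_rel * meta_d
  mu <- c(left = meta_d / 2, right = -meta_d / 2)
  out <- array(NA_real_, dim = c(2, 2, K),
               dimnames = list(stim = c("left", "right"),
                               resp = c("left", "right"), bin = seq_len(K)))
  bl <- c(c1, crit_left, Inf)    # boundaries for "left" responses
  br <- c(c1, crit_right, -Inf)  # boundaries for "right" responses
  for (s in 1:2) {
    p_left <- 1 - pnorm(c1 - mu[s])
    p_right <- pnorm(c1 - mu[s])
    for (k in seq_len(K)) {
      # bin k = k-th lowest confidence; for left responses the evidence
      # interval (bl[k], bl[k+1]] sits just above c1 for low confidence
      out[s, 1, k] <- (pnorm(bl[k + 1] - mu[s]) - pnorm(bl[k] - mu[s])) / p_left
      out[s, 2, k] <- (pnorm(br[k] - mu[s]) - pnorm(br[k + 1] - mu[s])) / p_right
    }
  }
  out
}

meta_d_nll <- function(par, counts, c_rel, K) {
  meta_d <- par[1]
  dl <- exp(par[2:K])
  dr <- exp(par[(K + 1):(2 * K - 1)])
  c1 <- c_rel * meta_d
  crit_left <- c1 + cumsum(dl)
  crit_right <- c1 - cumsum(dr)
  pr <- meta_d_cell_probs(meta_d, c_rel, crit_left, crit_right, K)
  pr <- pmax(pr, 1e-12)
  -sum(counts * log(pr))
}

#' Fit meta-d' by maximum likelihood
#'
#' Fits the metacognitive sensitivity meta-d': the type-1 sensitivity an
#' ideal signal-detection observer would need in order to produce the
#' observed confidence-rating data, with the type-1 criterion held at the
#' empirically fixed relative position c' = c/d'. The multinomial likelihood
#' of the confidence-bin counts, conditional on stimulus and response, is
#' maximized over meta-d' and 2(K-1) monotone type-2 criteria. When any cell
#' count is zero, 1/(2K) is added to every cell (log-linear padding).
#'
#' @param counts A `type2_counts` object from [bin_confidence()].
#' @param on_nonconvergence `"warn"` (default) records a flag; `"error"`
#'   aborts with the best objective value.
#' @return An object of class `metacog_result`: list with `d_prime`,
#'   `criterion_c`, `meta_d`, `ratio` (meta-d'/d', `NA` unless d' > 0),
#'   `type2_criteria` (named list `left`, `right`), `log_likelihood`,
#'   `n_trials`, `K`, `converged`.
#' @export
fit_meta_d <- function(counts, on_nonconvergence = c("warn", "error")) {
  stopifnot(inherits(counts, "type2_counts"))
  on_nonconvergence <- match.arg(on_nonconvergence)
  t1 <- type1_sdt(counts$type1$hits, counts$type1$misses,
                  counts$type1$false_alarms, counts$type1$correct_rejections)
  d1 <- t1$d_prime
  c1 <- t1$criterion_c
  c_rel <- if (abs(d1) > 1e-10) c1 / d1 else 0
  K <- counts$K
  obs <- counts$counts
  if (any(obs == 0)) obs <- obs + 1 / (2 * K)

  start <- c(d1, rep(log(0.5), 2 * (K - 1)))
  fit <- nlminb(start, meta_d_nll, counts = obs, c_rel = c_rel, K = K,
                lower = c(-10, rep(-8, 2 * (K - 1))),
                upper = c(10, rep(3, 2 * (K - 1))),
                control = list(rel.tol = 1e-10, abs.tol = 1e-12, iter.max = 500))
  converged <- fit$convergence == 0
  if (!converged && on_nonconvergence == "error") {
    abort(sprintf("meta-d' fit did not converge (objective %.6f, message: %s).",
                  fit$objective, fit$message))
  }
  if (!converged) warn(sprintf("meta-d' fit flagged non-convergence: %s", fit$message))
  meta_d <- fit$par[1]
  mc1 <- c_rel * meta_d
  crit_left <- mc1 + cumsum(exp(fit$par[2:K]))
  crit_right <- mc1 - cumsum(exp(fit$par[(K + 1):(2 * K - 1)]))
  structure(
    list(
      d_prime = d1,
      criterion_c = c1,
      meta_d = meta_d,
      ratio = if (d1 > 0) meta_d / d1 else NA_real_,
      type2_criteria = list(left = crit_left, right = crit_right),
      log_likelihood = -fit$objective,
      n_trials = counts$n_trials,
      K = K,
      converged = converged
    ),
    class = "metacog_result"
  )
}

#' Metacognitive efficiency (meta-d'/d')
#'
#' A ratio of 1 means all first-order evidence is used when rating
#' confidence; below 1 the confidence judgment is metacognitively
#' inefficient; above 1 more information enters the confidence judgment
#' than the primary choice (e.g. continued post-decisional accumulation).
#' Undefined (NA) when d' <= 0.
#'
#' @param result A `metacog_result` from [fit_meta_d()].
#' @return A single numeric ratio, `NA` if d' <= 0.
#' @export
metacog_efficiency <- function(result) {
  stopifnot(inherits(result, "metacog_result"))
  if (!is.finite(result$d_prime) || result$d_prime <= 0) return(NA_real_)
  result$meta_d / result$d_prime
}
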