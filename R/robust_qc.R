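#' Squared robust Mahalanobis distances
#'
#' Distances from a minimum-covariance-determinant (MCD) location/scatter
#' estimate (via [MASS::cov.rob()]), rescaled for consistency so that the
#' median squared distance matches the chi-square median, `qchisq(0.5, p)`.
#' The MCD subset search is run under a fixed internal seed, so results are
#' deterministic.
#'
#' @param X A numeric matrix/data frame (subjects x variables), no missing
#'   values, with more than `2 * ncol` rows.
#' @param seed Seed for the subset search (default 0).
#' @return Numeric vector of squared robust distances, with attributes
#'   `center` and `cov` (the rescaled robust scatter).
#' @export
robust_distances <- function(X, seed = 0) {
  X <- as.matrix(X)
  if (anyNA(X)) abort("`X` must not contain missing values.")
  n <- nrow(X); p <- ncol(X)
  if (n <= 2 * p) abort(sprintf("Need more than 2 * %d rows; got %d.", p, n))
  qr_rank <- qr(scale(X, scale = FALSE))$rank
  if (qr_rank < p) {
    cc <- cor(X)
    bad <- which(abs(cc) > 1 - 1e-10 & row(cc) < col(cc), arr.ind = TRUE)
    cols <- if (nrow(bad)) {
      paste(colnames(X)[bad[, 1]], colnames(X)[bad[, 2]], sep = " ~ ", collapse = "; ")
    } else "unknown"
    abort(paste0("Singular robust scatter: collinear columns (", cols, ")."))
  }
  fit <- with_seed(seed, MASS::cov.rob(X, method = "mcd"))
  d2 <- mahalanobis(X, fit$center, fit$cov)
  cf <- median(d2) / qchisq(0.5, p)
  d2 <- d2 / cf
  structure(d2, center = fit$center, cov = fit$cov * cf)
}

#' Adjusted-quantile multivariate outlier flags
#'
#' Flags observations whose squared robust distance exceeds an adaptive
#' cutoff: the larger of the chi-square quantile `qchisq(chisq_quantile, p)`
#' and an adjusted quantile placed where the empirical tail of the distance
#' distribution departs from the chi-square reference by more than a
#' critical deviation (an adaptive-reweighting rule in the style of the
#' mvoutlier adjusted quantile plot; the critical deviation is
#' `(0.24 - 0.003 p) / sqrt(n)` for `p <= 10`, scaled by `alpha / 0.05`,
#' and the tail comparison starts at `qchisq(1 - delta, p)`).
#'
#' Outliers are reported, not removed: downstream model fitting keeps all
#' subjects.
#'
#' @param distances Squared robust distances (e.g. [robust_distances()]).
#' @param p Number of variables the distances were computed from.
#' @param chisq_quantile Floor quantile for the cutoff (default .975).
#' @param delta Tail start probability (default .05).
#' @param alpha Scale of the critical deviation (default .05).
#' @return An object of class `outlier_report`: list with `distances`,
#'   `threshold`, `flags`, `n_outliers` and `params`.
#' @export
adjusted_quantile_flags <- function(distances, p, chisq_quantile = 0.975,
                                    delta = 0.05, alpha = 0.05) {
  d2 <- as.numeric(distances)
  n <- length(d2)
  if (n < 10) abort("Need at least 10 distances.")
  check_scalar_prob(chisq_quantile, "chisq_quantile")
  floor_q <- qchisq(chisq_quantile, p)
  tail_start <- qchisq(1 - delta, p)
  ord <- sort(d2)
  ecdf_mid <- (seq_len(n) - 0.5) / n
  in_tail <- ord >= tail_start
  dev <- pchisq(ord, p) - ecdf_mid
  a_n <- if (any(in_tail)) max(c(dev[in_tail], 0)) else 0
  pcrit <- if (p <= 10) (0.24 - 0.003 * p) / sqrt(n) else (0.252 - 0.0018 * p) / sqrt(n)
  pcrit <- pcrit * (alpha / 0.05)
  threshold <- floor_q
  if (a_n > pcrit) {
    adaptive <- ord[max(1L, n - ceiling(n * a_n))]
    threshold <- max(floor_q, adaptive)
  }
  flags <- d2 > threshold
  structure(
    list(distances = d2, threshold = threshold, flags = flags,
         n_outliers = sum(flags),
         params = list(chisq_quantile = chisq_quantile, delta = delta,
                       alpha = alpha, p = p, pcrit = pcrit,
                       tail_deviation = a_n)),
    class = "outlier_report"
  )
}

#' Flag multivariate outliers in a subject-level table
#'
#' Convenience wrapper: robust distances on the selected columns, then
#' adjusted-quantile flags. Rows with missing values are excluded from the
#' computation and flagged `NA`.
#'
#' @param data A data frame.
#' @param vars Character vector of numeric columns to use.
#' @param seed Seed for the MCD subset search.
#' @param ... Passed to [adjusted_quantile_flags()].
#' @return The `outlier_report`, with an extra `row_flags` element aligned
#'   with `data` rows.
#' @export
flag_outliers <- function(data, vars, seed = 0, ...) {
  X <- as.data.frame(data)[, vars, drop = FALSE]
  ok <- complete.cases(X)
  d2 <- robust_distances(as.matrix(X[ok, ]), seed = seed)
  rep <- adjusted_quantile_flags(d2, p = length(vars), ...)
  row_flags <- rep(NA, nrow(X))
  row_flags[ok] <- rep$flags
  rep$row_flags <- row_flags
  rep
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Robust outlier report: %d of %d flagged (threshold %.2f, chi-square floor %.2f)\n",
              x$n_outliers, length(x$distances), x$threshold,
              qchisq(x$params$chisq_quantile, x$params$p)))
  invisible(x)
}
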