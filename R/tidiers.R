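#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a mind-wandering factor model
#'
#' @param x A `mw_factor_model`.
#' @param ... Unused.
#' @return A tibble with one row per indicator: `indicator`, `loading`,
#'   `mean`, `sd`.
#' @method tidy mw_factor_model
#' @export
tidy.mw_factor_model <- function(x, ...) {
  tibble::tibble(indicator = names(x$loadings), loading = unname(x$loadings),
                 mean = unname(x$center), sd = unname(x$scale))
}

#' @rdname tidy.mw_factor_model
#' @method glance mw_factor_model
#' @export
glance.mw_factor_model <- function(x, ...) {
  tibble::tibble(n = x$n, prop_variance = x$eigenvalues[1] / length(x$loadings))
}

#' Tidy a meta-d' fit
#'
#' @param x A `metacog_result`.
#' @param ... Unused.
#' @return `tidy()`: one row per fitted quantity; `glance()`: a one-row
#'   model summary.
#' @method tidy metacog_result
#' @export
tidy.metacog_result <- function(x, ...) {
  tibble::tibble(
    term = c("d_prime", "criterion_c", "meta_d", "ratio",
             paste0("crit_left_", seq_along(x$type2_criteria$left)),
             paste0("crit_right_", seq_along(x$type2_criteria$right))),
    estimate = c(x$d_prime, x$criterion_c, x$meta_d, x$ratio,
                 x$type2_criteria$left, x$type2_criteria$right)
  )
}

#' @rdname tidy.metacog_result
#' @method glance metacog_result
#' @export
glance.metacog_result <- function(x, ...) {
  tibble::tibble(d_prime = x$d_prime, meta_d = x$meta_d, ratio = x$ratio,
                 log_likelihood = x$log_likelihood, n_trials = x$n_trials,
                 K = x$K, converged = x$converged)
}

#' Tidy a fitted path model
#'
#' @param x A `sem_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per free parameter with `term`, `estimate`,
#'   `std_estimate`, `se` (sandwich), `se_naive`, `z`, `p_value`;
#'   `glance()`: fit statistics.
#' @method tidy sem_fit
#' @export
tidy.sem_fit <- function(x, ...) {
  z <- x$theta / x$se
  tibble::tibble(
    term = names(x$theta),
    estimate = unname(x$theta),
    std_estimate = unname(x$standardized),
    se = unname(x$se),
    se_naive = unname(x$se_naive),
    z = unname(z),
    p_value = 2 * pnorm(abs(unname(z)), lower.tail = FALSE)
  )
}

#' @rdname tidy.sem_fit
#' @method glance sem_fit
#' @export
glance.sem_fit <- function(x, ...) {
  tibble::tibble(chi_sq = x$chi_sq, df = x$df, p_value = x$p_value,
                 cfi = x$cfi, rmsea = x$rmsea,
                 baseline_chi_sq = x$baseline_chi_sq,
                 baseline_df = x$baseline_df, n = x$n,
                 n_free = x$n_free, converged = x$converged,
                 heywood = x$heywood)
}

#' Tidy an outlier report
#'
#' @param x An `outlier_report`.
#' @param ... Unused.
#' @return `tidy()`: one row per observation with its squared robust
#'   distance and flag; `glance()`: the threshold and counts.
#' @method tidy outlier_report
#' @export
tidy.outlier_report <- function(x, ...) {
  tibble::tibble(row = seq_along(x$distances), distance = x$distances,
                 outlier = x$flags)
}

#' @rdname tidy.outlier_report
#' @method glance outlier_report
#' @export
glance.outlier_report <- function(x, ...) {
  tibble::tibble(n = length(x$distances), n_outliers = x$n_outliers,
                 threshold = x$threshold,
                 chisq_floor = qchisq(x$params$chisq_quantile, x$params$p))
}
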