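#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_col geom_errorbar labs facet_wrap theme_minimal position_dodge
#'   geom_pointrange scale_color_manual stat_function coord_flip
NULL

#' @export
ggplot2::autoplot

#' Staircase trajectory of a dot-discrimination session
#'
#' @param object A `dot_session`.
#' @param ... Unused.
#' @return A ggplot: dot difference over trials, colored by correctness.
#' @method autoplot dot_session
#' @export
autoplot.dot_session <- function(object, ...) {
  ggplot(object, aes(x = .data$trial, y = .data$delta)) +
    geom_line(color = "grey60") +
    geom_point(aes(color = .data$correct), size = 0.8) +
    scale_color_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f02")) +
    labs(x = "Trial", y = "Dot difference (dots)", color = "Correct",
         title = "Weighted up-down staircase trajectory") +
    theme_minimal()
}

#' Condition-cell plot of the conflict task
#'
#' Means (across subjects) of the per-subject median RTs and error rates by
#' congruency and previous congruency: the classic factorial plot in which
#' converging lines indicate a congruency sequence (Gratton) effect.
#'
#' @param cells Output of [cell_medians()].
#' @return A ggplot.
#' @export
plot_conflict_cells <- function(cells) {
  summ <- cells |>
    tidyr::pivot_longer(c("median_rt", "error_rate"),
                        names_to = "measure", values_to = "value") |>
    dplyr::group_by(.data$measure, .data$prev_congruency, .data$congruency) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     se = sd(.data$value, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$value))),
                     .groups = "drop") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
                                          median_rt = "Median RT (ms)",
                                          error_rate = "Error rate (%)"))
  ggplot(summ, aes(x = .data$prev_congruency, y = .data$mean,
                   group = .data$congruency, color = .data$congruency)) +
    geom_line(position = position_dodge(0.1)) +
    geom_pointrange(aes(ymin = .data$mean - 1.96 * .data$se,
                        ymax = .data$mean + 1.96 * .data$se),
                    position = position_dodge(0.1)) +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = "Previous trial", y = NULL, color = "Current trial") +
    theme_minimal()
}

#' Loadings of the behavioral mind-wandering factor
#'
#' @param object A `mw_factor_model`.
#' @param ... Unused.
#' @return A ggplot bar chart of the (unit-normalized) loadings.
#' @method autoplot mw_factor_model
#' @export
autoplot.mw_factor_model <- function(object, ...) {
  df <- tidy.mw_factor_model(object)
  ggplot(df, aes(x = .data$indicator, y = .data$loading)) +
    geom_col(fill = "#2c7fb8") +
    geom_hline(yintercept = 0) +
    coord_flip() +
    labs(x = NULL, y = "Loading",
         title = "Behavioral mind-wandering factor") +
    theme_minimal()
}

#' Standardized estimates of a fitted path model
#'
#' @param object A `sem_fit`.
#' @param ... Unused.
#' @return A ggplot dot-and-whisker plot of the standardized loadings,
#'   paths and covariances with +/- 1.96 sandwich-SE whiskers (on the
#'   unstandardized scale the whiskers are omitted; here the standardized
#'   estimate is shown with the z-based interval transferred through the
#'   ratio of standardized to raw estimates).
#' @method autoplot sem_fit
#' @export
autoplot.sem_fit <- function(object, ...) {
  df <- tidy.sem_fit(object)
  df <- df[grepl("=~|~", df$term) & !grepl("~~", df$term) |
             grepl("~~", df$term) & !vapply(strsplit(df$term, " ~~ "),
                                            function(p) p[1] == p[2], logical(1)), ]
  scale_ratio <- ifelse(df$estimate == 0, 1, df$std_estimate / df$estimate)
  df$lo <- df$std_estimate - 1.96 * df$se * abs(scale_ratio)
  df$hi <- df$std_estimate + 1.96 * df$se * abs(scale_ratio)
  ggplot(df, aes(x = stats::reorder(.data$term, .data$std_estimate),
                 y = .data$std_estimate)) +
    geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    geom_pointrange(aes(ymin = .data$lo, ymax = .data$hi)) +
    coord_flip() +
    labs(x = NULL, y = "Standardized estimate") +
    theme_minimal()
}

#' Distance plot of a robust outlier report
#'
#' Ordered squared robust distances against chi-square plotting positions
#' with the adaptive threshold.
#'
#' @param object An `outlier_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot outlier_report
#' @export
autoplot.outlier_report <- function(object, ...) {
  n <- length(object$distances)
  df <- tibble::tibble(
    theoretical = qchisq((seq_len(n) - 0.5) / n, object$params$p),
    distance = sort(object$distances)
  )
  ggplot(df, aes(x = .data$theoretical, y = .data$distance)) +
    geom_point(size = 0.9) +
    geom_hline(yintercept = object$threshold, color = "#d95f02", linetype = 2) +
    labs(x = "Chi-square quantile", y = "Squared robust distance",
         title = sprintf("%d of %d flagged", object$n_outliers, n)) +
    theme_minimal()
}
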