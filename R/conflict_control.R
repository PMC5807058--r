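#' Apply the conflict-task trial exclusions
#'
#' Flags, in order: the first trial of each block, error trials, and trials
#' immediately following an error (the post-error rule does not spill over
#' block boundaries). The RT analysis uses trials passing all three rules;
#' the error-rate analysis retains error trials but drops first-of-block and
#' post-error trials. The operation is idempotent: re-applying it changes
#' nothing.
#'
#' @param session A `conflict_session` tibble (possibly several subjects).
#' @return The input with added columns `removed_by` (`"first_of_block"`,
#'   `"error"`, `"post_error"` or `NA`), `keep_rt` and `keep_error`.
#' @export
apply_exclusions <- function(session) {
  df <- dplyr::as_tibble(session)
  df$removed_by <- NULL; df$keep_rt <- NULL; df$keep_error <- NULL
  df |>
    dplyr::group_by(.data$subject_id, .data$block) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(
      first_of_block = dplyr::row_number() == 1L,
      post_error = dplyr::lag(!.data$correct, default = FALSE),
      removed_by = dplyr::case_when(
        first_of_block ~ "first_of_block",
        !.data$correct ~ "error",
        post_error ~ "post_error",
        TRUE ~ NA_character_
      ),
      keep_rt = !.data$first_of_block & .data$correct & !.data$post_error,
      keep_error = !.data$first_of_block & !.data$post_error
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"first_of_block", -"post_error") |>
    dplyr::arrange(.data$subject_id, .data$trial)
}

#' Per-subject condition-cell summaries
#'
#' Median correct RT and mean error rate per (previous congruency x
#' congruency) cell, after the exclusions of [apply_exclusions()] (applied
#' here if the flags are absent). Previous congruency is read from the
#' immediately preceding presented trial, whether or not that trial was
#' itself excluded. Even-sized cells use the mean-of-middle median
#' convention (`stats::median`).
#'
#' @param session A (possibly flagged) `conflict_session` tibble.
#' @return A tibble with one row per subject x cell: `subject_id`,
#'   `prev_congruency`, `congruency`, `median_rt`, `error_rate` (percent),
#'   `n_rt`, `n_error`, and `flag` (non-empty when a cell is empty).
#' @export
cell_medians <- function(session) {
  df <- dplyr::as_tibble(session)
  if (!all(c("keep_rt", "keep_error") %in% names(df))) df <- apply_exclusions(df)
  df <- df[df$prev_congruency %in% c("congruent", "incongruent"), ]
  cells <- df |>
    dplyr::group_by(.data$subject_id, .data$prev_congruency, .data$congruency) |>
    dplyr::summarise(
      median_rt = median(.data$rt_ms[.data$keep_rt]),
      error_rate = 100 * mean(!.data$correct[.data$keep_error]),
      n_rt = sum(.data$keep_rt),
      n_error = sum(.data$keep_error),
      .groups = "drop"
    ) |>
    tidyr::complete(
      subject_id,
      prev_congruency = c("congruent", "incongruent"),
      congruency = c("congruent", "incongruent")
    ) |>
    dplyr::mutate(flag = dplyr::if_else(
      is.na(.data$median_rt) | .data$n_rt == 0 | is.na(.data$n_rt),
      "empty_cell", ""
    ))
  cells
}

#' Gratton (congruency sequence) index per subject
#'
#' The RT congruency effect after congruent trials minus the one after
#' incongruent trials, and the analogous error-rate contrast.
#'
#' @param cells Output of [cell_medians()].
#' @return A tibble per subject: `ce_after_congruent`, `ce_after_incongruent`
#'   (ms), `gratton` (their difference, ms), `error_ce_after_congruent`,
#'   `error_ce_after_incongruent`, `error_gratton` (percentage points).
#' @export
gratton_index <- function(cells) {
  wide <- cells |>
    dplyr::mutate(cell = paste(substr(.data$prev_congruency, 1, 1),
                               substr(.data$congruency, 1, 1), sep = "_")) |>
    dplyr::select("subject_id", "cell", "median_rt", "error_rate") |>
    tidyr::pivot_wider(names_from = "cell",
                       values_from = c("median_rt", "error_rate"))
  tibble::tibble(
    subject_id = wide$subject_id,
    ce_after_congruent = wide$median_rt_c_i - wide$median_rt_c_c,
    ce_after_incongruent = wide$median_rt_i_i - wide$median_rt_i_c,
    gratton = (wide$median_rt_c_i - wide$median_rt_c_c) -
      (wide$median_rt_i_i - wide$median_rt_i_c),
    error_ce_after_congruent = wide$error_rate_c_i - wide$error_rate_c_c,
    error_ce_after_incongruent = wide$error_rate_i_i - wide$error_rate_i_c,
    error_gratton = (wide$error_rate_c_i - wide$error_rate_c_c) -
      (wide$error_rate_i_i - wide$error_rate_i_c)
  )
}

#' 2 x 2 within-subject repeated-measures ANOVA
#'
#' Standard within-subject decomposition for a congruency x previous
#' congruency design with one observation per subject and cell: each effect
#' is tested against its effect-by-subject interaction, with df (1, n - 1),
#' and partial eta squared is SS_effect / (SS_effect + SS_error). Subjects
#' with incomplete cells are dropped with a warning.
#'
#' @param cells Output of [cell_medians()].
#' @param dv Which cell measure to analyse: `"median_rt"` or `"error_rate"`.
#' @return A tibble with rows `congruency`, `prev_congruency`,
#'   `congruency:prev_congruency` and columns `effect`, `F`, `df1`, `df2`,
#'   `p`, `partial_eta_sq`, `n`.
#' @export
rm_anova_2x2 <- function(cells, dv = c("median_rt", "error_rate")) {
  dv <- match.arg(dv)
  wide <- cells |>
    dplyr::select("subject_id", "prev_congruency", "congruency",
                  value = dplyr::all_of(dv)) |>
    tidyr::pivot_wider(names_from = c("prev_congruency", "congruency"),
                       values_from = "value")
  need <- c("congruent_congruent", "congruent_incongruent",
            "incongruent_congruent", "incongruent_incongruent")
  if (!all(need %in% names(wide))) abort("All four condition cells are required.")
  ok <- complete.cases(wide[, need])
  if (any(!ok)) {
    warn(sprintf("Dropping %d subject(s) with incomplete cells.", sum(!ok)))
  }
  Y <- as.matrix(wide[ok, need])
  n <- nrow(Y)
  if (n < 3) abort("Need at least 3 subjects with complete cells.")
  # factor coding: columns are (prevC, C), (prevC, I), (prevI, C), (prevI, I)
  a <- c(1, 1, 2, 2)  # prev_congruency level per column
  b <- c(1, 2, 1, 2)  # congruency level per column
  grand <- mean(Y)
  m_subj <- rowMeans(Y)
  m_a <- vapply(1:2, function(l) mean(Y[, a == l]), numeric(1))
  m_b <- vapply(1:2, function(l) mean(Y[, b == l]), numeric(1))
  m_ab <- matrix(colMeans(Y)[order(a * 10 + b)], 2, 2, byrow = TRUE)
  m_ia <- vapply(1:2, function(l) rowMeans(Y[, a == l, drop = FALSE]), numeric(n))
  m_ib <- vapply(1:2, function(l) rowMeans(Y[, b == l, drop = FALSE]), numeric(n))

  ss_a <- 2 * n * sum((m_a - grand)^2)
  ss_b <- 2 * n * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a - grand, m_b - grand, `+`) - grand)^2)
  ss_as <- 2 * sum((m_ia - matrix(m_subj, n, 2) -
                      matrix(m_a, n, 2, byrow = TRUE) + grand)^2)
  ss_bs <- 2 * sum((m_ib - matrix(m_subj, n, 2) -
                      matrix(m_b, n, 2, byrow = TRUE) + grand)^2)
  resid <- Y
  for (j in seq_len(ncol(Y))) {
    resid[, j] <- Y[, j] - m_ia[, a[j]] - m_ib[, b[j]] + m_subj -
      m_ab[a[j], b[j]] + m_a[a[j]] + m_b[b[j]] - grand
  }
  ss_abs <- sum(resid^2)

  one <- function(effect, ss_eff, ss_err) {
    if (ss_eff < 1e-12) {
      return(tibble::tibble(effect = effect, F = 0, df1 = 1L, df2 = n - 1L,
                            p = 1, partial_eta_sq = 0, n = n))
    }
    Fv <- (ss_eff / 1) / (ss_err / (n - 1))
    tibble::tibble(effect = effect, F = Fv, df1 = 1L, df2 = n - 1L,
                   p = pf(Fv, 1, n - 1, lower.tail = FALSE),
                   partial_eta_sq = ss_eff / (ss_eff + ss_err), n = n)
  }
  dplyr::bind_rows(
    one("prev_congruency", ss_a, ss_as),
    one("congruency", ss_b, ss_bs),
    one("congruency:prev_congruency", ss_ab, ss_abs)
  )
}
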