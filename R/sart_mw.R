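#' Behavioral mind-wandering indicators
#'
#' Computes the four behavioral markers of mind wandering from a set of SART
#' trials: the percentage of No-Go trials with a response (commissions), the
#' percentage of Go trials without a response (omissions), the standard
#' deviation of RTs on responded Go trials, and the percentage of Go trials
#' with anticipatory RTs (< 100 ms). Components that cannot be computed
#' (e.g. no No-Go trials in the pool) are returned as `NA` and named in the
#' `flags` column rather than silently zeroed.
#'
#' @param trials A tibble of SART trials (columns `is_target`, `responded`,
#'   `rt_ms`), e.g. `gen_sart_session(...)$trials` or a pooled subset.
#' @return A one-row tibble: `nogo_fail_pct`, `go_fail_pct`,
#'   `rt_variability`, `anticipation_pct`, `n_go`, `n_nogo`, `flags`
#'   (comma-separated names of undefined components, `""` if none).
#' @export
compute_indicators <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0L) {
    abort("`trials` is empty: no SART trials to compute indicators from.")
  }
  go <- trials[!trials$is_target, ]
  nogo <- trials[trials$is_target, ]
  flags <- character(0)

  nogo_fail <- if (nrow(nogo) > 0) 100 * mean(nogo$responded) else {
    flags <- c(flags, "nogo_fail_pct"); NA_real_
  }
  if (nrow(go) > 0) {
    go_fail <- 100 * mean(!go$responded)
    anticipation <- 100 * sum(go$responded & go$rt_ms < 100) / nrow(go)
  } else {
    flags <- c(flags, "go_fail_pct", "anticipation_pct")
    go_fail <- anticipation <- NA_real_
  }
  rts <- go$rt_ms[go$responded]
  rt_var <- if (length(rts) >= 2) sd(rts) else {
    flags <- c(flags, "rt_variability"); NA_real_
  }
  tibble::tibble(
    nogo_fail_pct = nogo_fail,
    go_fail_pct = go_fail,
    rt_variability = rt_var,
    anticipation_pct = anticipation,
    n_go = nrow(go),
    n_nogo = nrow(nogo),
    flags = paste(flags, collapse = ",")
  )
}

indicator_cols <- c("nogo_fail_pct", "go_fail_pct", "rt_variability", "anticipation_pct")

#' Extract the latent behavioral mind-wandering factor
#'
#' Standardizes the four indicators and takes the first principal axis of
#' their correlation matrix as the loading vector of a single latent factor.
#' Loadings are unit-normalized and oriented so that the anticipation
#' indicator loads positively (higher score = more mind wandering). Scores
#' are the standardized data projected on the loadings.
#'
#' @param indicator_matrix A subjects x 4 matrix/data frame with columns
#'   `nogo_fail_pct`, `go_fail_pct`, `rt_variability`, `anticipation_pct`
#'   (>= 5 complete rows).
#' @return An object of class `mw_factor_model`: list with `loadings`,
#'   `center`, `scale`, `scores` (for the training rows) and `n`.
#' @export
extract_mw_factor <- function(indicator_matrix) {
  X <- as.matrix(as.data.frame(indicator_matrix)[, indicator_cols])
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 5) abort("Need at least 5 complete indicator rows to extract a factor.")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant indicator column(s): ",
                 paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr, scale = sds)
  R <- cor(X)
  e <- eigen(R, symmetric = TRUE)
  v <- e$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  if (v[match("anticipation_pct", colnames(X))] < 0) v <- -v
  names(v) <- colnames(X)
  structure(
    list(loadings = v, center = ctr, scale = sds,
         scores = as.numeric(Z %*% v), n = nrow(X),
         eigenvalues = e$values),
    class = "mw_factor_model"
  )
}

#' Score indicator vectors through a fitted mind-wandering factor model
#'
#' @param object A `mw_factor_model`.
#' @param newdata A data frame with the four indicator columns.
#' @param ... Unused.
#' @return Numeric factor scores (NA where any indicator is missing).
#' @export
predict.mw_factor_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, indicator_cols])
  Z <- scale(X, center = object$center, scale = object$scale)
  as.numeric(Z %*% object$loadings)
}

#' Label the trial segments preceding subjective reports
#'
#' For each report, the `k` trials immediately preceding it form a segment
#' (truncated at the session start). In probe mode the segment is labelled
#' `on_task` when the probe was answered "focused" and `off_task` otherwise
#' (the three off-task options are not differentiated). In self-caught mode
#' every report segment is `off_task` and all remaining trials form the
#' `on_task` pool. A trial never appears in two report segments: overlapping
#' trials are assigned to the nearer report (earlier report on ties).
#'
#' @param session A `sart_session`.
#' @param k Segment length in trials (default 4).
#' @param exclude_aware If `TRUE`, segments preceding "aware mind wandering"
#'   probe answers are dropped (robustness variant).
#' @return A tibble with one row per labelled trial: `trial`, `report_id`
#'   (NA for the self-mode on-task pool), `kind`, `label`.
#' @export
segment_preceding_reports <- function(session, k = 4, exclude_aware = FALSE) {
  stopifnot(inherits(session, "sart_session"), k >= 1)
  reports <- session$reports
  trials <- session$trials
  mode <- session$config$mode
  if (nrow(reports) == 0L) {
    return(tibble::tibble(trial = integer(0), report_id = integer(0),
                          kind = character(0), label = character(0)))
  }
  reports$report_id <- seq_len(nrow(reports))
  if (mode == "probe") {
    reports$label <- ifelse(reports$option == "focused", "on_task", "off_task")
    if (exclude_aware) reports <- reports[reports$option != "aware_mw", ]
  } else {
    reports$label <- "off_task"
  }
  seg <- purrr::pmap_dfr(
    reports[, c("report_id", "after_trial", "kind", "label")],
    function(report_id, after_trial, kind, label) {
      lo <- max(0L, after_trial - k)
      if (after_trial - 1L < lo) return(NULL)
      tibble::tibble(trial = seq(lo, after_trial - 1L), report_id = report_id,
                     kind = kind, label = label, after_trial = after_trial)
    }
  )
  # overlap resolution: each trial belongs to the nearest report
  if (nrow(seg)) {
    seg <- seg |>
      dplyr::mutate(dist = .data$after_trial - .data$trial) |>
      dplyr::arrange(.data$trial, .data$dist, .data$report_id) |>
      dplyr::distinct(.data$trial, .keep_all = TRUE) |>
      dplyr::select(-"dist", -"after_trial")
  }
  if (mode == "self") {
    rest <- setdiff(trials$trial, seg$trial)
    seg <- dplyr::bind_rows(
      seg,
      tibble::tibble(trial = rest, report_id = NA_integer_,
                     kind = NA_character_, label = "on_task")
    )
  }
  dplyr::arrange(seg, .data$trial)
}

#' Subjective mind-wandering detection index
#'
#' Pools the trials of a subject's off-task report segments and on-task
#' material (see [segment_preceding_reports()]), computes the behavioral
#' indicators on each pool, scores both through a group-level factor model,
#' and returns the difference off - on. Large positive values mean the
#' subject's reports track their behavioral mind wandering.
#'
#' @param session A `sart_session`.
#' @param model A fitted `mw_factor_model` (group level).
#' @param k Segment length (default 4).
#' @param exclude_aware Passed to [segment_preceding_reports()].
#' @return A one-row tibble: `subject_id`, `off_factor`, `on_factor`,
#'   `index`, `n_off_segments`, `n_on_segments`, `flags` (`""` when the
#'   index is defined).
#' @export
detection_index <- function(session, model, k = 4, exclude_aware = FALSE) {
  stopifnot(inherits(model, "mw_factor_model"))
  seg <- segment_preceding_reports(session, k = k, exclude_aware = exclude_aware)
  trials <- session$trials
  sid <- trials$subject_id[1] %||% NA_integer_
  pools <- list(
    off = trials[trials$trial %in% seg$trial[seg$label == "off_task"], ],
    on  = trials[trials$trial %in% seg$trial[seg$label == "on_task"], ]
  )
  n_off <- length(unique(seg$report_id[seg$label == "off_task"]))
  n_on <- if (session$config$mode == "probe") {
    length(unique(seg$report_id[seg$label == "on_task"]))
  } else {
    1L * (nrow(pools$on) > 0)
  }
  flags <- character(0)
  score <- function(pool, which) {
    if (nrow(pool) == 0L) {
      flags <<- c(flags, paste0("empty_", which, "_pool"))
      return(NA_real_)
    }
    ind <- compute_indicators(pool)
    if (nzchar(ind$flags)) {
      flags <<- c(flags, paste0(which, ":", ind$flags))
      return(NA_real_)
    }
    predict(model, ind)
  }
  off <- score(pools$off, "off")
  on <- score(pools$on, "on")
  tibble::tibble(
    subject_id = sid,
    off_factor = off,
    on_factor = on,
    index = off - on,
    n_off_segments = n_off,
    n_on_segments = n_on,
    flags = paste(flags, collapse = ",")
  )
}
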