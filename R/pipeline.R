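#' Pipeline run configuration
#'
#' Collects every knob of the simulation-plus-analysis pipeline with the
#' study defaults: 63 subjects, 225-trial probe-caught and 2 x 120-trial
#' self-caught SART versions, 200 dot-discrimination trials, 160 conflict
#' trials, 4 confidence bins, 4-trial report segments, and the adjusted
#' quantile outlier parameters (.975, .05, .05).
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed; all per-subject, per-task seeds derive from it.
#' @param dot_trials Dot-task trials per subject.
#' @param confidence_bins Number of confidence bins `K`.
#' @param segment_len Pre-report segment length `k`.
#' @param outlier List of adjusted-quantile parameters.
#' @param trait_covariance Latent trait correlation matrix.
#' @param out_dir Optional output directory for the CSV/JSON artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 63, seed = 1, dot_trials = 200,
                       confidence_bins = 4, segment_len = 4,
                       outlier = list(chisq_quantile = 0.975, delta = 0.05, alpha = 0.05),
                       trait_covariance = trait_covariance_default(),
                       out_dir = NULL) {
  stopifnot(n_subjects >= 1, dot_trials >= 1, confidence_bins >= 2, segment_len >= 1)
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         dot_trials = as.integer(dot_trials),
         confidence_bins = as.integer(confidence_bins),
         segment_len = as.integer(segment_len), outlier = outlier,
         trait_covariance = trait_covariance, out_dir = out_dir),
    class = "run_config"
  )
}

#' Read / write a run configuration (YAML or JSON)
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param config A `run_config`.
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$trait_covariance <- as.list(as.data.frame(x$trait_covariance))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tc <- do.call(cbind, x$trait_covariance)
  rownames(tc) <- colnames(tc)
  run_config(
    n_subjects = x$n_subjects, seed = x$seed, dot_trials = x$dot_trials,
    confidence_bins = x$confidence_bins, segment_len = x$segment_len,
    outlier = x$outlier, trait_covariance = tc,
    out_dir = x$out_dir
  )
}

# trial-log schemas for the on-disk CSV artifacts (0-based trial indices)
trial_schemas <- list(
  sart_trials = c("subject_id", "trial", "block", "digit", "is_target",
                  "responded", "rt_ms", "latent_state"),
  sart_reports = c("subject_id", "after_trial", "kind", "option"),
  dot_trials = c("subject_id", "trial", "delta", "correct_side", "choice",
                 "correct", "confidence", "rt_ms"),
  conflict_trials = c("subject_id", "trial", "block", "dimension",
                      "congruency", "prev_congruency", "rt_ms", "correct")
)

#' Write / read tidy trial logs
#'
#' RFC-4180 CSV with a mandatory header; doubles are written with a
#' shortest round-trip representation so `read(write(x))` reproduces the
#' table. `kind` selects the expected column schema; a missing column is a
#' named error.
#'
#' @param records A tibble conforming to the schema.
#' @param path Output path.
#' @param kind One of `"sart_trials"`, `"sart_reports"`, `"dot_trials"`,
#'   `"conflict_trials"`.
#' @return `read_trial_csv()` returns a tibble.
#' @export
write_trial_csv <- function(records, path, kind = NULL) {
  if (!is.null(kind)) check_schema(records, kind)
  if (requireNamespace("readr", quietly = TRUE)) {
    readr::write_csv(records, path, na = "")
  } else {
    write.csv(records, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path, kind = NULL) {
  df <- if (requireNamespace("readr", quietly = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(read.csv(path))
  }
  if (!is.null(kind)) check_schema(df, kind)
  df
}

check_schema <- function(df, kind) {
  cols <- trial_schemas[[kind]]
  if (is.null(cols)) abort(sprintf("Unknown trial-log kind '%s'.", kind))
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("Schema mismatch for '%s': missing column(s) %s.",
                  kind, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

#' Sample size for detecting a correlation
#'
#' Smallest n with the requested power for a two-sided test of rho = 0,
#' by the Fisher-z approximation
#' `n = ((z_{1-alpha/2} + z_{power}) / atanh(rho))^2 + 3`, rounded up.
#'
#' @param rho Target correlation (0 < rho < 1).
#' @param alpha Significance level.
#' @param power Desired power (1 - beta).
#' @return Integer sample size.
#' @export
#' @examples
#' sample_size_for_correlation(0.35)  # 62
sample_size_for_correlation <- function(rho, alpha = 0.05, power = 0.80) {
  stopifnot(rho > 0, rho < 1)
  check_scalar_prob(alpha, "alpha"); check_scalar_prob(power, "power")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  n <- (max(z, 0) / atanh(rho))^2 + 3
  max(4L, as.integer(ceiling(n)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          parent = e)
  })
}

#' Run the full simulation-and-analysis pipeline
#'
#' Generates a trait cohort and all task sessions, then computes: the
#' behavioral mind-wandering factor and detection index (probe-caught and
#' self-caught SART versions), meta-d'/d' metacognitive efficiency, the
#' Gratton cognitive-control index with its 2 x 2 ANOVA, robust outlier
#' reports, and the structural path model per SART version. Identical
#' configurations (including the seed) produce identical bundles.
#'
#' @param config A [run_config()].
#' @param keep_sessions Keep all trial-level logs in the returned bundle
#'   (default TRUE; set FALSE to save memory in large cohorts).
#' @return A list of class `pipeline_result` with elements `profiles`,
#'   `sessions`, `mw` (per version), `metacog`, `control`, `outliers`,
#'   `sem`, `subject_tables`, `config`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), keep_sessions = TRUE) {
  stopifnot(inherits(config, "run_config"))
  n <- config$n_subjects
  seeds <- matrix(spawn_seeds(config$seed, 4L * n), nrow = n,
                  dimnames = list(NULL, c("sart_probe", "sart_self", "dot", "conflict")))

  profiles <- run_stage("synth_cohort", gen_population(n, config$trait_covariance, config$seed))

  probe_cfg <- sart_config("probe", segment_len = config$segment_len)
  self_cfg <- sart_config("self", segment_len = config$segment_len)
  sess_probe <- run_stage("synth_cohort", lapply(seq_len(n), function(i)
    gen_sart_session(profiles[i, ], probe_cfg, seeds[i, "sart_probe"])))
  sess_self <- run_stage("synth_cohort", lapply(seq_len(n), function(i)
    gen_sart_session(profiles[i, ], self_cfg, seeds[i, "sart_self"])))
  sess_dot <- run_stage("synth_cohort", lapply(seq_len(n), function(i)
    gen_dot_session(profiles[i, ], config$dot_trials, seeds[i, "dot"])))
  sess_conflict <- run_stage("synth_cohort", dplyr::bind_rows(
    lapply(seq_len(n), function(i) gen_conflict_session(profiles[i, ], seeds[i, "conflict"]))))

  mw <- lapply(list(probe = sess_probe, self = sess_self), function(sessions) {
    run_stage("sart_mw", {
      ind <- dplyr::bind_rows(lapply(sessions, function(s) {
        dplyr::bind_cols(tibble::tibble(subject_id = s$trials$subject_id[1]),
                         compute_indicators(s$trials))
      }))
      model <- extract_mw_factor(ind)
      ind$factor_score <- predict(model, ind)
      det <- dplyr::bind_rows(lapply(sessions, detection_index,
                                     model = model, k = config$segment_len))
      list(indicators = ind, model = model, detection = det)
    })
  })

  metacog <- run_stage("metacog_sdt", dplyr::bind_rows(lapply(sess_dot, function(s) {
    fit <- fit_meta_d(bin_confidence(s, config$confidence_bins))
    tibble::tibble(subject_id = s$subject_id[1], d_prime = fit$d_prime,
                   criterion_c = fit$criterion_c, meta_d = fit$meta_d,
                   ratio = fit$ratio, n_trials = fit$n_trials,
                   converged = fit$converged)
  })))

  control <- run_stage("conflict_control", {
    flagged <- apply_exclusions(sess_conflict)
    cells <- cell_medians(flagged)
    list(cells = cells, indices = gratton_index(cells),
         anova_rt = rm_anova_2x2(cells, "median_rt"),
         anova_error = rm_anova_2x2(cells, "error_rate"))
  })

  subject_tables <- lapply(mw, function(m) {
    dplyr::left_join(m$indicators[, c("subject_id", indicator_cols, "factor_score")],
                     m$detection[, c("subject_id", "index")], by = "subject_id") |>
      dplyr::left_join(metacog[, c("subject_id", "ratio")], by = "subject_id") |>
      dplyr::left_join(control$indices[, c("subject_id", "gratton")], by = "subject_id") |>
      dplyr::rename(detection = "index", metacog = "ratio", control = "gratton")
  })

  outlier_vars <- c("factor_score", "detection", "metacog", "control")
  outliers <- lapply(subject_tables, function(tab) {
    if (sum(complete.cases(tab[, outlier_vars])) <= 2 * length(outlier_vars)) {
      warn("Too few complete subjects for robust outlier detection; skipping.")
      return(NULL)
    }
    run_stage("robust_qc", flag_outliers(
      tab, outlier_vars,
      chisq_quantile = config$outlier$chisq_quantile,
      delta = config$outlier$delta, alpha = config$outlier$alpha))
  })

  sem <- lapply(subject_tables, function(tab) {
    run_stage("sem_path", fit_ml_sem(mw_path_model(), tab))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mindwandr")),
    seed = config$seed, n_subjects = n,
    n_sem = vapply(sem, function(f) f$n, numeric(1)),
    n_excluded = vapply(sem, function(f) n - f$n, numeric(1)),
    stage_seeds = list(master = config$seed,
                       per_subject = apply(seeds, 2, unname, simplify = FALSE))
  )

  bundle <- structure(
    list(profiles = profiles,
         sessions = if (keep_sessions) {
           list(sart_probe = sess_probe, sart_self = sess_self,
                dot = sess_dot, conflict = sess_conflict)
         } else NULL,
         mw = mw, metacog = metacog, control = control,
         outliers = outliers, sem = sem,
         subject_tables = subject_tables,
         config = config, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(bundle, config$out_dir)
  bundle
}

# serialize every artifact of a pipeline run to tidy CSV / JSON
write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  if (!is.null(bundle$sessions)) {
    for (v in c("sart_probe", "sart_self")) {
      write_trial_csv(dplyr::bind_rows(lapply(bundle$sessions[[v]], `[[`, "trials")),
                      fp(paste0(v, "_trials.csv")), "sart_trials")
      write_trial_csv(dplyr::bind_rows(lapply(bundle$sessions[[v]], `[[`, "reports")),
                      fp(paste0(v, "_reports.csv")), "sart_reports")
    }
    write_trial_csv(dplyr::bind_rows(bundle$sessions$dot), fp("dot_trials.csv"), "dot_trials")
    write_trial_csv(bundle$sessions$conflict, fp("conflict_trials.csv"), "conflict_trials")
  }
  jsonlite::write_json(
    list(config = list(n_subjects = bundle$config$n_subjects,
                       seed = bundle$config$seed,
                       dot_trials = bundle$config$dot_trials),
         traits = bundle$profiles),
    fp("cohort.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (v in names(bundle$mw)) {
    out <- dplyr::left_join(
      bundle$mw[[v]]$indicators[, c("subject_id", indicator_cols, "factor_score", "flags")],
      bundle$mw[[v]]$detection[, c("subject_id", "index", "n_off_segments", "flags")],
      by = "subject_id", suffix = c("", "_detection"))
    out$version <- v
    write_trial_csv(dplyr::rename(out, detection_index = "index"),
                    fp(paste0("mw_indices_", v, ".csv")))
  }
  write_trial_csv(bundle$metacog, fp("metacog.csv"))
  write_trial_csv(bundle$control$indices, fp("control_indices.csv"))
  jsonlite::write_json(
    list(median_rt = bundle$control$anova_rt, error_rate = bundle$control$anova_error),
    fp("anova.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(
    lapply(bundle$outliers, function(o) {
      o$row_flags <- NULL
      unclass(o)
    }),
    fp("outliers.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(bundle$sem, function(f) {
      list(estimates = as.list(f$theta), se = as.list(setNames(f$se, names(f$theta))),
           standardized = as.list(f$standardized),
           chi_sq = f$chi_sq, df = f$df, p_value = f$p_value,
           cfi = f$cfi, rmsea = f$rmsea, n = f$n,
           converged = f$converged, heywood = f$heywood)
    }),
    fp("sem_fit.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$manifest, fp("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
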