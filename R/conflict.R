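#' Default conflict-task cell parameters
#'
#' Population-level cell parameters of the arrow-priming conflict task, by
#' (previous congruency x congruency). RT medians (ms) imply a congruency
#' effect of 90 ms after congruent and 70 ms after incongruent trials (a
#' 20 ms congruency sequence effect); error rates imply error congruency
#' effects of 2.23 and 0.25 percentage points.
#'
#' @return A tibble with columns `prev_congruency`, `congruency`,
#'   `median_rt`, `error_rate` (fractions) and the lognormal `sdlog`.
#' @export
conflict_cell_defaults <- function() {
  tibble::tibble(
    prev_congruency = c("congruent", "congruent", "incongruent", "incongruent"),
    congruency = c("congruent", "incongruent", "congruent", "incongruent"),
    median_rt = c(450, 540, 460, 530),
    error_rate = c(0.0175, 0.0398, 0.0347, 0.0372),
    sdlog = 0.20
  )
}

#' Simulate one conflict-task session
#'
#' Generates 160 trials in four blocks of 40. Consecutive trials alternate
#' between the horizontal and vertical dimension; each block is balanced
#' (20 congruent, 20 incongruent). Correct-trial RTs are lognormal with cell
#' medians given by [conflict_cell_defaults()], shifted additively by the
#' subject's `base_speed` (relative to the population mean of 370 ms) and
#' with the congruency sequence effect set to the subject's
#' `control_strength` (in ms): a subject with `control_strength = 20`
#' reproduces the default 90/70 ms pattern, `control_strength = 0` shows no
#' sequential modulation. Error probabilities are the default cell rates.
#'
#' @param profile One-row trait tibble (see [gen_population()]).
#' @param seed Integer seed.
#' @param n_blocks,block_len Block structure (defaults 4 x 40).
#' @return A tibble of class `conflict_session`: `subject_id`, `trial`
#'   (0-based), `block`, `dimension`, `congruency`, `prev_congruency`
#'   (`"none"` on the first trial of each block), `rt_ms`, `correct`.
#' @export
gen_conflict_session <- function(profile, seed, n_blocks = 4, block_len = 40) {
  cells <- conflict_cell_defaults()
  shift <- (profile$base_speed %||% 370) - 370
  cs <- profile$control_strength %||% 20
  # interaction contrast: adding d * (-1, +1, +1, -1) changes the Gratton
  # index by 4d, leaving the mean congruency effect and both main effects
  # untouched
  d <- (cs - 20) / 4
  cell_rt <- cells$median_rt + shift + d * c(-1, 1, 1, -1)
  names(cell_rt) <- paste(cells$prev_congruency, cells$congruency, sep = ".")
  cell_err <- setNames(cells$error_rate, names(cell_rt))

  with_seed(seed, {
    stopifnot(block_len %% 2 == 0)
    per_block <- lapply(seq_len(n_blocks), function(b) {
      congr <- sample(rep(c("congruent", "incongruent"), block_len / 2))
      tibble::tibble(block = b, congruency = congr)
    })
    out <- dplyr::bind_rows(per_block)
    n <- nrow(out)
    # strict dimension alternation across the whole session
    dims <- c("horizontal", "vertical")
    if (sample(c(TRUE, FALSE), 1L)) dims <- rev(dims)
    out$dimension <- rep(dims, length.out = n)
    out$trial <- seq_len(n) - 1L
    out$prev_congruency <- dplyr::lag(out$congruency)
    first_of_block <- !duplicated(out$block)
    out$prev_congruency[first_of_block] <- "none"
    key <- ifelse(out$prev_congruency == "none",
                  paste("congruent", out$congruency, sep = "."),
                  paste(out$prev_congruency, out$congruency, sep = "."))
    med <- cell_rt[key]
    err_p <- cell_err[key]
    out$correct <- runif(n) >= err_p
    out$rt_ms <- rlnorm(n, meanlog = log(med) - 0.05 * !out$correct, sdlog = cells$sdlog[1])
    out$subject_id <- profile$subject_id %||% 1L
    out <- out[, c("subject_id", "trial", "block", "dimension", "congruency",
                   "prev_congruency", "rt_ms", "correct")]
    class(out) <- c("conflict_session", class(out))
    out
  })
}
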