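#' SART session configuration
#'
#' Configuration for the Go/No-Go sustained-attention task. In probe mode a
#' single run of 225 trials contains 12 unpredictable thought probes whose
#' spacing, converted at 2.5 s per trial, respects the 30-90 s interval as
#' far as the session length allows (the schedule is compressed near the end
#' so that all probes fit). In self-caught mode two blocks of 120 trials are
#' run without probes and the subject presses a key on noticing their own
#' mind wandering.
#'
#' @param mode `"probe"` or `"self"`.
#' @param n_trials Total trials; defaults to 225 (probe) or 240 (self, two
#'   blocks of 120).
#' @param n_probes Number of probes in probe mode (default 12).
#' @param probe_gap_s Bounds of the inter-probe interval in seconds.
#' @param trial_duration_s Seconds per trial (300 ms digit + 200 ms mask +
#'   2000 ms blank = 2.5 s).
#' @param target_digit The No-Go digit (default 3).
#' @param target_rate Fraction of No-Go trials (default 1/9).
#' @param segment_len Trials per pre-report segment used downstream.
#' @param n_blocks Number of blocks in self mode (default 2).
#' @return A list of class `sart_config`.
#' @export
sart_config <- function(mode = c("probe", "self"), n_trials = NULL,
                        n_probes = 12, probe_gap_s = c(30, 90),
                        trial_duration_s = 2.5, target_digit = 3,
                        target_rate = 1 / 9, segment_len = 4, n_blocks = 2) {
  mode <- match.arg(mode)
  if (is.null(n_trials)) n_trials <- if (mode == "probe") 225L else 240L
  if (mode == "probe" && n_probes < 1) abort("`n_probes` must be >= 1 in probe mode.")
  stopifnot(n_trials >= 1, length(probe_gap_s) == 2L, probe_gap_s[1] <= probe_gap_s[2],
            trial_duration_s > 0, target_rate > 0, target_rate < 1, segment_len >= 1)
  structure(
    list(mode = mode, n_trials = as.integer(n_trials), n_probes = as.integer(n_probes),
         probe_gap_s = probe_gap_s, trial_duration_s = trial_duration_s,
         target_digit = as.integer(target_digit), target_rate = target_rate,
         segment_len = as.integer(segment_len), n_blocks = as.integer(n_blocks)),
    class = "sart_config"
  )
}

# Per-state emission parameters of the SART simulator. States encode graded
# perceptual decoupling: weak decoupling inflates RT variance and No-Go
# commissions; deep decoupling additionally produces Go omissions and
# anticipations (< 100 ms presses).
sart_emissions <- function() {
  list(
    commission = c(on_task = 0.15, weak_decoupled = 0.55, deep_decoupled = 0.85),
    omission   = c(on_task = 0.005, weak_decoupled = 0.05, deep_decoupled = 0.30),
    antic_mult = c(on_task = 0.10, weak_decoupled = 1.50, deep_decoupled = 6.00),
    sdlog      = c(on_task = 0.12, weak_decoupled = 0.30, deep_decoupled = 0.48),
    meanlog_shift = c(on_task = 0, weak_decoupled = 0.03, deep_decoupled = 0.08),
    return_rate = 0.10,
    # probe answer model: off-task option chosen with probability
    # b0*(1 - da) + da * gain(state); the false-alarm floor vanishes as
    # detection ability da -> 1, and at da = 0 the answer is independent of
    # the attentional state.
    probe_base = 0.15,
    probe_gain = c(on_task = 0, weak_decoupled = 0.85, deep_decoupled = 1.00),
    # fraction of detection_ability acting as the per-trial self-catch hazard;
    # calibrated so a typical subject produces single-digit "B" presses per
    # session rather than catching every episode instantly
    self_hazard_scale = 0.25
  )
}

# Draw the probe positions (number of completed trials before each probe).
# Gaps are uniform on the trial-converted interval, truncated so that the
# remaining probes still fit; the final probes are forced in before the end
# of the session when necessary.
schedule_probes <- function(config) {
  lo <- max(1L, ceiling(config$probe_gap_s[1] / config$trial_duration_s))
  hi <- max(lo, floor(config$probe_gap_s[2] / config$trial_duration_s))
  pos <- integer(config$n_probes)
  cur <- 0L
  for (j in seq_len(config$n_probes)) {
    m <- config$n_probes - j        # probes still to place after this one
    cap <- config$n_trials - cur - lo * m
    if (cap >= lo) {
      gap <- sample(seq(lo, min(hi, cap)), 1L)
    } else {
      gap <- max(1L, cap)           # forced placement near the end
    }
    # cap so the remaining probes still fit at distinct positions
    cur <- min(cur + gap, config$n_trials - m)
    pos[j] <- cur
  }
  pos
}

#' Simulate one SART session
#'
#' Latent attention follows a three-state Markov chain (`on_task`,
#' `weak_decoupled`, `deep_decoupled`): the chain leaves the on-task state
#' with per-trial probability `mw_propensity` (split 2:1 weak:deep) and
#' returns with rate 0.10; behavior degrades gradedly with state depth (see
#' `sart_emissions()`). Probe answers pick an off-task option with
#' probability increasing in state depth and in `detection_ability`; in
#' self-caught mode the subject notices being off-task with per-trial hazard
#' `detection_ability` and presses "B". After any report attention resets to
#' the on-task state.
#'
#' @param profile One-row trait tibble (see [gen_population()]).
#' @param config A [sart_config()].
#' @param seed Integer seed.
#' @return A list of class `sart_session` with elements `trials` (tibble:
#'   `subject_id`, `trial` 0-based, `block`, `digit`, `is_target`,
#'   `responded`, `rt_ms`, `latent_state`) and `reports` (tibble:
#'   `subject_id`, `after_trial`, `kind`, `option`), plus the `config`.
#' @export
gen_sart_session <- function(profile, config = sart_config(), seed) {
  stopifnot(inherits(config, "sart_config"))
  em <- sart_emissions()
  p <- profile$mw_propensity
  da <- profile$detection_ability
  check_scalar_prob(p, "mw_propensity")
  check_scalar_prob(da, "detection_ability")
  base_speed <- profile$base_speed
  lapse <- profile$lapse_rate
  stopifnot(base_speed > 0, lapse >= 0, lapse <= 1)
  n <- config$n_trials
  states <- c("on_task", "weak_decoupled", "deep_decoupled")

  with_seed(seed, {
    n_targets <- round(n * config$target_rate)
    target_pos <- sort(sample.int(n, n_targets))
    digit <- sample(setdiff(1:9, config$target_digit), n, replace = TRUE)
    digit[target_pos] <- config$target_digit
    is_target <- digit == config$target_digit

    block <- if (config$mode == "self") {
      rep(seq_len(config$n_blocks), each = ceiling(n / config$n_blocks))[seq_len(n)]
    } else {
      rep(1L, n)
    }

    probe_after <- if (config$mode == "probe") schedule_probes(config) else integer(0)

    state <- 1L
    st_vec <- integer(n)
    reports <- list()
    off_options <- c("empty", "unaware_mw", "aware_mw")
    off_probs <- list(
      on_task = c(1, 1, 1) / 3,
      weak_decoupled = c(0.3, 0.5, 0.2),
      deep_decoupled = c(0.3, 0.2, 0.5)
    )
    for (i in seq_len(n)) {
      # block transitions restart attention (short break between blocks)
      if (i > 1L && block[i] != block[i - 1L]) state <- 1L
      # probe between trial i-1 and i: reports on the state "just before"
      if (config$mode == "probe" && (i - 1L) %in% probe_after && i > 1L) {
        s_prev <- states[st_vec[i - 1L]]
        p_off <- min(1, em$probe_base * (1 - da) + da * em$probe_gain[[s_prev]])
        if (runif(1) < p_off) {
          opt <- sample(off_options, 1L, prob = off_probs[[s_prev]])
        } else {
          opt <- "focused"
        }
        reports[[length(reports) + 1L]] <-
          list(after_trial = i - 1L, kind = "probe", option = opt)
        state <- 1L
      }
      # evolve the chain
      u <- runif(1)
      if (state == 1L) {
        if (u < 2 * p / 3) state <- 2L else if (u < p) state <- 3L
      } else if (state == 2L) {
        if (u < em$return_rate) state <- 1L
        else if (u < em$return_rate + p / 3) state <- 3L
      } else {
        if (u < em$return_rate) state <- 1L
      }
      st_vec[i] <- state
      # self-caught report after this trial
      if (config$mode == "self" && state > 1L && runif(1) < em$self_hazard_scale * da) {
        opt <- sample(c("empty", "mw"), 1L, prob = c(0.3, 0.7))
        reports[[length(reports) + 1L]] <-
          list(after_trial = i, kind = "self_caught", option = opt)
        state <- 1L
      }
    }
    # terminal probe (scheduled after the last trial)
    if (config$mode == "probe" && n %in% probe_after) {
      s_prev <- states[st_vec[n]]
      p_off <- min(1, em$probe_base * (1 - da) + da * em$probe_gain[[s_prev]])
      opt <- if (runif(1) < p_off) {
        sample(off_options, 1L, prob = off_probs[[s_prev]])
      } else "focused"
      reports[[length(reports) + 1L]] <-
        list(after_trial = n, kind = "probe", option = opt)
    }

    st_chr <- states[st_vec]
    p_ant <- pmin(1, lapse * em$antic_mult[st_vec])
    anticip <- runif(n) < p_ant
    responded <- logical(n)
    rt <- rep(NA_real_, n)
    commission <- runif(n) < em$commission[st_vec]
    omission <- runif(n) < em$omission[st_vec]
    go <- !is_target
    responded[go] <- !omission[go]
    responded[!go] <- commission[!go]
    responded[anticip] <- TRUE
    n_resp <- sum(responded)
    meanlog <- log(base_speed) + em$meanlog_shift[st_vec] - 0.1 * is_target
    rt[responded] <- rlnorm(n_resp, meanlog[responded], em$sdlog[st_vec][responded])
    rt[anticip] <- runif(sum(anticip), 0, 100)

    trials <- tibble::tibble(
      subject_id = profile$subject_id %||% 1L,
      trial = seq_len(n) - 1L,
      block = block,
      digit = digit,
      is_target = is_target,
      responded = responded,
      rt_ms = rt,
      latent_state = st_chr
    )
    reports <- if (length(reports)) {
      tibble::tibble(
        subject_id = profile$subject_id %||% 1L,
        after_trial = vapply(reports, `[[`, integer(1), "after_trial"),
        kind = vapply(reports, `[[`, character(1), "kind"),
        option = vapply(reports, `[[`, character(1), "option")
      )
    } else {
      tibble::tibble(subject_id = integer(0), after_trial = integer(0),
                     kind = character(0), option = character(0))
    }
    structure(list(trials = trials, reports = reports, config = config),
              class = "sart_session")
  })
}
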