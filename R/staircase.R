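#' Create a weighted up-down staircase state
#'
#' The dot-discrimination difficulty (difference in dots between the two
#' clouds) is adapted with an unequal-step staircase: the difference grows by
#' two dots after an incorrect answer and shrinks by one dot after a correct
#' answer, which tracks ~2/3 accuracy at asymptote. After four consecutive
#' reversals between correct and incorrect responses the steps double to
#' (4, 2); after eight consecutive reversals they return to (2, 1).
#'
#' @param delta Starting dot difference (>= 1).
#' @return A list of class `staircase_state` with fields `delta`,
#'   `base_steps`, `current_steps` (named `up`/`down`),
#'   `consecutive_reversals` and `last_correct`.
#' @seealso [staircase_update()]
#' @export
staircase_state <- function(delta = 20) {
  stopifnot(delta >= 1)
  structure(
    list(
      delta = delta,
      base_steps = c(up = 2, down = 1),
      current_steps = c(up = 2, down = 1),
      consecutive_reversals = 0L,
      last_correct = NA
    ),
    class = "staircase_state"
  )
}

#' Advance the staircase after one trial
#'
#' Applies the weighted up-down rule: `delta` increases by the current "up"
#' step after an incorrect response and decreases by the current "down" step
#' after a correct response, floored at 1 dot. A *reversal* is counted when
#' correctness flips relative to the previous trial; the counter resets to 0
#' when correctness repeats. When the counter reaches 4 the step sizes
#' double to (4, 2); when it reaches 8 they return to (2, 1) and the counter
#' resets.
#'
#' @param state A `staircase_state`.
#' @param correct Logical; was the response on this trial correct?
#' @return The updated `staircase_state`.
#' @export
#' @examples
#' s <- staircase_state(delta = 10)
#' staircase_update(s, correct = TRUE)$delta   # 9
#' staircase_update(s, correct = FALSE)$delta  # 12
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct), length(correct) == 1L)
  if (isTRUE(correct)) {
    state$delta <- max(1, state$delta - state$current_steps[["down"]])
  } else {
    state$delta <- state$delta + state$current_steps[["up"]]
  }
  if (!is.na(state$last_correct)) {
    if (correct != state$last_correct) {
      state$consecutive_reversals <- state$consecutive_reversals + 1L
      if (state$consecutive_reversals == 4L) {
        state$current_steps <- c(up = 4, down = 2)
      } else if (state$consecutive_reversals == 8L) {
        state$current_steps <- state$base_steps
        state$consecutive_reversals <- 0L
      }
    } else {
      state$consecutive_reversals <- 0L
    }
  }
  state$last_correct <- correct
  state
}

#' Simulate a dot-discrimination session with confidence ratings
#'
#' Two dot clouds are shown (reference 50 dots, comparison 50 + delta); the
#' subject picks the side with more dots and rates confidence on a
#' continuous scale from 0 ("sure false") through 0.5 ("no idea") to 1
#' ("sure correct"). Per trial, signed evidence `x ~ N(s * delta / sigma_s, 1)`
#' (s = +1 when the right side is correct; `sigma_s = 6` dots of sensory
#' noise) drives the choice by its sign. Confidence is the observer's
#' posterior probability that the chosen side was correct, computed from a
#' second read-out `x2 = x + N(0, sigma_m^2)` where `sigma_m` is the
#' subject's metacognitive noise: with `sigma_m = 0` confidence uses exactly
#' the decision evidence; larger `sigma_m` decouples confidence from
#' accuracy. Difficulty follows the weighted staircase of
#' [staircase_update()].
#'
#' @param profile One-row trait tibble from [gen_population()] (fields
#'   `metacog_noise` and `subject_id` are used).
#' @param n_trials Number of trials (default 200, i.e. eight blocks of 25).
#' @param seed Integer seed.
#' @param start_delta Starting dot difference (default 20).
#' @param sigma_s Sensory noise in dots (default 6).
#' @return A tibble of class `dot_session`: `subject_id`, `trial` (0-based),
#'   `delta`, `correct_side`, `choice`, `correct`, `confidence`, `rt_ms`.
#' @export
gen_dot_session <- function(profile, n_trials = 200, seed,
                            start_delta = 20, sigma_s = 6) {
  stopifnot(n_trials >= 1)
  sigma_m <- profile$metacog_noise
  stopifnot(is.numeric(sigma_m), sigma_m >= 0)
  with_seed(seed, {
    side <- sample(c(-1, 1), n_trials, replace = TRUE) # +1 = right correct
    e1 <- rnorm(n_trials)
    e2 <- rnorm(n_trials)
    rt_noise <- rnorm(n_trials)
    delta <- numeric(n_trials)
    st <- staircase_state(start_delta)
    x <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      delta[i] <- st$delta
      x[i] <- side[i] * delta[i] / sigma_s + e1[i]
      st <- staircase_update(st, correct = ((x[i] >= 0) == (side[i] == 1)))
    }
    choice <- ifelse(x >= 0, 1, -1)
    correct <- choice == side
    x2 <- x + sigma_m * e2
    tau2 <- 1 + sigma_m^2
    # The observer does not know the trial's dot difference; the posterior
    # is computed at the staircase-tracked sensitivity (the (2,1) rule
    # converges on ~2/3 correct), i.e. confidence is a fixed monotone map
    # of the choice-signed metacognitive evidence.
    mu_ref <- qnorm(2 / 3)
    confidence <- plogis(2 * mu_ref * choice * x2 / tau2)
    rt_ms <- exp(log(600) - 0.3 * (confidence - 0.5) + 0.25 * rt_noise)
    tibble::tibble(
      subject_id = profile$subject_id %||% 1L,
      trial = seq_len(n_trials) - 1L,
      delta = delta,
      correct_side = ifelse(side == 1, "right", "left"),
      choice = ifelse(choice == 1, "right", "left"),
      correct = correct,
      confidence = confidence,
      rt_ms = rt_ms
    ) -> out
    class(out) <- c("dot_session", class(out))
    attr(out, "sigma_s") <- sigma_s
    attr(out, "sigma_m") <- sigma_m
    out
  })
}
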