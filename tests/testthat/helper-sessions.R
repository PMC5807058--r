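# Shared helpers: hand-built sessions and profiles used across test files.

make_profile <- function(subject_id = 1L, mw_propensity = 0.2,
                         detection_ability = 0.5, metacog_noise = 0.8,
                         control_strength = 20, base_speed = 370,
                         lapse_rate = 0.02) {
  tibble::tibble(subject_id = subject_id, mw_propensity = mw_propensity,
                 detection_ability = detection_ability,
                 metacog_noise = metacog_noise,
                 control_strength = control_strength,
                 base_speed = base_speed, lapse_rate = lapse_rate)
}

with_seed_shuffle <- function(x, seed) mindwandr:::with_seed(seed, sample(x))

# a synthetic sart_session built directly from trial/report tables
make_sart_session <- function(trials, reports, mode = "probe") {
  structure(
    list(trials = trials, reports = reports,
         config = sart_config(mode, n_trials = nrow(trials))),
    class = "sart_session"
  )
}

make_sart_trials <- function(n, is_target = rep(FALSE, n),
                             responded = rep(TRUE, n),
                             rt_ms = rep(300, n), subject_id = 1L) {
  tibble::tibble(
    subject_id = subject_id, trial = seq_len(n) - 1L, block = 1L,
    digit = ifelse(is_target, 3L, 5L), is_target = is_target,
    responded = responded, rt_ms = ifelse(responded, rt_ms, NA_real_),
    latent_state = "on_task"
  )
}

make_reports <- function(after_trial, kind = "probe", option = "focused",
                         subject_id = 1L) {
  tibble::tibble(subject_id = subject_id, after_trial = as.integer(after_trial),
                 kind = kind, option = option)
}

# minimal dot-session table for binning (only the columns bin_confidence uses)
make_dot_table <- function(correct_side, choice, confidence, subject_id = 1L) {
  tibble::tibble(subject_id = subject_id,
                 trial = seq_along(confidence) - 1L,
                 correct_side = correct_side, choice = choice,
                 correct = correct_side == choice,
                 confidence = confidence, rt_ms = 600)
}

# conflict cells table from four RT values (prevC-C, prevC-I, prevI-C, prevI-I)
# and optional error-rate values in the same order
make_cells <- function(rt, err = c(0, 0, 0, 0), subject_id = 1L) {
  tibble::tibble(
    subject_id = subject_id,
    prev_congruency = c("congruent", "congruent", "incongruent", "incongruent"),
    congruency = c("congruent", "incongruent", "congruent", "incongruent"),
    median_rt = rt, error_rate = err, n_rt = 10L, n_error = 10L, flag = ""
  )
}

# independent fitter check: nested grid search over (meta_d, two type-2
# criterion offsets) for K = 2 bins, refined to a 0.001 lattice
grid_fit_meta_d_2bin <- function(counts) {
  t1 <- type1_sdt(counts$type1$hits, counts$type1$misses,
                  counts$type1$false_alarms, counts$type1$correct_rejections)
  c_rel <- t1$criterion_c / t1$d_prime
  obs <- counts$counts
  if (any(obs == 0)) obs <- obs + 1 / (2 * counts$K)
  nll <- function(md, dl, dr) {
    c1 <- c_rel * md
    bl <- c(c1, c1 + dl, Inf); br <- c(c1, c1 - dr, -Inf)
    mu <- c(md / 2, -md / 2)
    tot <- 0
    for (s in 1:2) {
      pl <- 1 - pnorm(c1 - mu[s]); prr <- pnorm(c1 - mu[s])
      for (k in 1:2) {
        p1 <- (pnorm(bl[k + 1] - mu[s]) - pnorm(bl[k] - mu[s])) / pl
        p2 <- (pnorm(br[k] - mu[s]) - pnorm(br[k + 1] - mu[s])) / prr
        tot <- tot - obs[s, 1, k] * log(max(p1, 1e-12)) -
          obs[s, 2, k] * log(max(p2, 1e-12))
      }
    }
    tot
  }
  centers <- c(t1$d_prime, 0.5, 0.5)
  widths <- c(2.5, 1, 1)
  best <- NULL
  obj <- NULL
  for (step in c(0.1, 0.01, 0.001)) {
    md_g <- seq(centers[1] - widths[1], centers[1] + widths[1], by = step)
    dl_g <- seq(max(0.001, centers[2] - widths[2]), centers[2] + widths[2], by = step)
    dr_g <- seq(max(0.001, centers[3] - widths[3]), centers[3] + widths[3], by = step)
    vals <- expand.grid(md = md_g, dl = dl_g, dr = dr_g)
    obj <- mapply(nll, vals$md, vals$dl, vals$dr)
    best <- vals[which.min(obj), ]
    centers <- as.numeric(best)
    widths <- rep(step * 1.5, 3)
  }
  list(meta_d = best$md, nll = min(obj))
}
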