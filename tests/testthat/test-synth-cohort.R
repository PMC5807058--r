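test_that("gen_population honors invariants and is seed-deterministic", {
  pop <- gen_population(63, seed = 1)
  expect_equal(nrow(pop), 63)
  expect_true(all(pop$mw_propensity >= 0 & pop$mw_propensity <= 1))
  expect_true(all(pop$detection_ability >= 0 & pop$detection_ability <= 1))
  expect_true(all(pop$lapse_rate >= 0 & pop$lapse_rate <= 1))
  expect_true(all(pop$metacog_noise >= 0))
  expect_true(all(pop$base_speed > 0))
  expect_identical(pop, gen_population(63, seed = 1))
  expect_false(identical(pop, gen_population(63, seed = 2)))
})

test_that("gen_population rejects non-PSD covariance with a diagnostic", {
  R <- trait_covariance_default()
  R[1, 2] <- R[2, 1] <- 1.5
  expect_error(gen_population(10, R, seed = 1), "positive semi-definite")
  expect_error(gen_population(10, R, seed = 1), "eigenvalue")
})

test_that("copula reproduces requested trait correlations at n = 10^4", {
  R0 <- diag(6)
  dimnames(R0) <- dimnames(trait_covariance_default())
  pop0 <- gen_population(10000, R0, seed = 11)
  lat <- attr(pop0, "latent")
  offdiag <- cor(lat)[upper.tri(diag(6))]
  expect_lt(max(abs(offdiag)), 0.03)

  pop <- gen_population(10000, seed = 12)
  r <- cor(pop$metacog_efficiency, pop$control_strength)
  expect_lt(abs(r - 0.29), 0.03)
})

test_that("probe sessions contain exactly 12 probe reports and 11% targets", {
  for (s in 1:6) {
    pop <- gen_population(1, seed = s)
    sess <- gen_sart_session(pop[1, ], sart_config("probe"), seed = 100 + s)
    expect_identical(nrow(sess$reports), 12L)
    expect_true(all(sess$reports$kind == "probe"))
    expect_equal(sum(sess$trials$is_target) / nrow(sess$trials), 1 / 9)
    gaps <- diff(c(0, sess$reports$after_trial))
    expect_true(all(gaps >= 1))
  }
})

test_that("a never-wandering perfect detector stays on task and reports it", {
  prof <- make_profile(mw_propensity = 0, detection_ability = 1, lapse_rate = 0)
  sp <- gen_sart_session(prof, sart_config("probe"), seed = 5)
  expect_true(all(sp$trials$latent_state == "on_task"))
  expect_true(all(sp$reports$option == "focused"))
  ss <- gen_sart_session(prof, sart_config("self"), seed = 6)
  expect_identical(nrow(ss$reports), 0L)
})

test_that("SART emissions degrade gradedly with state depth", {
  prof <- make_profile(mw_propensity = 0.3)
  big <- gen_sart_session(prof, sart_config("probe", n_trials = 1e5, n_probes = 1),
                          seed = 11)
  tr <- big$trials
  comm <- vapply(c("on_task", "weak_decoupled", "deep_decoupled"), function(st) {
    mean(tr$responded[tr$is_target & tr$latent_state == st])
  }, numeric(1))
  expect_true(comm["deep_decoupled"] >= comm["weak_decoupled"])
  expect_true(comm["weak_decoupled"] >= comm["on_task"])
  # deep state additionally produces omissions and anticipations
  go <- tr[!tr$is_target, ]
  omis <- tapply(!go$responded, go$latent_state, mean)
  expect_gt(omis[["deep_decoupled"]], omis[["on_task"]])
  antic <- tapply(go$responded & go$rt_ms < 100, go$latent_state, mean)
  expect_gt(antic[["deep_decoupled"]], antic[["on_task"]])
  # byte-identical regeneration
  again <- gen_sart_session(prof, sart_config("probe", n_trials = 1e5, n_probes = 1),
                            seed = 11)
  expect_identical(big, again)
})

test_that("staircase follows the weighted up-down rule with step doubling", {
  s <- staircase_state(delta = 10)
  expect_equal(staircase_update(s, TRUE)$delta, 9)
  expect_equal(staircase_update(s, FALSE)$delta, 12)
  expect_equal(staircase_update(staircase_state(delta = 1), TRUE)$delta, 1)

  # four consecutive reversals (alternating correctness) double the steps
  s <- staircase_state(delta = 30)
  outcomes <- c(TRUE, FALSE, TRUE, FALSE, TRUE)  # flips at trials 2..5
  for (i in seq_along(outcomes)) {
    before <- s$consecutive_reversals
    s <- staircase_update(s, outcomes[i])
    if (s$consecutive_reversals == 4L) {
      expect_equal(unname(s$current_steps), c(4, 2))
    }
  }
  expect_equal(unname(s$current_steps), c(4, 2))
  # doubled steps now move delta by 4 / 2
  d0 <- s$delta
  s2 <- staircase_update(s, FALSE)
  expect_equal(s2$delta, d0 + 4)
  expect_equal(staircase_update(s, TRUE)$delta, d0 - 2)
  # continue flipping to the eighth reversal: steps reset, counter cleared
  for (k in 1:4) s <- staircase_update(s, !s$last_correct)
  expect_equal(unname(s$current_steps), c(2, 1))
  expect_equal(s$consecutive_reversals, 0L)
  # a repeat resets the counter
  s <- staircase_state(delta = 10)
  s <- staircase_update(s, TRUE); s <- staircase_update(s, FALSE)
  expect_equal(s$consecutive_reversals, 1L)
  s <- staircase_update(s, FALSE)
  expect_equal(s$consecutive_reversals, 0L)
})

test_that("dot sessions: confidence tracks accuracy unless metacognitive noise dominates", {
  ideal <- gen_dot_session(make_profile(metacog_noise = 0), 10000, seed = 21)
  expect_gt(cor(ideal$confidence, ideal$correct, method = "spearman"), 0.2)
  noisy <- gen_dot_session(make_profile(metacog_noise = 50), 10000, seed = 22)
  expect_lt(abs(cor(noisy$confidence, noisy$correct, method = "spearman")), 0.03)
  expect_true(all(ideal$confidence >= 0 & ideal$confidence <= 1))
  expect_true(all(ideal$delta >= 1))
  expect_identical(ideal, gen_dot_session(make_profile(metacog_noise = 0), 10000, seed = 21))
})

test_that("staircase keeps session accuracy in the expected band", {
  for (s in 1:5) {
    sess <- gen_dot_session(make_profile(), 200, seed = 30 + s)
    acc <- mean(sess$correct)
    expect_gte(acc, 0.60)
    expect_lte(acc, 0.82)
  }
})

test_that("conflict sessions have the prescribed block and balance structure", {
  sess <- gen_conflict_session(make_profile(), seed = 41)
  expect_equal(nrow(sess), 160)
  expect_equal(length(unique(sess$block)), 4)
  expect_equal(sum(sess$congruency == "congruent"), 80)
  expect_true(all(table(sess$block, sess$congruency) == 20))
  expect_true(all(sess$dimension[-1] != sess$dimension[-160]))
  first <- !duplicated(sess$block)
  expect_true(all(sess$prev_congruency[first] == "none"))
  expect_true(all(sess$prev_congruency[!first] ==
                    sess$congruency[which(!first) - 1L]))
  expect_identical(sess, gen_conflict_session(make_profile(), seed = 41))
})

test_that("zero control strength removes the congruency sequence effect", {
  prof <- make_profile(control_strength = 0)
  g <- lapply(1:600, function(i) {
    p <- prof; p$subject_id <- i
    gen_conflict_session(p, seed = 500 + i)
  })
  cells <- cell_medians(apply_exclusions(dplyr::bind_rows(g)))
  idx <- gratton_index(cells)
  expect_lt(abs(mean(idx$ce_after_congruent) - mean(idx$ce_after_incongruent)), 6)
})
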