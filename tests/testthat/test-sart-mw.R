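test_that("indicators match hand-computed values on a toy trial set", {
  rts <- c(350, 360, 340, 355, 345, 80, 500, 420)
  trials <- make_sart_trials(
    n = 10,
    is_target = c(rep(FALSE, 9), TRUE),
    responded = c(rep(TRUE, 8), FALSE, TRUE),
    rt_ms = c(rts, NA, 320)
  )
  ind <- compute_indicators(trials)
  expect_equal(ind$nogo_fail_pct, 100)
  expect_equal(ind$go_fail_pct, 100 / 9)
  expect_equal(ind$anticipation_pct, 100 / 9)  # the 80 ms press, of 9 Go trials
  # frozen from the defining formula: sd of the 8 listed RTs
  expect_equal(ind$rt_variability, 119.66471, tolerance = 1e-6)
  expect_identical(ind$flags, "")
})

test_that("degenerate sessions give zero indicators or flags", {
  perfect <- make_sart_trials(10, is_target = c(rep(FALSE, 9), TRUE),
                              responded = c(rep(TRUE, 9), FALSE),
                              rt_ms = c(rep(300, 9), NA))
  expect_equal(unlist(compute_indicators(perfect)[, 1:4]),
               c(nogo_fail_pct = 0, go_fail_pct = 0, rt_variability = 0,
                 anticipation_pct = 0))
  no_nogo <- make_sart_trials(5)
  ind <- compute_indicators(no_nogo)
  expect_true(is.na(ind$nogo_fail_pct))
  expect_match(ind$flags, "nogo_fail_pct")
  expect_error(compute_indicators(make_sart_trials(0)), "empty")
})

test_that("factor extraction equals an independent svd oracle and handles rank-1 data", {
  set.seed(7)
  X <- matrix(rnorm(24), 6, 4)
  colnames(X) <- c("nogo_fail_pct", "go_fail_pct", "rt_variability", "anticipation_pct")
  m <- extract_mw_factor(X)
  # oracle: leading right singular vector of the standardized data equals the
  # leading eigenvector of the correlation matrix
  v <- svd(scale(X))$v[, 1]
  v <- v / sqrt(sum(v^2))
  if (v[4] < 0) v <- -v
  expect_equal(unname(m$loadings), v, tolerance = 1e-8)
  expect_equal(sum(m$loadings^2), 1, tolerance = 1e-12)

  shared <- rnorm(8)
  X1 <- outer(shared, c(1, 2, 3, 4)) + 5
  colnames(X1) <- colnames(X)
  m1 <- extract_mw_factor(X1)
  expect_equal(abs(unname(m1$loadings)), rep(0.5, 4), tolerance = 1e-8)
  expect_equal(abs(cor(m1$scores, shared)), 1, tolerance = 1e-8)

  Xc <- X; Xc[, 2] <- 1
  expect_error(extract_mw_factor(Xc), "go_fail_pct")
  expect_error(extract_mw_factor(X[1:4, ]), "at least 5")
})

test_that("factor loadings are all positive on simulated graded-decoupling cohorts", {
  pop <- gen_population(120, seed = 3)
  ind <- dplyr::bind_rows(lapply(1:120, function(i) {
    compute_indicators(gen_sart_session(pop[i, ], sart_config("probe"), 900 + i)$trials)
  }))
  m <- extract_mw_factor(ind)
  expect_true(all(m$loadings > 0))
})

test_that("pre-report segments follow the 0-based index arithmetic", {
  trials <- make_sart_trials(50)
  sess <- make_sart_session(trials, make_reports(40, option = "focused"), "probe")
  seg <- segment_preceding_reports(sess, k = 4)
  expect_setequal(seg$trial, 36:39)
  expect_true(all(seg$label == "on_task"))

  trials20 <- make_sart_trials(20)
  sess_self <- make_sart_session(trials20, make_reports(10, "self_caught", "mw"), "self")
  seg2 <- segment_preceding_reports(sess_self, k = 4)
  expect_setequal(seg2$trial[seg2$label == "off_task"], 6:9)
  expect_setequal(seg2$trial[seg2$label == "on_task"], setdiff(0:19, 6:9))

  # overlapping self-caught segments: each trial goes to the nearer report
  sess_ovl <- make_sart_session(
    trials20, make_reports(c(5, 7), "self_caught", "mw"), "self")
  seg3 <- segment_preceding_reports(sess_ovl, k = 4)
  off <- seg3[seg3$label == "off_task", ]
  expect_setequal(off$trial[off$report_id == 1], 1:4)
  expect_setequal(off$trial[off$report_id == 2], 5:6)
  expect_equal(anyDuplicated(seg3$trial), 0)

  # truncation at the session start
  sess_tr <- make_sart_session(trials20, make_reports(2, "self_caught", "mw"), "self")
  seg4 <- segment_preceding_reports(sess_tr, k = 4)
  expect_setequal(seg4$trial[seg4$label == "off_task"], 0:1)
})

test_that("aware-mind-wandering exclusion drops only aware segments", {
  trials <- make_sart_trials(60)
  reps <- make_reports(c(20, 40, 60),
                       option = c("aware_mw", "unaware_mw", "focused"))
  sess <- make_sart_session(trials, reps, "probe")
  seg_all <- segment_preceding_reports(sess, k = 4)
  seg_ex <- segment_preceding_reports(sess, k = 4, exclude_aware = TRUE)
  expect_setequal(seg_all$trial[seg_all$label == "off_task"], c(16:19, 36:39))
  expect_setequal(seg_ex$trial[seg_ex$label == "off_task"], 36:39)
})

test_that("detection index is zero for identical pools and positive for degraded off pools", {
  pop <- gen_population(60, seed = 13)
  ind <- dplyr::bind_rows(lapply(1:60, function(i) {
    compute_indicators(gen_sart_session(pop[i, ], sart_config("probe"), 700 + i)$trials)
  }))
  model <- extract_mw_factor(ind)

  # both pools contain one withheld No-Go and three Go responses at
  # identical RTs: the indicator vectors coincide exactly
  n <- 28
  is_target <- rep(FALSE, n); is_target[c(9, 21)] <- TRUE  # trials 8 and 20
  responded <- !is_target
  rt <- rep(c(310, 330, 350, 370), length.out = n)
  rt[c(9, 21)] <- NA
  rt[9:12] <- c(NA, 310, 330, 350); rt[21:24] <- c(NA, 310, 330, 350)
  tr <- make_sart_trials(n, is_target = is_target, responded = responded, rt_ms = rt)
  sess <- make_sart_session(tr, make_reports(c(12, 24), option = c("focused", "aware_mw")), "probe")
  di <- detection_index(sess, model, k = 4)
  expect_equal(di$index, 0, tolerance = 1e-12)

  # degrade the off pool: a commission, an anticipation, wilder RTs
  tr2 <- tr
  off_rows <- tr2$trial %in% 20:23
  tr2$is_target[off_rows] <- c(TRUE, FALSE, FALSE, FALSE)
  tr2$responded[off_rows] <- TRUE
  tr2$rt_ms[off_rows] <- c(80, 600, 90, 350)
  sess2 <- make_sart_session(tr2, make_reports(c(12, 24), option = c("focused", "aware_mw")), "probe")
  di2 <- detection_index(sess2, model, k = 4)
  expect_gt(di2$index, 0)

  # empty off-pool class propagates a flag instead of a number
  tr3 <- tr
  tr3$is_target[tr3$trial %in% 20:23] <- FALSE
  sess3 <- make_sart_session(tr3, make_reports(c(12, 24), option = c("focused", "aware_mw")), "probe")
  di3 <- detection_index(sess3, model, k = 4)
  expect_true(is.na(di3$index))
  expect_match(di3$flags, "nogo")
})

test_that("shifting all RTs leaves the RT-variability channel unchanged", {
  rts <- seq(300, 440, by = 20)
  tr <- make_sart_trials(8, rt_ms = rts)
  tr_shift <- make_sart_trials(8, rt_ms = rts + 150)
  expect_equal(compute_indicators(tr)$rt_variability,
               compute_indicators(tr_shift)$rt_variability)
})

test_that("reports uncorrelated with state give a near-zero mean detection index", {
  # detection_ability = 0: the off-answer probability is identical in every
  # attentional state, so off and on pools are statistically exchangeable
  pop <- gen_population(400, seed = 17)
  pop$detection_ability <- 0
  cfg <- sart_config("probe")
  sess <- lapply(1:400, function(i) gen_sart_session(pop[i, ], cfg, 3000 + i))
  ind <- dplyr::bind_rows(lapply(sess, function(s) compute_indicators(s$trials)))
  model <- extract_mw_factor(ind)
  idx <- vapply(sess, function(s) detection_index(s, model)$index, numeric(1))
  expect_lt(abs(mean(idx, na.rm = TRUE)), 0.7)
})

test_that("detection index tracks ground-truth detection ability in sign", {
  pop <- gen_population(400, seed = 19)
  cfg <- sart_config("probe")
  sess <- lapply(1:400, function(i) gen_sart_session(pop[i, ], cfg, 5000 + i))
  ind <- dplyr::bind_rows(lapply(sess, function(s) compute_indicators(s$trials)))
  model <- extract_mw_factor(ind)
  idx <- vapply(sess, function(s) detection_index(s, model)$index, numeric(1))
  rho <- cor(idx, pop$detection_ability, use = "complete.obs", method = "spearman")
  expect_gt(rho, 0.1)
})

test_that("behavioral factor scores agree across probe and self versions", {
  pop <- gen_population(200, seed = 33)
  s1 <- lapply(1:200, function(i) gen_sart_session(pop[i, ], sart_config("probe"), 40000 + i))
  s2 <- lapply(1:200, function(i) gen_sart_session(pop[i, ], sart_config("self"), 80000 + i))
  i1 <- dplyr::bind_rows(lapply(s1, function(s) compute_indicators(s$trials)))
  i2 <- dplyr::bind_rows(lapply(s2, function(s) compute_indicators(s$trials)))
  m1 <- extract_mw_factor(i1); m2 <- extract_mw_factor(i2)
  expect_gt(cor(predict(m1, i1), predict(m2, i2)), 0.5)
})
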