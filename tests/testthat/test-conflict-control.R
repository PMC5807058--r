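test_that("exclusions remove first-of-block, error and post-error trials in order", {
  sess <- gen_conflict_session(make_profile(), seed = 1)
  sess$correct <- TRUE
  fl <- apply_exclusions(sess)
  expect_equal(sum(!is.na(fl$removed_by)), 4)
  expect_true(all(fl$removed_by[!is.na(fl$removed_by)] == "first_of_block"))
  expect_equal(sum(!fl$keep_rt), 4)  # 2.5% of 160

  sess2 <- sess
  sess2$correct[sess2$trial == 10] <- FALSE
  fl2 <- apply_exclusions(sess2)
  expect_false(fl2$keep_rt[fl2$trial == 10])
  expect_false(fl2$keep_rt[fl2$trial == 11])
  expect_equal(fl2$removed_by[fl2$trial == 10], "error")
  expect_equal(fl2$removed_by[fl2$trial == 11], "post_error")
  # error-rate analysis keeps the error trial but not its successor
  expect_true(fl2$keep_error[fl2$trial == 10])
  expect_false(fl2$keep_error[fl2$trial == 11])

  # an error on the last trial of a block does not spill into the next block
  sess3 <- sess
  last_b1 <- max(sess3$trial[sess3$block == 1])
  sess3$correct[sess3$trial == last_b1] <- FALSE
  fl3 <- apply_exclusions(sess3)
  expect_equal(fl3$removed_by[fl3$trial == last_b1 + 1], "first_of_block")
  expect_equal(sum(fl3$removed_by == "post_error", na.rm = TRUE), 0)

  # idempotence
  expect_identical(apply_exclusions(fl2), fl2)
})

test_that("cell medians use the sort-based median conventions", {
  sess <- gen_conflict_session(make_profile(), seed = 2)
  cells <- cell_medians(apply_exclusions(sess))
  expect_equal(nrow(cells), 4)
  # independent sort-based oracle per cell
  fl <- apply_exclusions(sess)
  for (i in seq_len(4)) {
    sel <- fl$keep_rt & fl$prev_congruency == cells$prev_congruency[i] &
      fl$congruency == cells$congruency[i]
    v <- sort(fl$rt_ms[sel])
    n <- length(v)
    med <- if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
    expect_equal(cells$median_rt[i], med)
  }
  # explicit odd / even median conventions on a hand-built session
  congr <- c("congruent", "congruent", "congruent", "congruent",
             "incongruent", "congruent", "incongruent", "incongruent")
  mini <- tibble::tibble(
    subject_id = 1L, trial = 0:7, block = 1L,
    dimension = rep(c("horizontal", "vertical"), 4),
    congruency = congr,
    prev_congruency = c("none", congr[-8]),
    rt_ms = c(999, 400, 500, 600, 400, 700, 600, 800),
    correct = TRUE
  )
  mc <- cell_medians(mini)
  get <- function(p, c) mc$median_rt[mc$prev_congruency == p & mc$congruency == c]
  expect_equal(get("congruent", "congruent"), 500)    # odd cell {400,500,600}
  expect_equal(get("congruent", "incongruent"), 500)  # even cell {400,600}
  expect_equal(get("incongruent", "congruent"), 700)
  expect_equal(get("incongruent", "incongruent"), 800)
})

test_that("gratton index reproduces the worked congruency-effect arithmetic", {
  g <- gratton_index(make_cells(c(450, 540, 460, 530),
                                c(1.75, 3.98, 3.47, 3.72)))
  expect_equal(g$ce_after_congruent, 90)
  expect_equal(g$ce_after_incongruent, 70)
  expect_equal(g$gratton, 20)
  expect_equal(g$error_ce_after_congruent, 2.23)
  expect_equal(g$error_ce_after_incongruent, 0.25)
  expect_equal(g$error_gratton, 1.98)
  # the identity holds by construction
  expect_equal(g$gratton, g$ce_after_congruent - g$ce_after_incongruent)

  flat <- gratton_index(make_cells(rep(500, 4)))
  expect_equal(flat$gratton, 0)
  expect_equal(flat$ce_after_congruent, 0)
})

test_that("the within-subject ANOVA matches aov and the paired-t-squared oracle", {
  set.seed(6)
  cells <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_cells(c(450, 540, 460, 530) + rnorm(4, 0, 20), subject_id = i)
  }))
  res <- rm_anova_2x2(cells, "median_rt")

  # paired-t oracle for the interaction
  g <- gratton_index(cells)$gratton
  tt <- stats::t.test(g / 2)
  Fint <- res$F[res$effect == "congruency:prev_congruency"]
  expect_equal(Fint, unname(tt$statistic)^2, tolerance = 1e-8)

  # full aov oracle for every effect
  d <- cells
  d$id <- factor(d$subject_id)
  d$A <- factor(d$prev_congruency)
  d$B <- factor(d$congruency)
  av <- summary(stats::aov(median_rt ~ A * B + Error(id / (A * B)), data = d))
  expect_equal(res$F[res$effect == "prev_congruency"],
               av[["Error: id:A"]][[1]]["A", "F value"], tolerance = 1e-8)
  expect_equal(res$F[res$effect == "congruency"],
               av[["Error: id:B"]][[1]]["B", "F value"], tolerance = 1e-8)
  expect_equal(Fint, av[["Error: id:A:B"]][[1]]["A:B", "F value"], tolerance = 1e-8)
  expect_true(all(res$df1 == 1 & res$df2 == 9))
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
})

test_that("identical cells across subjects give F = 0 everywhere", {
  cells <- dplyr::bind_rows(lapply(1:8, function(i) {
    make_cells(rep(500, 4), subject_id = i)
  }))
  res <- rm_anova_2x2(cells, "median_rt")
  expect_true(all(res$F == 0))
})

test_that("the null ANOVA keeps its nominal type-I error rate", {
  set.seed(17)
  reject <- vapply(1:1000, function(r) {
    cells <- dplyr::bind_rows(lapply(1:63, function(i) {
      make_cells(500 + rnorm(4, 0, 30), subject_id = i)
    }))
    res <- rm_anova_2x2(cells, "median_rt")
    res$p[res$effect == "congruency:prev_congruency"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(reject) - 0.05), 0.015)
})

test_that("the exclusion-and-median pipeline recovers the generator's cell structure", {
  pop <- gen_population(200, seed = 10)
  seeds <- mindwandr:::spawn_seeds(99, 200)
  sess <- dplyr::bind_rows(lapply(1:200, function(i) {
    gen_conflict_session(pop[i, ], seed = seeds[i])
  }))
  g <- gratton_index(cell_medians(apply_exclusions(sess)))
  expect_lt(abs(mean(g$ce_after_congruent) - 90), 5)
  expect_lt(abs(mean(g$ce_after_incongruent) - 70), 5)
  expect_equal(g$gratton, g$ce_after_congruent - g$ce_after_incongruent)
  expect_equal(g$error_gratton,
               g$error_ce_after_congruent - g$error_ce_after_incongruent)
})
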