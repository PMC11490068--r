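small_pop <- function(seed = 5, n = 30, sd_r_neg = 0.3) {
  generate_reader_population(
    population_config(n_readers = n, sd_r_neg = sd_r_neg, seed = seed),
    mc = mc_config(2e4, seed))
}

small_cfg <- function(seed = 3, n_days = 5L) {
  schedule_config(n_days = n_days, exams_per_day = 960L, batches_per_day = 32L,
                  readers_per_day = 16L, prevalence = 0.01, seed = seed)
}

test_that("schedule config enforces its divisibility invariants", {
  expect_error(schedule_config(readers_per_day = 15),
               class = "doubleread_invalid_argument")
  expect_error(schedule_config(batches_per_day = 30),
               class = "doubleread_invalid_argument")
  expect_error(schedule_config(exams_per_day = 4001),
               class = "doubleread_invalid_argument")
  expect_error(schedule_config(prevalence = 1.5),
               class = "doubleread_invalid_argument")
})

test_that("the default year schedule has the programme-scale totals", {
  gen <- small_pop()
  cfg <- schedule_config(seed = 1)
  sched <- build_year_schedule(cfg, gen$params, "similar_fpr", rates = gen$rates)
  expect_equal(length(sched$days), 365L)
  expect_equal(cfg$n_days * cfg$exams_per_day, 1460000L)
  expect_equal(length(sched$days[[1]]$pair_1), 8L)
  # each pair serves 4 batches of 125 exams
  expect_equal(as.integer(table(sched$days[[1]]$batch_pair)), rep(4L, 8L))
  expect_equal(cfg$exams_per_day %/% cfg$batches_per_day, 125L)
  # every pool reader appears in exactly one pair
  d1 <- sched$days[[1]]
  expect_setequal(c(d1$pair_1, d1$pair_2), d1$pool)
})

test_that("group rates have the exact closed form for identical readers at sigma = 0", {
  r <- -2.2
  a <- plogis(r)
  params <- model_parameters(
    data.frame(reader_id = sprintf("R%02d", 1:16),
               r_neg = rep(r, 16), r_pos = rep(r, 16)),
    sigma_neg = 0, sigma_pos = 0)
  cfg <- small_cfg()
  exams <- generate_exam_stream(cfg, params)
  sched <- build_year_schedule(cfg, params, "random",
                               rates = data.frame(reader_id = params$readers$reader_id,
                                                  tpr = a, fpr = a))
  out <- simulate_strategy(params, sched, exams)
  expect_equal(out$fpr, 2 * a - a^2, tolerance = 1e-12)
  single <- simulate_individual(params, cfg, exams)
  expect_equal(single$fpr, a, tolerance = 1e-12)
})

test_that("all strategies share the exam stream and beat single reading on shared randomness", {
  gen <- small_pop()
  cfg <- small_cfg()
  res <- compare_pairing_strategies(gen$params, cfg, rates = gen$rates,
                                    n_boot = 50)
  expect_equal(nrow(res), 8L)
  expect_equal(length(unique(res$exam_checksum)), 1L)
  ind <- res[res$strategy == "individual", ]
  paired <- res[res$strategy != "individual", ]
  expect_true(all(paired$tpr > ind$tpr))
  expect_true(all(paired$fpr > ind$fpr))
  # concordance categories partition the exams
  n_exams <- cfg$n_days * cfg$exams_per_day
  expect_true(all(paired$concordant_positive + paired$concordant_negative +
                    paired$discordant == n_exams))
})

test_that("p_pair dominates both single-reader probabilities exam by exam", {
  gen <- small_pop(seed = 9)
  cfg <- small_cfg(seed = 11, n_days = 2L)
  exams <- generate_exam_stream(cfg, gen$params)
  sched <- build_year_schedule(cfg, gen$params, "opposite_tpr", rates = gen$rates)
  out <- simulate_strategy(gen$params, sched, exams)
  o <- out$outcomes
  expect_true(all(o$p_pair >= pmax(o$a1, o$a2) - 1e-15))
  expect_equal(o$p_pair, o$a1 + o$a2 - o$a1 * o$a2, tolerance = 1e-12)
})

test_that("simulation is deterministic in the master seed and flags empty strata", {
  gen <- small_pop(seed = 21)
  cfg <- small_cfg(seed = 13, n_days = 2L)
  exams <- generate_exam_stream(cfg, gen$params)
  sched <- build_year_schedule(cfg, gen$params, "random", rates = gen$rates)
  out1 <- simulate_strategy(gen$params, sched, exams)
  sched2 <- build_year_schedule(cfg, gen$params, "random", rates = gen$rates)
  out2 <- simulate_strategy(gen$params, sched2, exams)
  expect_identical(out1$outcomes, out2$outcomes)
  # no positives -> TPR flagged undefined, not fabricated
  exams0 <- exams
  exams0$positive <- FALSE
  out0 <- simulate_strategy(gen$params, sched, exams0)
  expect_true(is.na(out0$tpr))
  expect_false(is.na(out0$fpr))
})

test_that("sampled binary outcomes are consistent with the analytic probabilities", {
  gen <- small_pop(seed = 33)
  cfg <- small_cfg(seed = 17)
  exams <- generate_exam_stream(cfg, gen$params)
  sched <- build_year_schedule(cfg, gen$params, "similar_fpr", rates = gen$rates)
  out <- simulate_strategy(gen$params, sched, exams)
  bin <- sample_binary_outcomes(out, seed = 7)
  n <- nrow(out$outcomes)
  expect_equal(bin$concordant_positive + bin$concordant_negative + bin$discordant, n)
  mu_tp <- sum(out$outcomes$p_pair[out$outcomes$positive])
  var_tp <- sum((out$outcomes$p_pair * (1 - out$outcomes$p_pair))[out$outcomes$positive])
  expect_lt(abs(bin$tp - mu_tp), 3 * sqrt(var_tp))
  # certainty case
  certain <- manual_outcome(c(1, 1), c(TRUE, FALSE))
  certain$outcomes$a1 <- c(1, 1); certain$outcomes$a2 <- c(1, 1)
  cb <- sample_binary_outcomes(certain, seed = 1)
  expect_equal(cb$concordant_positive, 2L)
})

test_that("bootstrap intervals behave at the edges and under Bonferroni adjustment", {
  o <- manual_outcome(rep(0.3, 200), rep(FALSE, 200))
  ci <- bootstrap_group_rates(o, n_boot = 100, seed = 2)
  expect_equal(ci$fpr_lo, 0.3)
  expect_equal(ci$fpr_hi, 0.3)
  expect_true(is.na(ci$tpr_lo))
  # adjusted interval is wider than unadjusted (alpha 0.05/6 ~ 0.00833)
  x <- with_seed(4, runif(500))
  o2 <- manual_outcome(x, rep(FALSE, 500))
  ci_raw <- bootstrap_group_rates(o2, n_boot = 400, n_comparisons = 1, seed = 3)
  ci_adj <- bootstrap_group_rates(o2, n_boot = 400, n_comparisons = 6, seed = 3)
  expect_lt(ci_adj$fpr_lo, ci_raw$fpr_lo)
  expect_gt(ci_adj$fpr_hi, ci_raw$fpr_hi)
})

test_that("recall rate and CDR extrapolation match hand arithmetic", {
  expect_equal(unname(recall_and_cdr(0.8, 0.05, 0.006)),
               c(1000 * (0.006 * 0.8 + 0.994 * 0.05), 4.8))
  expect_equal(unname(recall_and_cdr(1, 0.1, 0.005)["cdr_per_1000"]), 5)
  expect_equal(unname(recall_and_cdr(0.7, 0.1, 0)),
               c(100, 0))
  expect_error(recall_and_cdr(1.2, 0.1, 0.005),
               class = "doubleread_invalid_argument")
})

test_that("similar-metric pairing lowers that metric's group value; opposite does not", {
  gen <- small_pop(seed = 41, n = 24, sd_r_neg = 0.4)
  lower <- 0L; reps <- 30L
  diffs <- vapply(seq_len(reps), function(i) {
    cfg <- schedule_config(n_days = 3L, exams_per_day = 960L,
                           batches_per_day = 32L, prevalence = 0.01,
                           seed = 5000L + i)
    exams <- generate_exam_stream(cfg, gen$params)
    sim <- function(s) simulate_strategy(
      gen$params, build_year_schedule(cfg, gen$params, s, rates = gen$rates), exams)
    c(sim("similar_fpr")$fpr - sim("random")$fpr,
      sim("opposite_fpr")$fpr - sim("random")$fpr)
  }, c(0, 0))
  expect_gt(mean(diffs[1, ] < 0), 0.8)         # similar-FPR below random
  expect_gt(mean(diffs[2, ]), mean(diffs[1, ]))  # opposite does not lower it
})
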