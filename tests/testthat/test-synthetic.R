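test_that("reader populations are reproducible with the configured size and association", {
  cfg <- population_config(n_readers = 16, seed = 3)
  gen <- generate_reader_population(cfg, mc = mc_config(2e4, 3))
  expect_equal(nrow(gen$params$readers), 16L)
  expect_false(anyDuplicated(gen$params$readers$reader_id) > 0)
  gen2 <- generate_reader_population(cfg, mc = mc_config(2e4, 3))
  expect_identical(gen$params$readers, gen2$params$readers)
  # configured TPR-FPR association shows up in the implied rates
  big <- generate_reader_population(
    population_config(n_readers = 500, cor_r = 0.8, seed = 11),
    mc = mc_config(1e4, 11))
  expect_gt(cor(big$rates$tpr, big$rates$fpr), 0.4)
  expect_error(population_config(n_readers = 4, cor_r = 1.5),
               class = "doubleread_invalid_argument")
  expect_error(population_config(n_readers = 4, sd_r_neg = -1),
               class = "doubleread_invalid_argument")
})

test_that("every exam is double read with a consistent case status", {
  gen <- generate_reader_population(population_config(n_readers = 8, seed = 2),
                                    mc = mc_config(1e4, 2))
  rec <- generate_reading_records(gen$params,
                                  dataset_config(n_exams = 5000, seed = 4))
  expect_equal(nrow(rec), 10000L)
  per_exam <- table(rec$exam_id)
  expect_true(all(per_exam == 2L))
  status_per_exam <- tapply(rec$case_status, rec$exam_id,
                            function(s) length(unique(s)))
  expect_true(all(status_per_exam == 1L))
  readers_per_exam <- tapply(rec$reader_id, rec$exam_id,
                             function(r) length(unique(r)))
  expect_true(all(readers_per_exam == 2L))
})

test_that("empirical rates match the model's marginal rates (one pair, many negatives)", {
  params <- model_parameters(
    data.frame(reader_id = c("A", "B"), r_neg = c(-2.5, -3.2), r_pos = c(1, 1)),
    sigma_neg = 1, sigma_pos = 1.5)
  rec <- generate_reading_records(
    params, dataset_config(n_exams = 50000, prevalence = 1e-9, seed = 8))
  counts <- aggregate_reading_records(rec)
  mc <- mc_config(2e5, 99)
  for (id in c("A", "B")) {
    row <- counts$readers[counts$readers$reader_id == id, ]
    a_model <- as.numeric(marginal_abnormal_rate(
      params$readers$r_neg[params$readers$reader_id == id], 1, mc))
    se <- sqrt(a_model * (1 - a_model) / row$k_neg)
    expect_lt(abs(row$a_neg / row$k_neg - a_model), 3 * se)
  }
  d_model <- as.numeric(marginal_disagreement(-2.5, -3.2, 1, mc))
  k <- counts$pairs$k_neg
  expect_lt(abs(counts$pairs$d_neg / k - d_model),
            3 * sqrt(d_model * (1 - d_model) / k))
})

test_that("the positive fraction tracks the configured prevalence", {
  gen <- generate_reader_population(population_config(n_readers = 4, seed = 5),
                                    mc = mc_config(1e4, 5))
  rec <- generate_reading_records(
    gen$params, dataset_config(n_exams = 10000, prevalence = 0.5, seed = 6))
  frac <- mean(rec$case_status[!duplicated(rec$exam_id)] == "positive")
  expect_gte(frac, 0.48)
  expect_lte(frac, 0.52)
})

test_that("exclusion criteria drop degenerate readers and under-volume pairs", {
  readers <- data.frame(
    reader_id = c("A", "B", "C", "D"),
    k_neg = c(100, 100, 100, 100), a_neg = c(5, 0, 4, 3),    # B: no FP
    k_pos = c(30, 30, 30, 30), a_pos = c(20, 10, 30, 15))    # C: all TP
  pairs <- data.frame(
    reader_id_1 = c("A", "A", "A"), reader_id_2 = c("B", "C", "D"),
    k_neg = c(50, 50, 50), d_neg = c(3, 2, 4),
    k_pos = c(20, 17, 16), d_pos = c(2, 1, 3))
  counts <- observed_counts(readers, pairs)
  out <- apply_exclusion_criteria(counts, 17)
  expect_setequal(out$readers$reader_id, c("A", "D"))
  # A-B dropped with reader B, A-C dropped with reader C,
  # A-D dropped for 16 < 17 positive reads
  expect_equal(nrow(out$pairs), 0L)
  out16 <- apply_exclusion_criteria(counts, 16)
  expect_equal(nrow(out16$pairs), 1L)  # A-D kept at threshold 16
  # pass-through when everything qualifies, and idempotence
  clean <- observed_counts(readers[c(1, 4), ], pairs[3, ])
  once <- apply_exclusion_criteria(clean, 16)
  expect_identical(once$readers, clean$readers)
  expect_identical(apply_exclusion_criteria(once, 16)$pairs, once$pairs)
})

test_that("record-level exclusion cascades and recomputes counts", {
  gen <- generate_reader_population(population_config(n_readers = 6, seed = 13),
                                    mc = mc_config(1e4, 13))
  rec <- generate_reading_records(
    gen$params, dataset_config(n_exams = 20000, prevalence = 0.01, seed = 14))
  counts <- aggregate_reading_records(rec)
  out <- apply_exclusion_criteria(counts, 17, records = rec)
  expect_true(all(out$pairs$k_pos >= 17))
  expect_true(all(out$readers$a_pos >= 1 & out$readers$a_neg >= 1))
  expect_true(all(out$readers$a_pos < out$readers$k_pos))
  surviving <- attr(out, "records")
  expect_identical(unclass(aggregate_reading_records(surviving))$readers,
                   unclass(out)$readers)
})

test_that("all-excluded input raises a dedicated error", {
  counts <- observed_counts(
    data.frame(reader_id = "A", k_neg = 10, a_neg = 0, k_pos = 5, a_pos = 5),
    data.frame(reader_id_1 = character(), reader_id_2 = character(),
               k_neg = integer(), d_neg = integer(),
               k_pos = integer(), d_pos = integer()))
  expect_error(apply_exclusion_criteria(counts), class = "doubleread_all_excluded")
})

test_that("generated data refitted recovers the generating marginal rates", {
  h <- recovery_harness_counts(n_exams = 50000L, seed = 57L)
  counts <- apply_exclusion_criteria(h$counts, 10L)
  fit <- fit_model(counts, fit_config(mc = mc_config(1e4, 6)))
  i <- match(fit$rates$reader_id, h$truth$rates$reader_id)
  expect_gt(cor(fit$rates$fpr, h$truth$rates$fpr[i]), 0.9)
  expect_gt(cor(fit$rates$tpr, h$truth$rates$tpr[i]), 0.9)
})
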