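one_reader_counts <- function(k_pos = 10, a_pos = 5) {
  observed_counts(
    data.frame(reader_id = "R1", k_neg = 0, a_neg = 0, k_pos = k_pos, a_pos = a_pos),
    data.frame(reader_id_1 = character(), reader_id_2 = character(),
               k_neg = integer(), d_neg = integer(),
               k_pos = integer(), d_pos = integer()))
}

test_that("the NLL reproduces the binomial closed form at sigma = 0", {
  params <- model_parameters(
    data.frame(reader_id = "R1", r_neg = 0, r_pos = 0),
    sigma_neg = 0, sigma_pos = 0)
  nll <- negative_log_likelihood(params, one_reader_counts(), mc_config(10, 1))
  expect_equal(nll, -10 * log(0.5), tolerance = 1e-12)  # 6.9315
  # minimized at the binomial MLE r_pos = qlogis(1/2) = 0
  grid <- seq(-1, 1, by = 0.05)
  vals <- vapply(grid, function(r) {
    p <- model_parameters(data.frame(reader_id = "R1", r_neg = 0, r_pos = r),
                          sigma_neg = 0, sigma_pos = 0)
    negative_log_likelihood(p, one_reader_counts(), mc_config(10, 1))
  }, 0)
  expect_equal(grid[which.min(vals)], 0)
})

test_that("a pair term with matched disagreement is minimized at the matching parameters", {
  # two identical readers, sigma = 0, pair disagreement exactly 2a(1-a)
  mk <- function(r) model_parameters(
    data.frame(reader_id = c("A", "B"), r_neg = c(0, 0), r_pos = c(r, r)),
    sigma_neg = 0, sigma_pos = 0)
  a_hat <- plogis(0.4)
  d_hat <- 2 * a_hat * (1 - a_hat)
  counts <- observed_counts(
    data.frame(reader_id = c("A", "B"), k_neg = c(0, 0), a_neg = c(0, 0),
               k_pos = c(1000, 1000), a_pos = round(1000 * a_hat)),
    data.frame(reader_id_1 = "A", reader_id_2 = "B", k_neg = 0, d_neg = 0,
               k_pos = 1000, d_pos = round(1000 * d_hat)))
  grid <- seq(0.1, 0.7, by = 0.05)
  vals <- vapply(grid, function(r)
    negative_log_likelihood(mk(r), counts, mc_config(10, 1)), 0)
  expect_equal(grid[which.min(vals)], 0.4, tolerance = 0.051)
  # pair term strictly penalizes parameters whose implied d differs from d_hat
  expect_true(all(vals[grid != 0.4] > min(vals)))
})

test_that("degenerate marginal rates signal degenerate-likelihood", {
  params <- model_parameters(
    data.frame(reader_id = "R1", r_neg = 0, r_pos = 50),
    sigma_neg = 0, sigma_pos = 0)
  expect_error(negative_log_likelihood(params, one_reader_counts(), mc_config(10, 1)),
               class = "doubleread_degenerate_likelihood")
})

test_that("fitting without pair data is not identifiable", {
  expect_error(fit_model(one_reader_counts(k_pos = 10, a_pos = 5)),
               class = "doubleread_not_identifiable")
})

test_that("fitted rates match a brute-force grid search on a tiny sigma = 0 instance", {
  # counts consistent with independent readers, so the optimum sits at sigma -> 0
  counts <- observed_counts(
    data.frame(reader_id = c("A", "B"), k_neg = c(4, 4), a_neg = c(2, 3),
               k_pos = c(4, 4), a_pos = c(2, 2)),
    data.frame(reader_id_1 = "A", reader_id_2 = "B",
               k_neg = 4, d_neg = 2, k_pos = 4, d_pos = 2))
  fit <- fit_model(counts, fit_config(f_tol = 1e-8, mc = mc_config(5e3, 2),
                                      max_iterations = 500))
  # brute force over (rA, rB) at sigma = 0, negative class
  grid <- seq(-3, 3, by = 0.01)
  neg_ll <- function(rA, rB) {
    aA <- plogis(rA); aB <- plogis(rB)
    d <- aA + aB - 2 * aA * aB
    -(2 * log(aA) + 2 * log(1 - aA) + 3 * log(aB) + 1 * log(1 - aB) +
        2 * log(d) + 2 * log(1 - d))
  }
  vals <- outer(grid, grid, Vectorize(neg_ll))
  best <- arrayInd(which.min(vals), dim(vals))
  expect_lt(abs(plogis(grid[best[1]]) - fit$rates$fpr[fit$rates$reader_id == "A"]), 0.01)
  expect_lt(abs(plogis(grid[best[2]]) - fit$rates$fpr[fit$rates$reader_id == "B"]), 0.01)
})

test_that("the Powell NLL trace is monotone and ends at or below the initial value", {
  h <- recovery_harness_counts(n_exams = 20000L, seed = 7L)
  counts <- apply_exclusion_criteria(h$counts, 5L)
  fit <- fit_model(counts, fit_config(mc = mc_config(5e3, 3)))
  expect_true(all(diff(fit$trace_neg) <= 1e-9))
  expect_true(all(diff(fit$trace_pos) <= 1e-9))
  expect_lte(fit$nll_by_class["neg"], fit$nll_init["neg"])
  expect_lte(fit$nll_by_class["pos"], fit$nll_init["pos"])
})

test_that("refitting with a different MC seed moves rates by less than 3 combined MC SEs", {
  h <- recovery_harness_counts(n_exams = 30000L, seed = 19L)
  counts <- apply_exclusion_criteria(h$counts, 5L)
  fit1 <- fit_model(counts, fit_config(f_tol = 1e-6, mc = mc_config(2e4, 101)))
  fit2 <- fit_model(counts, fit_config(f_tol = 1e-6, mc = mc_config(2e4, 202)))
  se_of <- function(fit, seed) {
    vapply(seq_len(nrow(fit$rates)), function(i) {
      attr(marginal_abnormal_rate(fit$params$readers$r_neg[i],
                                  fit$params$sigma_neg,
                                  mc_config(2e4, seed)), "mc_se")
    }, 0)
  }
  se <- sqrt(se_of(fit1, 101)^2 + se_of(fit2, 202)^2)
  expect_true(all(abs(fit1$rates$fpr - fit2$rates$fpr) < 3 * se))
})

test_that("modeled pair disagreement predicts held-out disagreement within binomial noise", {
  h <- recovery_harness_counts(n_exams = 40000L, seed = 23L)
  counts <- apply_exclusion_criteria(h$counts, 5L)
  fit <- fit_model(counts, fit_config(mc = mc_config(1e4, 5)))
  held <- generate_reading_records(
    h$truth$params, dataset_config(n_exams = 40000L, prevalence = 0.0099,
                                   pair_scheme = "chained", seed = 999L))
  held_counts <- aggregate_reading_records(held)
  key <- paste(held_counts$pairs$reader_id_1, held_counts$pairs$reader_id_2)
  fkey <- paste(fit$pair_disagreement$reader_id_1, fit$pair_disagreement$reader_id_2)
  i <- match(key, fkey)
  d_model <- fit$pair_disagreement$dr_neg[i]
  k <- held_counts$pairs$k_neg
  d_obs <- held_counts$pairs$d_neg / k
  expect_true(all(abs(d_obs - d_model) < 4 * sqrt(d_model * (1 - d_model) / k)))
})

test_that("evaluate_fit returns 1 for a perfect fit and NA for degenerate inputs", {
  h <- recovery_harness_counts(n_exams = 20000L, seed = 31L)
  counts <- apply_exclusion_criteria(h$counts, 5L)
  fit <- fit_model(counts, fit_config(mc = mc_config(5e3, 3)))
  # perfect fit: replace modeled rates with the adjusted observed rates
  obs <- direct_rates(counts)
  fake <- fit
  fake$rates$tpr <- obs$readers$tpr
  fake$rates$fpr <- obs$readers$fpr
  fake$pair_disagreement$dr_neg <- obs$pairs$dr_neg
  fake$pair_disagreement$dr_pos <- obs$pairs$dr_pos
  diag <- evaluate_fit(fake, counts)
  expect_equal(unname(diag["pearson_tpr"]), 1)
  expect_equal(unname(diag["pearson_disagree_neg"]), 1)
  # zero-variance modeled rates are undefined, not 0
  fake$rates$tpr <- rep(0.5, nrow(fake$rates))
  expect_true(is.na(evaluate_fit(fake, counts)["pearson_tpr"]))
})
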