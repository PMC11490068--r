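# Independent oracles and tiny fixtures used across the suite.

# 200-node Gauss-Hermite quadrature for E[plogis(r + sigma C)], C ~ N(0,1):
# the deterministic reference the Monte Carlo integrals are checked against.
gh_nodes <- pracma::gaussHermite(200)

gh_marginal_rate <- function(r, sigma) {
  sum(gh_nodes$w * stats::plogis(r + sigma * sqrt(2) * gh_nodes$x)) / sqrt(pi)
}

gh_disagreement <- function(r1, r2, sigma) {
  a1 <- stats::plogis(r1 + sigma * sqrt(2) * gh_nodes$x)
  a2 <- stats::plogis(r2 + sigma * sqrt(2) * gh_nodes$x)
  sum(gh_nodes$w * (a1 * (1 - a2) + a2 * (1 - a1))) / sqrt(pi)
}

# Hand-checkable 8-row double-read fixture: two readers, four exams.
toy_records <- function() {
  data.frame(
    exam_id = rep(c("e1", "e2", "e3", "e4"), each = 2L),
    case_status = rep(c("negative", "negative", "positive", "positive"), each = 2L),
    reader_id = rep(c("R1", "R2"), 4L),
    decision = c(1L, 0L, 0L, 0L, 1L, 1L, 0L, 1L),
    stringsAsFactors = FALSE)
}

# Enumerate all perfect matchings of an even-sized pool; return the minimal
# total within-pair absolute metric difference (brute-force reference for
# similarity_pairing optimality).
min_matching_cost <- function(metric) {
  enum <- function(idx) {
    if (length(idx) == 0L) return(0)
    first <- idx[1]
    rest <- idx[-1]
    min(vapply(seq_along(rest), function(i) {
      abs(metric[first] - metric[rest[i]]) + enum(rest[-i])
    }, 0))
  }
  enum(seq_along(metric))
}

matching_cost <- function(pairs, metric) {
  sum(abs(metric[pairs$reader_id_1] - metric[pairs$reader_id_2]))
}

# Minimal strategy_outcome for direct tests of the inference helpers.
manual_outcome <- function(p_pair, positive) {
  structure(list(outcomes = data.frame(p_pair = p_pair, positive = positive),
                 tpr = if (any(positive)) mean(p_pair[positive]) else NA_real_,
                 fpr = if (any(!positive)) mean(p_pair[!positive]) else NA_real_,
                 strategy = "manual", exam_checksum = 0),
            class = "strategy_outcome")
}

# Parameter-recovery harness shared by the fitting tests and the acceptance
# suite: records from a known 10-reader population read in chained pairs.
recovery_harness_counts <- function(n_exams = 101000L, seed = 42L) {
  truth <- with_seed_readers(seed)
  cfg <- dataset_config(n_exams = n_exams, prevalence = 0.0099,
                        pair_scheme = "chained", seed = seed + 1L)
  records <- generate_reading_records(truth$params, cfg)
  counts <- aggregate_reading_records(records)
  list(truth = truth, counts = counts, records = records)
}

with_seed_readers <- function(seed) {
  cfg <- population_config(n_readers = 10L, mean_r_neg = -3.3, sd_r_neg = 0.3,
                           mean_r_pos = 1.0, sd_r_pos = 0.5, cor_r = 0.6,
                           sigma_neg = 1.0, sigma_pos = 1.5, seed = seed)
  generate_reader_population(cfg, mc = mc_config(2e5, seed))
}
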