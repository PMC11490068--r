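#' Screening-programme schedule configuration
#'
#' Defaults reproduce a year-long national-programme workload: 365 screening
#' days of 4,000 examinations in 32 batches, a pool of 16 readers per day
#' forming 8 pairs, so each pair reads 4 batches of 125 exams and the year
#' totals 1,460,000 examinations.
#'
#' @param n_days Number of screening days (default 365).
#' @param exams_per_day Examinations per day (default 4,000), divisible by
#'   `batches_per_day`.
#' @param batches_per_day Batches per day (default 32), divisible by the
#'   number of pairs.
#' @param readers_per_day Readers drawn per day (default 16, must be even).
#' @param prevalence Positive-case probability (default 0.006).
#' @param seed Master seed; sub-streams for reader pools, exam stream, random
#'   pairing, decision sampling and bootstrap are derived from it.
#' @return Object of class `schedule_config`.
#' @export
schedule_config <- function(n_days = 365L, exams_per_day = 4000L,
                            batches_per_day = 32L, readers_per_day = 16L,
                            prevalence = 0.006, seed = 1L) {
  if (readers_per_day < 2 || readers_per_day %% 2 != 0)
    stop_invalid("readers_per_day must be even and >= 2")
  n_pairs <- readers_per_day %/% 2
  if (batches_per_day %% n_pairs != 0)
    stop_invalid("batches_per_day must be divisible by readers_per_day / 2")
  if (exams_per_day %% batches_per_day != 0)
    stop_invalid("exams_per_day must be divisible by batches_per_day")
  if (prevalence <= 0 || prevalence >= 1) stop_invalid("prevalence must be in (0, 1)")
  if (n_days < 1) stop_invalid("n_days must be >= 1")
  structure(list(n_days = as.integer(n_days),
                 exams_per_day = as.integer(exams_per_day),
                 batches_per_day = as.integer(batches_per_day),
                 readers_per_day = as.integer(readers_per_day),
                 n_pairs = as.integer(n_pairs),
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "schedule_config")
}

# The day-by-day reader pools, shared by all strategies: drawn from one
# dedicated stream so changing the pairing strategy cannot perturb them.
draw_reader_pools <- function(cfg, n_readers) {
  if (n_readers < cfg$readers_per_day)
    stop_invalid("population smaller than readers_per_day")
  with_seed(derive_seed(cfg$seed, 41L), {
    vapply(seq_len(cfg$n_days),
           function(d) sample.int(n_readers, cfg$readers_per_day),
           integer(cfg$readers_per_day))
  })  # readers_per_day x n_days matrix of population row indices
}

#' Build the year schedule for one pairing strategy
#'
#' For each day: draw the day's reader pool (without replacement, from a
#' pool stream independent of the strategy), form pairs by the strategy using
#' the MODELED marginal TPR/FPR as metrics, assign batches to pairs in
#' balanced round-robin (every pair gets `batches_per_day / n_pairs`
#' batches), and exams to batches in equal contiguous blocks.
#'
#' @param cfg [schedule_config()].
#' @param params [model_parameters()] for the reader population.
#' @param strategy One of [pairing_strategies()].
#' @param rates Optional data frame `reader_id`, `tpr`, `fpr` of modeled
#'   marginal rates (computed from `params` if omitted).
#' @param composite_slope `"per_day"` (regression over the day's pool,
#'   default) or `"global"` (one slope over the whole population) for the
#'   composite strategies.
#' @return Object of class `year_schedule`: list of per-day schedules, each
#'   with `day`, `pool` (reader indices into `params$readers`), `pair_1`,
#'   `pair_2` (reader indices per pair), `batch_pair` (pair index per batch);
#'   plus the config and strategy.
#' @export
build_year_schedule <- function(cfg, params, strategy, rates = NULL,
                                composite_slope = c("per_day", "global")) {
  stopifnot(inherits(cfg, "schedule_config"), inherits(params, "model_parameters"))
  composite_slope <- match.arg(composite_slope)
  if (!strategy %in% pairing_strategies())
    stop_invalid("unknown strategy: ", strategy)
  if (is.null(rates))
    rates <- reader_marginal_rates(params, mc_config(1e5, derive_seed(cfg$seed, 40L)))
  idx <- match(params$readers$reader_id, rates$reader_id)
  if (anyNA(idx)) stop_invalid("rates must cover every reader in params")
  tpr_all <- stats::setNames(rates$tpr[idx], params$readers$reader_id)
  fpr_all <- stats::setNames(rates$fpr[idx], params$readers$reader_id)

  if (composite_slope == "global" && strategy %in%
      c("similar_composite", "opposite_composite")) {
    score_all <- composite_scores(tpr_all, fpr_all)
  } else score_all <- NULL

  pools <- draw_reader_pools(cfg, nrow(params$readers))
  n_batch_per_pair <- cfg$batches_per_day %/% cfg$n_pairs
  batch_pair <- rep(seq_len(cfg$n_pairs), times = n_batch_per_pair)  # round-robin
  ids <- params$readers$reader_id
  days <- lapply(seq_len(cfg$n_days), function(d) {
    pool <- pools[, d]
    pool_ids <- ids[pool]
    pr <- if (!is.null(score_all)) {
      sc <- score_all[pool_ids]
      if (strategy == "similar_composite") similarity_pairing(sc)
      else opposite_pairing(sc)
    } else {
      pair_pool(strategy, tpr_all[pool_ids], fpr_all[pool_ids],
                seed = derive_seed(cfg$seed, 42000L + d))
    }
    list(day = d, pool = pool,
         pair_1 = match(pr$reader_id_1, ids),
         pair_2 = match(pr$reader_id_2, ids),
         batch_pair = batch_pair)
  })
  structure(list(days = days, cfg = cfg, strategy = strategy),
            class = "year_schedule")
}

#' Generate the shared exam stream for a schedule
#'
#' Case status and the latent case effect of every examination of the year,
#' drawn from streams derived from the schedule seed only — so all pairing
#' strategies simulated under the same config see identical examinations.
#'
#' @param cfg [schedule_config()].
#' @param params [model_parameters()] (supplies the case-effect SDs).
#' @return Data frame with one row per exam: `day`, `batch`, `positive`
#'   (logical), `case_effect`.
#' @export
generate_exam_stream <- function(cfg, params) {
  stopifnot(inherits(cfg, "schedule_config"), inherits(params, "model_parameters"))
  n <- cfg$n_days * cfg$exams_per_day
  per_batch <- cfg$exams_per_day %/% cfg$batches_per_day
  day <- rep(seq_len(cfg$n_days), each = cfg$exams_per_day)
  batch <- rep(rep(seq_len(cfg$batches_per_day), each = per_batch), cfg$n_days)
  pos <- with_seed(derive_seed(cfg$seed, 43L), stats::runif(n) < cfg$prevalence)
  ce <- numeric(n)
  n_pos <- sum(pos)
  if (n_pos > 0)
    ce[pos] <- with_seed(derive_seed(cfg$seed, 44L),
                         stats::rnorm(n_pos, 0, params$sigma_pos))
  if (n_pos < n)
    ce[!pos] <- with_seed(derive_seed(cfg$seed, 45L),
                          stats::rnorm(n - n_pos, 0, params$sigma_neg))
  data.frame(day = day, batch = batch, positive = pos, case_effect = ce)
}

exam_stream_checksum <- function(exams) {
  sum(exams$positive) + round(sum(exams$case_effect), 6)
}

#' Simulate double reading under one pairing schedule
#'
#' For every exam the two conditional abnormal probabilities are evaluated at
#' the exam's shared case effect (`a = plogis(r + C)`, with `r` the reader's
#' effect for the exam's case class) and combined into the paired positive
#' probability `a1 + a2 - a1 a2`. The group endpoints are the means of the
#' paired probability over positive exams (TPR) and negative exams (FPR).
#'
#' @param params [model_parameters()].
#' @param schedule A `year_schedule` from [build_year_schedule()].
#' @param exams The shared exam stream from [generate_exam_stream()].
#' @return Object of class `strategy_outcome`: `outcomes` (per-exam data
#'   frame with reader indices, `a1`, `a2`, `p_pair`), `tpr`, `fpr` (NA when
#'   a stratum is empty), `strategy`, `exam_checksum`.
#' @export
simulate_strategy <- function(params, schedule, exams) {
  stopifnot(inherits(schedule, "year_schedule"), inherits(params, "model_parameters"))
  cfg <- schedule$cfg
  if (nrow(exams) != cfg$n_days * cfg$exams_per_day)
    stop_invalid("exam stream does not match the schedule config")
  n_pairs <- cfg$n_pairs
  # day x pair lookup matrices of reader indices
  R1 <- vapply(schedule$days, function(d) d$pair_1, integer(n_pairs))
  R2 <- vapply(schedule$days, function(d) d$pair_2, integer(n_pairs))
  pair_idx <- schedule$days[[1]]$batch_pair[exams$batch]
  i1 <- R1[cbind(pair_idx, exams$day)]
  i2 <- R2[cbind(pair_idx, exams$day)]
  r1 <- ifelse(exams$positive, params$readers$r_pos[i1], params$readers$r_neg[i1])
  r2 <- ifelse(exams$positive, params$readers$r_pos[i2], params$readers$r_neg[i2])
  a1 <- stats::plogis(r1 + exams$case_effect)
  a2 <- stats::plogis(r2 + exams$case_effect)
  p_pair <- a1 + a2 - a1 * a2
  outcomes <- data.frame(day = exams$day, batch = exams$batch,
                         positive = exams$positive,
                         reader_1 = i1, reader_2 = i2,
                         a1 = a1, a2 = a2, p_pair = p_pair)
  structure(list(outcomes = outcomes,
                 tpr = if (any(exams$positive)) mean(p_pair[exams$positive]) else NA_real_,
                 fpr = if (any(!exams$positive)) mean(p_pair[!exams$positive]) else NA_real_,
                 strategy = schedule$strategy,
                 exam_checksum = exam_stream_checksum(exams)),
            class = "strategy_outcome")
}

#' Simulate single reading on the same exams
#'
#' Each exam is read by exactly one of the day's pool readers; batches are
#' assigned to readers round-robin so each reader reads
#' `batches_per_day / readers_per_day` batches. The group endpoints are the
#' means of the single conditional probability by case class.
#'
#' @param params [model_parameters()].
#' @param cfg [schedule_config()].
#' @param exams Shared exam stream ([generate_exam_stream()]).
#' @return A `strategy_outcome` with `strategy = "individual"`; the per-exam
#'   `a1` holds the single reader's probability and `p_pair` equals it.
#' @export
simulate_individual <- function(params, cfg, exams) {
  stopifnot(inherits(cfg, "schedule_config"), inherits(params, "model_parameters"))
  if (cfg$batches_per_day %% cfg$readers_per_day != 0)
    stop_invalid("batches_per_day must be divisible by readers_per_day for single reading")
  pools <- draw_reader_pools(cfg, nrow(params$readers))
  batch_reader <- rep(seq_len(cfg$readers_per_day),
                      times = cfg$batches_per_day %/% cfg$readers_per_day)
  slot <- batch_reader[exams$batch]
  i1 <- pools[cbind(slot, exams$day)]
  r1 <- ifelse(exams$positive, params$readers$r_pos[i1], params$readers$r_neg[i1])
  a1 <- stats::plogis(r1 + exams$case_effect)
  outcomes <- data.frame(day = exams$day, batch = exams$batch,
                         positive = exams$positive,
                         reader_1 = i1, reader_2 = NA_integer_,
                         a1 = a1, a2 = NA_real_, p_pair = a1)
  structure(list(outcomes = outcomes,
                 tpr = if (any(exams$positive)) mean(a1[exams$positive]) else NA_real_,
                 fpr = if (any(!exams$positive)) mean(a1[!exams$positive]) else NA_real_,
                 strategy = "individual",
                 exam_checksum = exam_stream_checksum(exams)),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("Strategy '%s': %s exams\n", x$strategy,
              format(nrow(x$outcomes), big.mark = ",")))
  cat(sprintf("  group TPR = %s, group FPR = %s\n",
              ifelse(is.na(x$tpr), "undefined (no positives)", sprintf("%.4f", x$tpr)),
              ifelse(is.na(x$fpr), "undefined (no negatives)", sprintf("%.4f", x$fpr))))
  invisible(x)
}

#' Sample binary decisions and classify paired assessments
#'
#' Draws each reader's recall decision from a Bernoulli at their conditional
#' probability and classifies every exam as concordant positive, concordant
#' negative, or discordant. Under the pairing rule, an exam is flagged when
#' any reader flags it, so true positives are flagged positive exams and
#' false positives are flagged negative exams.
#'
#' @param outcome A `strategy_outcome` from [simulate_strategy()].
#' @param seed Integer seed for the decision stream.
#' @return List with `tp`, `fp`, `concordant_positive`, `concordant_negative`,
#'   `discordant` counts and the per-exam `decisions` matrix.
#' @export
sample_binary_outcomes <- function(outcome, seed) {
  stopifnot(inherits(outcome, "strategy_outcome"))
  o <- outcome$outcomes
  n <- nrow(o)
  single <- all(is.na(o$a2))
  u <- with_seed(seed, stats::runif(if (single) n else 2L * n))
  d1 <- u[seq_len(n)] < o$a1
  d2 <- if (single) d1 else u[n + seq_len(n)] < o$a2
  flagged <- d1 | d2
  list(tp = sum(flagged & o$positive),
       fp = sum(flagged & !o$positive),
       concordant_positive = sum(d1 & d2),
       concordant_negative = sum(!d1 & !d2),
       discordant = sum(d1 != d2),
       decisions = cbind(reader_1 = d1, reader_2 = if (single) NA else d2))
}

#' Bootstrap confidence intervals for group TPR and FPR
#'
#' Percentile intervals from resampling exams with replacement, stratified by
#' case status (TPR and FPR are means over disjoint strata). With
#' `n_comparisons > 1` the level is Bonferroni-adjusted to
#' `1 - (1 - conf) / n_comparisons` (6 when contrasting the similar/opposite
#' strategies against random, 7 when contrasting all strategies against
#' individual reading).
#'
#' @param outcome A `strategy_outcome`.
#' @param n_boot Number of bootstrap resamples (default 1,000).
#' @param conf Base confidence level (default 0.95).
#' @param n_comparisons Bonferroni divisor (default 1 = unadjusted).
#' @param seed Integer seed for the resampling stream.
#' @return List with `tpr`, `fpr` point estimates and `tpr_lo`, `tpr_hi`,
#'   `fpr_lo`, `fpr_hi`; `NA` for an empty stratum is not fabricated.
#' @export
bootstrap_group_rates <- function(outcome, n_boot = 1000L, conf = 0.95,
                                  n_comparisons = 1L, seed = 1L) {
  stopifnot(inherits(outcome, "strategy_outcome"))
  if (n_boot < 1) stop_invalid("n_boot must be >= 1")
  if (n_comparisons < 1) stop_invalid("n_comparisons must be >= 1")
  alpha <- (1 - conf) / n_comparisons
  o <- outcome$outcomes
  boot_stratum <- function(x, s) {
    if (length(x) == 0L) return(c(NA_real_, NA_real_))
    means <- with_seed(s, {
      n <- length(x)
      vapply(seq_len(n_boot), function(b) mean(x[sample.int(n, n, replace = TRUE)]), 0)
    })
    stats::quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  }
  ci_pos <- boot_stratum(o$p_pair[o$positive], derive_seed(seed, 51L))
  ci_neg <- boot_stratum(o$p_pair[!o$positive], derive_seed(seed, 52L))
  list(tpr = outcome$tpr, tpr_lo = ci_pos[1], tpr_hi = ci_pos[2],
       fpr = outcome$fpr, fpr_lo = ci_neg[1], fpr_hi = ci_neg[2])
}

#' Recall rate and cancer detection rate per 1,000 examinations
#'
#' Extrapolates group TPR and FPR to programme-level endpoints:
#' `RR/1000 = 1000 (prevalence * TPR + (1 - prevalence) * FPR)` and
#' `CDR/1000 = 1000 * prevalence * TPR`.
#'
#' @param tpr,fpr Group rates in \[0, 1\].
#' @param prevalence Positive-case probability in \[0, 1\].
#' @return Named numeric vector `rr_per_1000`, `cdr_per_1000`.
#' @examples
#' recall_and_cdr(0.8, 0.05, 0.006)  # CDR 4.8, RR ~54.5 per 1,000
#' @export
recall_and_cdr <- function(tpr, fpr, prevalence) {
  check_prob(tpr, "tpr"); check_prob(fpr, "fpr"); check_prob(prevalence, "prevalence")
  c(rr_per_1000 = 1000 * (prevalence * tpr + (1 - prevalence) * fpr),
    cdr_per_1000 = 1000 * prevalence * tpr)
}

#' Compare all pairing strategies plus individual reading
#'
#' Runs the full pipeline for the seven pairing strategies and single
#' reading on one shared exam stream and shared daily reader pools (the only
#' difference between strategies is the pairing), with bootstrap confidence
#' intervals, sampled TP/FP counts, and RR/CDR extrapolation.
#'
#' @param params [model_parameters()].
#' @param cfg [schedule_config()].
#' @param strategies Strategies to run (default all seven).
#' @param rates Optional modeled marginal rates (computed if omitted).
#' @param n_boot Bootstrap resamples (default 1,000).
#' @param n_comparisons Bonferroni divisor for the CIs (default 6, the
#'   six strategy-vs-random contrasts).
#' @param include_individual Add a single-reading row (default TRUE).
#' @return Data frame, one row per strategy (plus `individual`): rates, CIs,
#'   sampled `tp`/`fp`, concordance counts, `rr_per_1000`, `cdr_per_1000`,
#'   and the shared `exam_checksum`.
#' @export
compare_pairing_strategies <- function(params, cfg,
                                       strategies = pairing_strategies(),
                                       rates = NULL, n_boot = 1000L,
                                       n_comparisons = 6L,
                                       include_individual = TRUE) {
  stopifnot(inherits(params, "model_parameters"), inherits(cfg, "schedule_config"))
  if (is.null(rates))
    rates <- reader_marginal_rates(params, mc_config(1e5, derive_seed(cfg$seed, 40L)))
  exams <- generate_exam_stream(cfg, params)
  run_one <- function(strategy, outcome) {
    ci <- bootstrap_group_rates(outcome, n_boot = n_boot,
                                n_comparisons = n_comparisons,
                                seed = derive_seed(cfg$seed, 46L))
    bin <- sample_binary_outcomes(outcome, derive_seed(cfg$seed, 47L))
    rc <- recall_and_cdr(ifelse(is.na(outcome$tpr), 0, outcome$tpr),
                         ifelse(is.na(outcome$fpr), 0, outcome$fpr),
                         cfg$prevalence)
    data.frame(strategy = strategy,
               tpr = outcome$tpr, tpr_lo = ci$tpr_lo, tpr_hi = ci$tpr_hi,
               fpr = outcome$fpr, fpr_lo = ci$fpr_lo, fpr_hi = ci$fpr_hi,
               tp = bin$tp, fp = bin$fp,
               concordant_positive = bin$concordant_positive,
               concordant_negative = bin$concordant_negative,
               discordant = bin$discordant,
               rr_per_1000 = rc["rr_per_1000"], cdr_per_1000 = rc["cdr_per_1000"],
               exam_checksum = outcome$exam_checksum,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(strategies, function(s) {
    sched <- build_year_schedule(cfg, params, s, rates = rates)
    run_one(s, simulate_strategy(params, sched, exams))
  })
  if (include_individual)
    rows <- c(rows, list(run_one("individual", simulate_individual(params, cfg, exams))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
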