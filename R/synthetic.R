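#' Synthetic reader-population configuration
#'
#' Defaults emulate the operating-point ranges seen in double-read screening
#' registries: individual FPR of a few percent, TPR around 60-80 percent, and a
#' positive association between the two (readers who recall more find more),
#' obtained from a bivariate normal on the logit-scale reader effects.
#'
#' @param n_readers Number of readers (>= 2).
#' @param mean_r_neg,sd_r_neg Mean / SD of the negative-case (FPR) effect.
#' @param mean_r_pos,sd_r_pos Mean / SD of the positive-case (TPR) effect.
#' @param cor_r Correlation between the two effects in \[-1, 1\].
#' @param sigma_neg,sigma_pos Case-effect standard deviations.
#' @param seed Integer seed.
#' @return Object of class `population_config`.
#' @export
population_config <- function(n_readers = 50L,
                              mean_r_neg = -3.3, sd_r_neg = 0.3,
                              mean_r_pos = 1.0, sd_r_pos = 0.5,
                              cor_r = 0.6,
                              sigma_neg = 1.0, sigma_pos = 1.5,
                              seed = 1L) {
  if (!is.numeric(n_readers) || n_readers < 2) stop_invalid("n_readers must be >= 2")
  if (sd_r_neg < 0 || sd_r_pos < 0) stop_invalid("effect SDs must be non-negative")
  if (!is.numeric(cor_r) || abs(cor_r) > 1) stop_invalid("cor_r must be in [-1, 1]")
  if (sigma_neg < 0 || sigma_pos < 0) stop_invalid("sigmas must be non-negative")
  structure(list(n_readers = as.integer(n_readers),
                 mean_r_neg = mean_r_neg, sd_r_neg = sd_r_neg,
                 mean_r_pos = mean_r_pos, sd_r_pos = sd_r_pos,
                 cor_r = cor_r, sigma_neg = sigma_neg, sigma_pos = sigma_pos,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Generate a ground-truth reader population
#'
#' Draws per-reader logit-scale effects from a bivariate normal with the
#' configured means, SDs and correlation, and computes each reader's implied
#' marginal TPR and FPR. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [population_config()].
#' @param mc [mc_config()] used for the implied marginal rates.
#' @return List with `params` ([model_parameters()] ground truth) and `rates`
#'   (data frame `reader_id`, `tpr`, `fpr`).
#' @export
generate_reader_population <- function(cfg, mc = mc_config(n_samples = 1e5,
                                                           seed = cfg$seed)) {
  stopifnot(inherits(cfg, "population_config"))
  z <- with_seed(derive_seed(cfg$seed, 11L),
                 matrix(stats::rnorm(2L * cfg$n_readers), ncol = 2L))
  r_neg <- cfg$mean_r_neg + cfg$sd_r_neg * z[, 1]
  r_pos <- cfg$mean_r_pos +
    cfg$sd_r_pos * (cfg$cor_r * z[, 1] + sqrt(1 - cfg$cor_r^2) * z[, 2])
  ids <- sprintf("R%04d", seq_len(cfg$n_readers))
  params <- model_parameters(
    data.frame(reader_id = ids, r_neg = r_neg, r_pos = r_pos,
               stringsAsFactors = FALSE),
    sigma_neg = cfg$sigma_neg, sigma_pos = cfg$sigma_pos)
  list(params = params, rates = reader_marginal_rates(params, mc))
}

#' Synthetic screening-dataset configuration
#'
#' @param n_exams Number of examinations (each double read).
#' @param prevalence Probability an exam is a positive (cancer) case;
#'   screening-realistic values are a few per 1,000 (default 0.006).
#' @param pair_scheme `"chained"` (reader i paired with i+1, wrapping; few
#'   overlapping pairs, guarantees identifiability) or `"random_rotation"`
#'   (each exam read by a uniformly drawn pair; emulates sparse registry
#'   coverage).
#' @param seed Integer seed.
#' @return Object of class `dataset_config`.
#' @export
dataset_config <- function(n_exams, prevalence = 0.006,
                           pair_scheme = c("chained", "random_rotation"),
                           seed = 1L) {
  if (!is.numeric(n_exams) || n_exams < 1) stop_invalid("n_exams must be >= 1")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop_invalid("prevalence must be in (0, 1)")
  pair_scheme <- match.arg(pair_scheme)
  structure(list(n_exams = as.integer(n_exams), prevalence = prevalence,
                 reads_per_exam = 2L, pair_scheme = pair_scheme,
                 seed = as.integer(seed)),
            class = "dataset_config")
}

#' Generate double-read screening records from a known model
#'
#' For each exam: case status ~ Bernoulli(prevalence); one latent case effect
#' ~ N(0, sigma^2) for the matching class, SHARED by the exam's two assigned
#' readers; each reader's recall decision ~ Bernoulli(plogis(r + C)). Case
#' status, positive-case effects, negative-case effects, pair assignment and
#' decisions each use an independent stream derived from `cfg$seed`, and the
#' positive and negative case-effect streams are independent (the two classes
#' are modeled as unrelated).
#'
#' @param truth Ground-truth [model_parameters()] (>= 2 readers).
#' @param cfg A [dataset_config()].
#' @return Data frame of reading records (two rows per exam): `exam_id`,
#'   `case_status`, `reader_id`, `decision`, `day`, `batch`.
#' @export
generate_reading_records <- function(truth, cfg) {
  stopifnot(inherits(truth, "model_parameters"), inherits(cfg, "dataset_config"))
  J <- nrow(truth$readers)
  if (J < 2L) stop_invalid("truth must contain at least 2 readers")
  n <- cfg$n_exams
  pos <- with_seed(derive_seed(cfg$seed, 21L), stats::runif(n) < cfg$prevalence)
  ce <- numeric(n)
  n_pos <- sum(pos)
  if (n_pos > 0)
    ce[pos] <- with_seed(derive_seed(cfg$seed, 22L),
                         stats::rnorm(n_pos, 0, truth$sigma_pos))
  if (n_pos < n)
    ce[!pos] <- with_seed(derive_seed(cfg$seed, 23L),
                          stats::rnorm(n - n_pos, 0, truth$sigma_neg))
  if (cfg$pair_scheme == "chained") {
    pair_of_exam <- (seq_len(n) - 1L) %% J + 1L
    i1 <- pair_of_exam
    i2 <- pair_of_exam %% J + 1L
  } else {
    ix <- with_seed(derive_seed(cfg$seed, 24L), {
      i1 <- sample.int(J, n, replace = TRUE)
      off <- sample.int(J - 1L, n, replace = TRUE)
      cbind(i1, (i1 + off - 1L) %% J + 1L)
    })
    i1 <- ix[, 1]; i2 <- ix[, 2]
  }
  r1 <- ifelse(pos, truth$readers$r_pos[i1], truth$readers$r_neg[i1])
  r2 <- ifelse(pos, truth$readers$r_pos[i2], truth$readers$r_neg[i2])
  u <- with_seed(derive_seed(cfg$seed, 25L), stats::runif(2L * n))
  dec1 <- as.integer(u[seq_len(n)] < stats::plogis(r1 + ce))
  dec2 <- as.integer(u[n + seq_len(n)] < stats::plogis(r2 + ce))
  exam_ids <- sprintf("E%07d", seq_len(n))
  status <- ifelse(pos, "positive", "negative")
  data.frame(exam_id = rep(exam_ids, 2L),
             case_status = rep(status, 2L),
             reader_id = truth$readers$reader_id[c(i1, i2)],
             decision = c(dec1, dec2),
             day = NA_integer_, batch = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Apply registry-style exclusion criteria
#'
#' Removes readers that cannot support a binomial fit (zero true positives,
#' zero false positives, or all assessments abnormal in either class) and
#' pairs with fewer than `min_positive_reads_per_pair` jointly read positive
#' exams. Removal cascades: pairs referencing a removed reader are dropped,
#' and when the original records are supplied, exams read by a removed reader
#' or an under-volume pair are dropped and all counts recomputed from the
#' surviving records, iterating to a fixed point.
#'
#' @param counts [observed_counts()].
#' @param min_positive_reads_per_pair Minimum jointly read positive exams per
#'   retained pair (default 17, the volume below which registry pairs proved
#'   too sparse for a stable fit).
#' @param records Optional reading-record data frame the counts came from.
#' @return Filtered [observed_counts()]; when `records` is supplied, the
#'   surviving records are attached as attribute `"records"`.
#' @export
apply_exclusion_criteria <- function(counts, min_positive_reads_per_pair = 17L,
                                     records = NULL) {
  stopifnot(inherits(counts, "observed_counts"))
  bad_reader <- function(r) {
    r$a_pos == 0 | r$a_neg == 0 | r$a_pos == r$k_pos | r$a_neg == r$k_neg
  }
  if (!is.null(records)) {
    repeat {
      counts <- aggregate_reading_records(records)
      drop_r <- counts$readers$reader_id[bad_reader(counts$readers)]
      low <- counts$pairs$k_pos < min_positive_reads_per_pair
      drop_pair <- counts$pairs[low, c("reader_id_1", "reader_id_2")]
      if (length(drop_r) == 0L && nrow(drop_pair) == 0L) break
      ord <- records[order(records$exam_id, records$reader_id, method = "radix"), ]
      runs <- rle(ord$exam_id)
      last <- cumsum(runs$lengths)
      two <- runs$lengths == 2L
      pkey <- character(0)
      exam_pair <- rep(NA_character_, length(runs$values))
      if (any(two))
        exam_pair[two] <- paste(ord$reader_id[last[two] - 1L],
                                ord$reader_id[last[two]])
      bad_pair_keys <- paste(drop_pair$reader_id_1, drop_pair$reader_id_2)
      bad_exams <- runs$values[!is.na(exam_pair) & exam_pair %in% bad_pair_keys]
      keep <- !(records$reader_id %in% drop_r) & !(records$exam_id %in% bad_exams)
      records <- records[keep, , drop = FALSE]
      if (nrow(records) == 0L)
        stop(structure(class = c("doubleread_all_excluded", "error", "condition"),
                       list(message = "exclusion criteria removed all records",
                            call = sys.call())))
      # exams that lost one of their two readers revert to single-read; exams
      # that lost both disappear
    }
    attr(counts, "records") <- records
    return(counts)
  }
  keep_r <- !bad_reader(counts$readers)
  readers <- counts$readers[keep_r, , drop = FALSE]
  if (nrow(readers) == 0L)
    stop(structure(class = c("doubleread_all_excluded", "error", "condition"),
                   list(message = "exclusion criteria removed all readers",
                        call = sys.call())))
  p <- counts$pairs
  if (nrow(p) > 0L) {
    keep_p <- p$k_pos >= min_positive_reads_per_pair &
      p$reader_id_1 %in% readers$reader_id &
      p$reader_id_2 %in% readers$reader_id
    p <- p[keep_p, , drop = FALSE]
  }
  observed_counts(readers, p)
}
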