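#' Observed binomial count tables
#'
#' Sufficient statistics of the reader-model likelihood: per reader, the
#' number of negative / positive exams read (`k_neg`, `k_pos`) and the number
#' called abnormal (`a_neg` false positives, `a_pos` true positives); per
#' observed pair, the jointly read exams (`k_neg`, `k_pos`) and the
#' disagreements (`d_neg`, `d_pos`). Pair ids are stored in canonical
#' (sorted) order.
#'
#' @param readers Data frame with columns `reader_id`, `k_neg`, `a_neg`,
#'   `k_pos`, `a_pos`.
#' @param pairs Data frame with columns `reader_id_1`, `reader_id_2`,
#'   `k_neg`, `d_neg`, `k_pos`, `d_pos` (may have zero rows).
#' @return Object of class `observed_counts`.
#' @export
observed_counts <- function(readers, pairs) {
  need_r <- c("reader_id", "k_neg", "a_neg", "k_pos", "a_pos")
  need_p <- c("reader_id_1", "reader_id_2", "k_neg", "d_neg", "k_pos", "d_pos")
  if (!is.data.frame(readers) || !all(need_r %in% names(readers)) || nrow(readers) < 1L)
    stop_invalid("readers must be a non-empty data frame with columns ",
                 paste(need_r, collapse = ", "))
  if (!is.data.frame(pairs) || !all(need_p %in% names(pairs)))
    stop_invalid("pairs must be a data frame with columns ",
                 paste(need_p, collapse = ", "))
  readers$reader_id <- as.character(readers$reader_id)
  if (anyDuplicated(readers$reader_id)) stop_invalid("duplicate reader_id in readers")
  with(readers, {
    if (any(a_neg < 0 | a_neg > k_neg | a_pos < 0 | a_pos > k_pos))
      stop_invalid("reader counts must satisfy 0 <= a <= k in each class")
  })
  if (nrow(pairs) > 0L) {
    pairs$reader_id_1 <- as.character(pairs$reader_id_1)
    pairs$reader_id_2 <- as.character(pairs$reader_id_2)
    if (any(pairs$reader_id_1 == pairs$reader_id_2))
      stop_invalid("pair reader ids must be distinct")
    swap <- pairs$reader_id_1 > pairs$reader_id_2
    tmp <- pairs$reader_id_1[swap]
    pairs$reader_id_1[swap] <- pairs$reader_id_2[swap]
    pairs$reader_id_2[swap] <- tmp
    with(pairs, {
      if (any(d_neg < 0 | d_neg > k_neg | d_pos < 0 | d_pos > k_pos))
        stop_invalid("pair counts must satisfy 0 <= d <= k in each class")
    })
    known <- c(pairs$reader_id_1, pairs$reader_id_2) %in% readers$reader_id
    if (!all(known)) stop_invalid("every pair reader id must appear in readers")
  }
  rownames(readers) <- NULL
  rownames(pairs) <- NULL
  structure(list(readers = readers, pairs = pairs), class = "observed_counts")
}

#' @export
print.observed_counts <- function(x, ...) {
  cat(sprintf("Observed counts: %d readers, %d pairs\n",
              nrow(x$readers), nrow(x$pairs)))
  cat(sprintf("  negatives read: %s; positives read: %s\n",
              format(sum(x$readers$k_neg), big.mark = ","),
              format(sum(x$readers$k_pos), big.mark = ",")))
  invisible(x)
}

#' Aggregate reading records into binomial count tables
#'
#' Collapses one-row-per-assessment records (each exam read by one or two
#' distinct readers) into the per-reader and per-pair sufficient statistics
#' of the likelihood. Single-read exams contribute to reader counts only;
#' double-read exams additionally contribute one Bernoulli trial to their
#' pair's disagreement counts.
#'
#' @param records Data frame with columns `exam_id`, `case_status`
#'   (`"positive"`/`"negative"`), `reader_id`, `decision` (0/1).
#' @return An [observed_counts()] object.
#' @export
aggregate_reading_records <- function(records) {
  need <- c("exam_id", "case_status", "reader_id", "decision")
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_malformed("records must be a non-empty data frame")
  if (!all(need %in% names(records)))
    stop_malformed("records must have columns ", paste(need, collapse = ", "))
  status <- as.character(records$case_status)
  if (!all(status %in% c("positive", "negative")))
    stop_malformed("case_status must be 'positive' or 'negative'")
  dec <- records$decision
  if (!all(dec %in% c(0, 1))) stop_malformed("decision must be 0 or 1")
  exam <- as.character(records$exam_id)
  reader <- as.character(records$reader_id)
  if (anyDuplicated(paste(exam, reader, sep = "\r")))
    stop_malformed("duplicate (exam_id, reader_id) rows")

  pos <- status == "positive"
  rid <- factor(reader)
  k_pos <- tabulate(rid[pos], nbins = nlevels(rid))
  k_neg <- tabulate(rid[!pos], nbins = nlevels(rid))
  a_pos <- as.vector(rowsum(as.numeric(dec[pos]), rid[pos], reorder = TRUE))
  a_pos <- merge_counts(levels(rid), levels(droplevels(rid[pos])), a_pos)
  a_neg <- as.vector(rowsum(as.numeric(dec[!pos]), rid[!pos], reorder = TRUE))
  a_neg <- merge_counts(levels(rid), levels(droplevels(rid[!pos])), a_neg)
  readers <- data.frame(reader_id = levels(rid),
                        k_neg = k_neg, a_neg = a_neg,
                        k_pos = k_pos, a_pos = a_pos,
                        stringsAsFactors = FALSE)

  ord <- order(exam, reader, method = "radix")
  ex <- exam[ord]
  runs <- rle(ex)
  if (any(runs$lengths > 2L))
    stop_malformed("an exam has more than 2 readers")
  last <- cumsum(runs$lengths)
  two <- runs$lengths == 2L
  i2 <- last[two]          # second row of each double-read exam
  i1 <- i2 - 1L            # first row
  if (any(two) && any(status[ord][i1] != status[ord][i2]))
    stop_malformed("an exam has inconsistent case_status across its two rows")
  if (any(two)) {
    pkey <- paste(reader[ord][i1], reader[ord][i2], sep = "\r")
    pf <- factor(pkey)
    ppos <- pos[ord][i1]
    disagree <- as.numeric(dec[ord][i1] != dec[ord][i2])
    kp_pos <- tabulate(pf[ppos], nbins = nlevels(pf))
    kp_neg <- tabulate(pf[!ppos], nbins = nlevels(pf))
    d_pos <- merge_counts(levels(pf), levels(droplevels(pf[ppos])),
                          as.vector(rowsum(disagree[ppos], pf[ppos], reorder = TRUE)))
    d_neg <- merge_counts(levels(pf), levels(droplevels(pf[!ppos])),
                          as.vector(rowsum(disagree[!ppos], pf[!ppos], reorder = TRUE)))
    ids <- do.call(rbind, strsplit(levels(pf), "\r", fixed = TRUE))
    pairs <- data.frame(reader_id_1 = ids[, 1], reader_id_2 = ids[, 2],
                        k_neg = kp_neg, d_neg = d_neg,
                        k_pos = kp_pos, d_pos = d_pos,
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(reader_id_1 = character(), reader_id_2 = character(),
                        k_neg = integer(), d_neg = integer(),
                        k_pos = integer(), d_pos = integer(),
                        stringsAsFactors = FALSE)
  }
  observed_counts(readers, pairs)
}

# align rowsum output (present levels only) to the full level set, 0-filling
merge_counts <- function(all_levels, present_levels, values) {
  out <- numeric(length(all_levels))
  out[match(present_levels, all_levels)] <- values
  out
}

#' Agresti-Coull adjusted binomial proportion
#'
#' Adds `z^2 / 2` pseudo-successes and `z^2` pseudo-trials before forming a
#' Wald-type interval: the adjusted centre is
#' `(x + z^2/2) / (n + z^2)` and the interval is centre +/- `z`
#' standard errors, clipped to \[0, 1\]. Vectorized over `successes` and
#' `trials`.
#'
#' @param successes Number of successes (0 <= successes <= trials).
#' @param trials Number of trials (>= 1).
#' @param conf Two-sided confidence level (default 0.95).
#' @return Data frame with columns `rate` (adjusted centre), `ci_low`,
#'   `ci_high`, `raw` (unadjusted proportion), `method`.
#' @examples
#' agresti_coull_estimate(0, 10)   # adjusted rate ~0.139, ci_low clipped at 0
#' @export
agresti_coull_estimate <- function(successes, trials, conf = 0.95) {
  if (any(trials < 1)) stop_invalid("trials must be >= 1")
  if (any(successes < 0 | successes > trials))
    stop_invalid("successes must lie in [0, trials]")
  if (!is.numeric(conf) || length(conf) != 1L || conf <= 0 || conf >= 1)
    stop_invalid("conf must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n_adj <- trials + z^2
  p_adj <- (successes + z^2 / 2) / n_adj
  half <- z * sqrt(p_adj * (1 - p_adj) / n_adj)
  data.frame(rate = p_adj,
             ci_low = pmax(0, p_adj - half),
             ci_high = pmin(1, p_adj + half),
             raw = successes / trials,
             method = "agresti_coull",
             stringsAsFactors = FALSE)
}

#' Direct (model-free) rate estimates with Agresti-Coull adjustment
#'
#' Per-reader TPR = A+/K+ and FPR = A-/K-, and per-pair disagreement rates
#' D/K in each case class, each Agresti-Coull adjusted. A reader or pair
#' with zero trials in a class gets `NA` for that class rather than a
#' fabricated rate.
#'
#' @param counts An [observed_counts()] object.
#' @param conf Confidence level (default 0.95).
#' @return List with data frames `readers` (`reader_id`, `tpr`, `tpr_lo`,
#'   `tpr_hi`, `fpr`, `fpr_lo`, `fpr_hi`, raw columns) and `pairs`
#'   (disagreement rates `dr_neg*`, `dr_pos*`).
#' @export
direct_rates <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "observed_counts"))
  r <- counts$readers
  est_cell <- function(a, k) {
    out <- data.frame(rate = rep(NA_real_, length(k)), ci_low = NA_real_,
                      ci_high = NA_real_, raw = NA_real_)
    ok <- k >= 1
    if (any(ok)) out[ok, c("rate", "ci_low", "ci_high", "raw")] <-
        agresti_coull_estimate(a[ok], k[ok], conf)[, c("rate", "ci_low", "ci_high", "raw")]
    out
  }
  tp <- est_cell(r$a_pos, r$k_pos)
  fp <- est_cell(r$a_neg, r$k_neg)
  readers <- data.frame(reader_id = r$reader_id,
                        tpr = tp$rate, tpr_lo = tp$ci_low, tpr_hi = tp$ci_high,
                        tpr_raw = tp$raw,
                        fpr = fp$rate, fpr_lo = fp$ci_low, fpr_hi = fp$ci_high,
                        fpr_raw = fp$raw,
                        stringsAsFactors = FALSE)
  p <- counts$pairs
  if (nrow(p) > 0L) {
    dn <- est_cell(p$d_neg, p$k_neg)
    dp <- est_cell(p$d_pos, p$k_pos)
    pairs <- data.frame(reader_id_1 = p$reader_id_1, reader_id_2 = p$reader_id_2,
                        dr_neg = dn$rate, dr_neg_lo = dn$ci_low, dr_neg_hi = dn$ci_high,
                        dr_neg_raw = dn$raw,
                        dr_pos = dp$rate, dr_pos_lo = dp$ci_low, dr_pos_hi = dp$ci_high,
                        dr_pos_raw = dp$raw,
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame()
  }
  list(readers = readers, pairs = pairs)
}
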