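#' The seven reader-pairing strategies
#'
#' @return Character vector of the recognised strategy names.
#' @export
pairing_strategies <- function() {
  c("similar_tpr", "similar_fpr", "similar_composite",
    "opposite_tpr", "opposite_fpr", "opposite_composite", "random")
}

check_pool <- function(metric) {
  if (is.null(names(metric)) || anyDuplicated(names(metric)))
    stop_invalid("metric must be a named vector with unique reader ids")
  if (anyNA(metric) || any(!is.finite(metric)))
    stop_invalid("metric values must be finite")
  n <- length(metric)
  if (n < 2L || n %% 2L != 0L)
    stop(structure(class = c("doubleread_invalid_pool", "error", "condition"),
                   list(message = "pool must contain an even number (>= 2) of readers",
                        call = sys.call(-1))))
  n
}

pairs_df <- function(ids1, ids2) {
  data.frame(reader_id_1 = ids1, reader_id_2 = ids2, stringsAsFactors = FALSE)
}

#' Pair readers with similar performance
#'
#' Sorts readers ascending by the metric (ties broken by reader id, stable)
#' and pairs consecutive readers: (1st, 2nd), (3rd, 4th), ... This adjacent
#' rule yields the perfect matching minimizing the total within-pair metric
#' difference.
#'
#' @param metric Named numeric vector, names = reader ids.
#' @return Data frame `reader_id_1`, `reader_id_2`, one row per pair.
#' @examples
#' similarity_pairing(c(a = 0.01, b = 0.06, c = 0.02, d = 0.05))
#' @export
similarity_pairing <- function(metric) {
  n <- check_pool(metric)
  ord <- order(metric, names(metric), method = "radix")
  ids <- names(metric)[ord]
  odd <- seq(1L, n, by = 2L)
  pairs_df(ids[odd], ids[odd + 1L])
}

#' Pair readers with opposite performance
#'
#' Splits the sorted readers into lower and upper halves (below and above the
#' median of the metric) and pairs the i-th lowest of the lower half with the
#' i-th lowest of the upper half, so every pair straddles the median.
#'
#' @inheritParams similarity_pairing
#' @return Data frame `reader_id_1`, `reader_id_2`.
#' @export
opposite_pairing <- function(metric) {
  n <- check_pool(metric)
  ord <- order(metric, names(metric), method = "radix")
  ids <- names(metric)[ord]
  h <- n %/% 2L
  pairs_df(ids[seq_len(h)], ids[h + seq_len(h)])
}

#' Composite pairing score: TPR + FPR x slope
#'
#' The slope is the ordinary-least-squares slope of TPR regressed on FPR
#' across the reader pool (the empirical TPR-FPR association line); each
#' reader's score is `TPR + FPR * slope`. With all FPR values identical the
#' regression is degenerate and an error is signalled.
#'
#' @param tpr,fpr Named numeric vectors over the same reader ids.
#' @return Named numeric vector of composite scores.
#' @examples
#' composite_scores(c(a = 0.6, b = 0.8), c(a = 0.02, b = 0.04))  # slope 10
#' @export
composite_scores <- function(tpr, fpr) {
  if (is.null(names(tpr)) || is.null(names(fpr)))
    stop_invalid("tpr and fpr must be named by reader id")
  fpr <- fpr[names(tpr)]
  if (anyNA(fpr)) stop_invalid("tpr and fpr must cover the same readers")
  if (length(tpr) < 2L) stop_invalid("need at least 2 readers")
  v <- stats::var(fpr)
  if (v == 0)
    stop(structure(class = c("doubleread_degenerate_regression", "error", "condition"),
                   list(message = "zero FPR variance: composite slope undefined",
                        call = sys.call())))
  slope <- stats::cov(fpr, tpr) / v
  tpr + fpr * slope
}

#' Random reader pairing
#'
#' A uniformly random perfect matching (readers sampled without replacement,
#' no self-pairs), reproducible from `seed`.
#'
#' @param readers Character vector of reader ids (even length >= 2).
#' @param seed Integer seed.
#' @return Data frame `reader_id_1`, `reader_id_2`.
#' @export
random_pairing <- function(readers, seed) {
  metric <- stats::setNames(seq_along(readers), readers)
  n <- check_pool(metric)
  perm <- with_seed(seed, sample.int(n))
  ids <- readers[perm]
  odd <- seq(1L, n, by = 2L)
  pairs_df(ids[odd], ids[odd + 1L])
}

# dispatch one strategy on a pool; tpr/fpr are named vectors over the pool
pair_pool <- function(strategy, tpr, fpr, seed = NULL) {
  switch(strategy,
         similar_tpr = similarity_pairing(tpr),
         similar_fpr = similarity_pairing(fpr),
         similar_composite = similarity_pairing(composite_scores(tpr, fpr)),
         opposite_tpr = opposite_pairing(tpr),
         opposite_fpr = opposite_pairing(fpr),
         opposite_composite = opposite_pairing(composite_scores(tpr, fpr)),
         random = random_pairing(names(tpr), seed),
         stop_invalid("unknown pairing strategy: ", strategy))
}
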