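#' @title Latent-trait probabilistic core
#'
#' @description
#' Each reader `j` carries a fixed logit-scale effect for negative cases
#' (`r_neg`, governing false positives) and one for positive cases (`r_pos`,
#' governing true positives). Each examination carries a latent normal case
#' effect `C ~ N(0, sigma^2)` shared by both of its readers, with separate
#' standard deviations for negative and positive cases. A reader's
#' conditional probability of calling an exam abnormal is
#' `plogis(r + C)`; marginal rates and paired disagreement rates are
#' expectations of these conditional probabilities over the case-effect
#' distribution, computed by Monte Carlo integration.
#'
#' @name core_model
NULL

#' Monte Carlo integration settings
#'
#' @param n_samples Number of case-effect draws per integral (default
#'   1,000,000, the precision regime where the marginal-rate coefficient of
#'   variation stays below 1 percent at screening-typical operating points).
#' @param seed Integer seed for the case-effect stream.
#' @return An object of class `mc_config`.
#' @examples
#' mc <- mc_config(n_samples = 1e5, seed = 7)
#' @export
mc_config <- function(n_samples = 1e6, seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || !is.finite(n_samples) ||
      n_samples < 1)
    stop_invalid("n_samples must be a positive integer")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("seed must be a finite integer")
  structure(list(n_samples = as.integer(round(n_samples)), seed = as.integer(seed)),
            class = "mc_config")
}

#' Reader population parameters
#'
#' Container for the full parameter vector of the reader model: one pair of
#' logit-scale effects per reader and the two case-effect standard
#' deviations.
#'
#' @param readers A data frame with columns `reader_id`, `r_neg`, `r_pos`
#'   (finite, logit scale; ids unique).
#' @param sigma_neg,sigma_pos Case-effect standard deviations (>= 0; zero is
#'   the degenerate no-case-effect limit).
#' @return An object of class `model_parameters`.
#' @examples
#' model_parameters(data.frame(reader_id = c("a", "b"),
#'                             r_neg = c(-3.2, -3.4), r_pos = c(0.9, 1.2)),
#'                  sigma_neg = 1, sigma_pos = 1.5)
#' @export
model_parameters <- function(readers, sigma_neg, sigma_pos) {
  if (!is.data.frame(readers) || nrow(readers) < 1L)
    stop_invalid("readers must be a non-empty data frame")
  need <- c("reader_id", "r_neg", "r_pos")
  if (!all(need %in% names(readers)))
    stop_invalid("readers must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(readers$reader_id))
    stop_invalid("reader_id values must be unique")
  check_finite(readers$r_neg, "r_neg")
  check_finite(readers$r_pos, "r_pos")
  check_finite(sigma_neg, "sigma_neg")
  check_finite(sigma_pos, "sigma_pos")
  if (sigma_neg < 0 || sigma_pos < 0)
    stop_invalid("case-effect standard deviations must be non-negative")
  readers <- data.frame(reader_id = as.character(readers$reader_id),
                        r_neg = as.numeric(readers$r_neg),
                        r_pos = as.numeric(readers$r_pos),
                        stringsAsFactors = FALSE)
  structure(list(readers = readers,
                 sigma_neg = as.numeric(sigma_neg),
                 sigma_pos = as.numeric(sigma_pos)),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("Reader model parameters: %d readers\n", nrow(x$readers)))
  cat(sprintf("  sigma_neg = %.4f, sigma_pos = %.4f\n", x$sigma_neg, x$sigma_pos))
  cat(sprintf("  r_neg in [%.3f, %.3f], r_pos in [%.3f, %.3f]\n",
              min(x$readers$r_neg), max(x$readers$r_neg),
              min(x$readers$r_pos), max(x$readers$r_pos)))
  invisible(x)
}

#' Overflow-safe logistic link
#'
#' Maps a logit-scale decision variable to an abnormal-interpretation
#' probability, `exp(q) / (1 + exp(q))`, evaluated without overflow for large
#' `|q|` (delegates to [stats::plogis()], which branches on the sign).
#'
#' @param q Numeric vector of finite logit values.
#' @return Probabilities in (0, 1).
#' @examples
#' logistic_link(0)    # 0.5
#' logistic_link(-50)  # ~2e-22, no underflow warning
#' @export
logistic_link <- function(q) {
  check_finite(q, "q")
  stats::plogis(q)
}

#' Conditional abnormal-interpretation probability
#'
#' Probability that a reader with logit effect `r` recalls an exam whose
#' latent case effect is `c`: `logistic_link(r + c)`. Strictly increasing in
#' both arguments.
#'
#' @param r Reader effect (logit scale).
#' @param c_eff Case effect (logit scale).
#' @return Probability in (0, 1).
#' @export
conditional_abnormal_probability <- function(r, c_eff) {
  check_finite(r, "r")
  check_finite(c_eff, "c_eff")
  stats::plogis(r + c_eff)
}

# Shared-case-effect draws for one Monte Carlo configuration: standard
# normal; scaled by sigma at use time so one stream serves all sigmas
# (common random numbers across likelihood evaluations).
mc_draws <- function(mc) {
  stopifnot(inherits(mc, "mc_config"))
  with_seed(mc$seed, stats::rnorm(mc$n_samples))
}

#' Marginal abnormal-interpretation rate
#'
#' Expected conditional probability over the case-effect distribution
#' `C ~ N(0, sigma^2)`, estimated by Monte Carlo with `mc$n_samples` draws
#' from `mc$seed`. For `sigma = 0` the exact value `logistic_link(r)` is
#' returned without sampling. The Monte Carlo standard error of the estimate
#' is attached as attribute `"mc_se"` (0 in the exact case).
#'
#' @param r Reader effect (logit scale, scalar).
#' @param sigma Case-effect standard deviation (>= 0).
#' @param mc An [mc_config()].
#' @param z Optional pre-drawn standard-normal vector to reuse across calls
#'   (common random numbers); overrides `mc`'s stream.
#' @return Scalar rate in (0, 1) with attribute `mc_se`.
#' @examples
#' marginal_abnormal_rate(-3, 1, mc_config(1e5, seed = 2))
#' @export
marginal_abnormal_rate <- function(r, sigma, mc = mc_config(), z = NULL) {
  check_finite(r, "r")
  check_finite(sigma, "sigma")
  if (sigma < 0) stop_invalid("sigma must be non-negative")
  if (sigma == 0) {
    out <- stats::plogis(r)
    attr(out, "mc_se") <- 0
    return(out)
  }
  if (is.null(z)) z <- mc_draws(mc)
  a <- stats::plogis(r + sigma * z)
  out <- mean(a)
  attr(out, "mc_se") <- stats::sd(a) / sqrt(length(a))
  out
}

#' Case-conditional disagreement probability
#'
#' Probability that two readers with conditional abnormal probabilities `a1`
#' and `a2` (same exam) give different binary decisions:
#' `a1 (1 - a2) + a2 (1 - a1)`. Symmetric in its arguments.
#'
#' @param a1,a2 Probabilities in \[0, 1\].
#' @return Probability in \[0, 1\].
#' @export
conditional_disagreement <- function(a1, a2) {
  check_prob(a1, "a1")
  check_prob(a2, "a2")
  a1 * (1 - a2) + a2 * (1 - a1)
}

#' Marginal pair disagreement rate
#'
#' Expectation of [conditional_disagreement()] over the shared case effect:
#' both readers see the SAME draw `C` within each Monte Carlo sample, which
#' is what induces the between-reader correlation (and makes the marginal
#' disagreement smaller than the independence value computed from the two
#' marginal rates). For `sigma = 0` the exact closed form on the marginal
#' rates is returned.
#'
#' @param r1,r2 The two readers' effects (logit scale).
#' @param sigma Case-effect standard deviation (>= 0).
#' @param mc An [mc_config()].
#' @param z Optional pre-drawn standard-normal vector (common random numbers).
#' @return Scalar disagreement probability with attribute `mc_se`.
#' @export
marginal_disagreement <- function(r1, r2, sigma, mc = mc_config(), z = NULL) {
  check_finite(r1, "r1")
  check_finite(r2, "r2")
  check_finite(sigma, "sigma")
  if (sigma < 0) stop_invalid("sigma must be non-negative")
  if (sigma == 0) {
    out <- conditional_disagreement(stats::plogis(r1), stats::plogis(r2))
    attr(out, "mc_se") <- 0
    return(out)
  }
  if (is.null(z)) z <- mc_draws(mc)
  a1 <- stats::plogis(r1 + sigma * z)
  a2 <- stats::plogis(r2 + sigma * z)
  d <- a1 * (1 - a2) + a2 * (1 - a1)
  out <- mean(d)
  attr(out, "mc_se") <- stats::sd(d) / sqrt(length(d))
  out
}

#' Paired positive probability
#'
#' Probability that a pair flags an exam, under the rule that disagreement
#' counts as an abnormal interpretation for the pair (any reader flagging
#' triggers consensus/arbitration): `a1 + a2 - a1 a2 = 1 - (1 - a1)(1 - a2)`.
#' Always at least `max(a1, a2)`.
#'
#' @param a1,a2 The two readers' abnormal probabilities for the exam.
#' @return Probability in \[0, 1\].
#' @examples
#' paired_positive_probability(0.6, 0.5)  # 0.8
#' @export
paired_positive_probability <- function(a1, a2) {
  check_prob(a1, "a1")
  check_prob(a2, "a2")
  a1 + a2 - a1 * a2
}

#' Modeled marginal TPR and FPR for every reader
#'
#' Convenience wrapper computing each reader's marginal true-positive rate
#' (from `r_pos`, `sigma_pos`) and false-positive rate (from `r_neg`,
#' `sigma_neg`). Positive- and negative-case integrals use independent
#' streams derived from `mc$seed`.
#'
#' @param params A [model_parameters()] object.
#' @param mc An [mc_config()].
#' @return Data frame with columns `reader_id`, `tpr`, `fpr`.
#' @export
reader_marginal_rates <- function(params, mc = mc_config()) {
  stopifnot(inherits(params, "model_parameters"))
  z_neg <- if (params$sigma_neg > 0)
    with_seed(derive_seed(mc$seed, 1L), stats::rnorm(mc$n_samples)) else NULL
  z_pos <- if (params$sigma_pos > 0)
    with_seed(derive_seed(mc$seed, 2L), stats::rnorm(mc$n_samples)) else NULL
  fpr <- vapply(params$readers$r_neg, function(r)
    as.numeric(marginal_abnormal_rate(r, params$sigma_neg, mc, z = z_neg)), 0)
  tpr <- vapply(params$readers$r_pos, function(r)
    as.numeric(marginal_abnormal_rate(r, params$sigma_pos, mc, z = z_pos)), 0)
  data.frame(reader_id = params$readers$reader_id, tpr = tpr, fpr = fpr,
             stringsAsFactors = FALSE)
}
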