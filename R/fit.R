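#' Fitting configuration
#'
#' @param f_tol Fractional convergence tolerance for Powell's method
#'   (default 1e-4).
#' @param max_iterations Maximum Powell sweeps per case class (default 200).
#' @param mc Monte Carlo settings ([mc_config()]); the same case-effect
#'   sample is reused for every likelihood evaluation within a fit (common
#'   random numbers), which makes the likelihood surface deterministic and
#'   lets Powell converge.
#' @param init Either `"from_direct_estimates"` (reader effects initialized
#'   at the logit of the Agresti-Coull-adjusted direct rates, sigma at 1) or
#'   `"user_supplied"` (pass `init_params` to [fit_model()]).
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(f_tol = 1e-4, max_iterations = 200L,
                       mc = mc_config(),
                       init = c("from_direct_estimates", "user_supplied")) {
  if (!is.numeric(f_tol) || f_tol <= 0) stop_invalid("f_tol must be > 0")
  init <- match.arg(init)
  stopifnot(inherits(mc, "mc_config"))
  structure(list(f_tol = f_tol, max_iterations = as.integer(max_iterations),
                 mc = mc, init = init),
            class = "fit_config")
}

# Marginal rates and pair disagreements for one case class given shared
# standard-normal draws z (n x 1). Returns list(a = per-reader rates,
# d = per-pair disagreement rates), all by position.
class_rates <- function(r, sigma, z, pair_i, pair_j) {
  if (sigma == 0) {
    a <- stats::plogis(r)
    d <- if (length(pair_i))
      a[pair_i] + a[pair_j] - 2 * a[pair_i] * a[pair_j] else numeric()
    return(list(a = a, d = d))
  }
  P <- stats::plogis(outer(sigma * z, r, "+"))
  a <- colMeans(P)
  d <- if (length(pair_i)) {
    Pi <- P[, pair_i, drop = FALSE]
    Pj <- P[, pair_j, drop = FALSE]
    colMeans(Pi + Pj - 2 * Pi * Pj)
  } else numeric()
  list(a = a, d = d)
}

# Binomial NLL for one case class; +Inf if a rate is numerically degenerate.
class_nll <- function(rates, k_r, a_r, k_p, d_p) {
  a <- rates$a
  d <- rates$d
  if (any(a <= 0 | a >= 1) || (length(d) && any(d <= 0 | d >= 1))) return(Inf)
  use <- k_r > 0
  nll <- -sum(a_r[use] * log(a[use]) + (k_r[use] - a_r[use]) * log1p(-a[use]))
  if (length(d)) {
    usep <- k_p > 0
    nll <- nll - sum(d_p[usep] * log(d[usep]) +
                       (k_p[usep] - d_p[usep]) * log1p(-d[usep]))
  }
  nll
}

#' Negative log-likelihood of the reader model
#'
#' The binomial log-likelihood of the observed per-reader abnormal counts
#' and per-pair disagreement counts under the model's marginal rates, negated
#' and with the parameter-free log-factorial constant dropped:
#' `-sum_j [ A ln a + (K - A) ln(1 - a) ]` over both case classes, plus the
#' corresponding pair terms `-sum [ D ln d + (K - D) ln(1 - d) ]`. Positive
#' and negative classes use independent Monte Carlo streams derived from
#' `mc$seed`.
#'
#' @param params [model_parameters()] covering every reader in `counts`.
#' @param counts [observed_counts()].
#' @param mc [mc_config()].
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, counts, mc = mc_config()) {
  stopifnot(inherits(params, "model_parameters"), inherits(counts, "observed_counts"))
  idx <- match(counts$readers$reader_id, params$readers$reader_id)
  if (anyNA(idx)) stop_invalid("every reader in counts needs a ReaderEffect in params")
  pair_i <- match(counts$pairs$reader_id_1, counts$readers$reader_id)
  pair_j <- match(counts$pairs$reader_id_2, counts$readers$reader_id)
  z_neg <- if (params$sigma_neg > 0)
    with_seed(derive_seed(mc$seed, 1L), stats::rnorm(mc$n_samples)) else numeric()
  z_pos <- if (params$sigma_pos > 0)
    with_seed(derive_seed(mc$seed, 2L), stats::rnorm(mc$n_samples)) else numeric()
  rn <- class_rates(params$readers$r_neg[idx], params$sigma_neg, z_neg, pair_i, pair_j)
  rp <- class_rates(params$readers$r_pos[idx], params$sigma_pos, z_pos, pair_i, pair_j)
  if (any(rn$a <= 0 | rn$a >= 1) || any(rp$a <= 0 | rp$a >= 1) ||
      (length(rn$d) && any(rn$d <= 0 | rn$d >= 1)) ||
      (length(rp$d) && any(rp$d <= 0 | rp$d >= 1)))
    stop(structure(class = c("doubleread_degenerate_likelihood", "error", "condition"),
                   list(message = "a marginal rate is exactly 0 or 1 at these parameters",
                        call = sys.call())))
  class_nll(rn, counts$readers$k_neg, counts$readers$a_neg,
            counts$pairs$k_neg, counts$pairs$d_neg) +
    class_nll(rp, counts$readers$k_pos, counts$readers$a_pos,
              counts$pairs$k_pos, counts$pairs$d_pos)
}

# one case class maximum-likelihood fit: joint Powell over (r_1..r_J, log sigma)
fit_one_class <- function(k_r, a_r, pair_i, pair_j, k_p, d_p, z, r_init, config) {
  obj <- function(theta) {
    r <- theta[-length(theta)]
    sigma <- exp(theta[length(theta)])
    if (!all(is.finite(r)) || !is.finite(sigma)) return(Inf)
    class_nll(class_rates(r, sigma, z, pair_i, pair_j), k_r, a_r, k_p, d_p)
  }
  theta0 <- c(r_init, 0)  # sigma initialized at 1 on the log scale
  res <- powell_minimize(obj, theta0, f_tol = config$f_tol,
                         max_iterations = config$max_iterations)
  if (!res$converged)
    stop(structure(class = c("doubleread_non_convergence", "error", "condition"),
                   list(message = sprintf(
                     "Powell did not converge within %d sweeps", config$max_iterations),
                     call = sys.call())))
  sigma <- exp(res$par[length(res$par)])
  r <- res$par[-length(res$par)]
  rates <- class_rates(r, sigma, z, pair_i, pair_j)
  list(r = r, sigma = sigma, a = rates$a, d = rates$d, nll = res$value,
       nll0 = res$trace[1], trace = res$trace, iterations = res$iterations)
}

#' Fit the reader model by maximum likelihood
#'
#' Maximizes the binomial likelihood of per-reader abnormal counts and
#' per-pair disagreement counts jointly over all reader effects and the
#' case-effect standard deviation, separately for the positive and negative
#' case classes (the two classes are independent). Optimization is Powell's
#' derivative-free method with fractional tolerance `config$f_tol`; sigma is
#' optimized on the log scale so positivity never binds; the Monte Carlo
#' case-effect sample is drawn once per class and held fixed across all
#' likelihood evaluations.
#'
#' Pair disagreement data are what identify sigma: the single-reader counts
#' alone admit many (r, sigma) combinations with identical marginal rates, so
#' `counts$pairs` must be non-empty.
#'
#' @param counts [observed_counts()]; every reader needs at least one
#'   abnormal and one normal assessment in each class it contributes to
#'   (apply [apply_exclusion_criteria()] first).
#' @param config [fit_config()].
#' @param init_params Optional [model_parameters()] starting point (used when
#'   `config$init == "user_supplied"`).
#' @return Object of class `reader_model_fit`: `params` (the fitted
#'   [model_parameters()]), `rates` (per-reader modeled marginal `tpr`,
#'   `fpr`), `pair_disagreement` (modeled `dr_neg`, `dr_pos` per observed
#'   pair), `nll` (total), `nll_by_class`, `trace_neg`/`trace_pos` (Powell
#'   iterate logs), `config`.
#' @export
fit_model <- function(counts, config = fit_config(), init_params = NULL) {
  stopifnot(inherits(counts, "observed_counts"), inherits(config, "fit_config"))
  if (nrow(counts$pairs) == 0L)
    stop(structure(class = c("doubleread_not_identifiable", "error", "condition"),
                   list(message = paste0(
                     "no pair data: the model is not identifiable from ",
                     "single-reader counts alone"), call = sys.call())))
  r <- counts$readers
  bad <- (r$k_pos > 0 & (r$a_pos == 0 | r$a_pos == r$k_pos)) |
    (r$k_neg > 0 & (r$a_neg == 0 | r$a_neg == r$k_neg))
  if (any(bad))
    stop_invalid("readers with degenerate counts (A = 0 or A = K) present: ",
                 paste(r$reader_id[bad], collapse = ", "),
                 "; apply_exclusion_criteria() first")

  if (config$init == "user_supplied") {
    if (is.null(init_params)) stop_invalid("init_params required for user_supplied init")
    idx <- match(r$reader_id, init_params$readers$reader_id)
    if (anyNA(idx)) stop_invalid("init_params must cover every reader in counts")
    r_neg0 <- init_params$readers$r_neg[idx]
    r_pos0 <- init_params$readers$r_pos[idx]
  } else {
    dr <- direct_rates(counts)
    r_neg0 <- stats::qlogis(ifelse(is.na(dr$readers$fpr), 0.5, dr$readers$fpr))
    r_pos0 <- stats::qlogis(ifelse(is.na(dr$readers$tpr), 0.5, dr$readers$tpr))
  }

  pair_i <- match(counts$pairs$reader_id_1, r$reader_id)
  pair_j <- match(counts$pairs$reader_id_2, r$reader_id)
  mc <- config$mc
  z_neg <- with_seed(derive_seed(mc$seed, 1L), stats::rnorm(mc$n_samples))
  z_pos <- with_seed(derive_seed(mc$seed, 2L), stats::rnorm(mc$n_samples))

  fit_neg <- fit_one_class(r$k_neg, r$a_neg, pair_i, pair_j,
                           counts$pairs$k_neg, counts$pairs$d_neg,
                           z_neg, r_neg0, config)
  fit_pos <- fit_one_class(r$k_pos, r$a_pos, pair_i, pair_j,
                           counts$pairs$k_pos, counts$pairs$d_pos,
                           z_pos, r_pos0, config)

  params <- model_parameters(
    data.frame(reader_id = r$reader_id, r_neg = fit_neg$r, r_pos = fit_pos$r,
               stringsAsFactors = FALSE),
    sigma_neg = fit_neg$sigma, sigma_pos = fit_pos$sigma)
  rates <- data.frame(reader_id = r$reader_id, tpr = fit_pos$a, fpr = fit_neg$a,
                      stringsAsFactors = FALSE)
  pair_dis <- if (nrow(counts$pairs)) {
    data.frame(reader_id_1 = counts$pairs$reader_id_1,
               reader_id_2 = counts$pairs$reader_id_2,
               dr_neg = fit_neg$d, dr_pos = fit_pos$d,
               stringsAsFactors = FALSE)
  } else data.frame()
  structure(list(params = params, rates = rates, pair_disagreement = pair_dis,
                 nll = fit_neg$nll + fit_pos$nll,
                 nll_by_class = c(neg = fit_neg$nll, pos = fit_pos$nll),
                 nll_init = c(neg = fit_neg$nll0, pos = fit_pos$nll0),
                 trace_neg = fit_neg$trace, trace_pos = fit_pos$trace,
                 iterations = c(neg = fit_neg$iterations, pos = fit_pos$iterations),
                 config = config),
            class = "reader_model_fit")
}

#' @export
print.reader_model_fit <- function(x, ...) {
  cat(sprintf("Reader model fit: %d readers, %d pairs\n",
              nrow(x$rates), nrow(x$pair_disagreement)))
  cat(sprintf("  NLL = %.3f (neg %.3f + pos %.3f)\n",
              x$nll, x$nll_by_class["neg"], x$nll_by_class["pos"]))
  cat(sprintf("  sigma_neg = %.4f, sigma_pos = %.4f\n",
              x$params$sigma_neg, x$params$sigma_pos))
  cat(sprintf("  Powell sweeps: neg %d, pos %d\n",
              x$iterations["neg"], x$iterations["pos"]))
  invisible(x)
}

safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Graphical-fit diagnostics: modeled vs observed rates
#'
#' Pearson correlations between the modeled marginal rates and the
#' Agresti-Coull-adjusted direct estimates, computed separately for reader
#' TPR, reader FPR, positive-case pair disagreement, and negative-case pair
#' disagreement. A coefficient with fewer than 3 paired points or zero
#' variance in either vector is reported as `NA` (undefined), never as 0.
#'
#' @param fitted A `reader_model_fit`.
#' @param counts The [observed_counts()] the model was fitted to (or held-out
#'   counts with the same ids).
#' @param conf Confidence level passed to the Agresti-Coull adjustment.
#' @return Object of class `fit_diagnostics`: named numeric vector with
#'   elements `pearson_tpr`, `pearson_fpr`, `pearson_disagree_pos`,
#'   `pearson_disagree_neg`.
#' @export
evaluate_fit <- function(fitted, counts, conf = 0.95) {
  stopifnot(inherits(fitted, "reader_model_fit"), inherits(counts, "observed_counts"))
  obs <- direct_rates(counts, conf)
  ir <- match(counts$readers$reader_id, fitted$rates$reader_id)
  if (anyNA(ir)) stop_invalid("fitted model and counts must share reader ids")
  out <- c(pearson_tpr = safe_cor(fitted$rates$tpr[ir], obs$readers$tpr),
           pearson_fpr = safe_cor(fitted$rates$fpr[ir], obs$readers$fpr),
           pearson_disagree_pos = NA_real_, pearson_disagree_neg = NA_real_)
  if (nrow(counts$pairs) > 0L && nrow(fitted$pair_disagreement) > 0L) {
    key_fit <- paste(fitted$pair_disagreement$reader_id_1,
                     fitted$pair_disagreement$reader_id_2)
    key_obs <- paste(counts$pairs$reader_id_1, counts$pairs$reader_id_2)
    ip <- match(key_obs, key_fit)
    if (!anyNA(ip)) {
      out["pearson_disagree_pos"] <-
        safe_cor(fitted$pair_disagreement$dr_pos[ip], obs$pairs$dr_pos)
      out["pearson_disagree_neg"] <-
        safe_cor(fitted$pair_disagreement$dr_neg[ip], obs$pairs$dr_neg)
    }
  }
  structure(out, class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat("Modeled vs observed Pearson correlations:\n")
  lab <- c(pearson_tpr = "reader TPR", pearson_fpr = "reader FPR",
           pearson_disagree_pos = "pair disagreement (positive cases)",
           pearson_disagree_neg = "pair disagreement (negative cases)")
  for (nm in names(lab))
    cat(sprintf("  %-36s %s\n", lab[nm],
                ifelse(is.na(x[nm]), "undefined", sprintf("%.3f", x[nm]))))
  invisible(x)
}
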