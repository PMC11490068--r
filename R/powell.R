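#' Powell's derivative-free direction-set minimization
#'
#' Minimizes a scalar function of several variables without derivatives:
#' successive Brent line minimizations along a maintained set of directions,
#' with Powell's rule for replacing the direction of largest decrease by the
#' overall displacement of the sweep (keeping the set close to conjugate).
#' Convergence is declared when one full sweep reduces the function by less
#' than the fractional tolerance,
#' `2 (f_old - f_new) <= f_tol (|f_old| + |f_new|) + 1e-25`.
#'
#' @param fn Objective function of a numeric vector.
#' @param x0 Numeric start vector.
#' @param f_tol Fractional convergence tolerance on the objective
#'   (default 1e-4).
#' @param max_iterations Maximum number of full direction sweeps.
#' @return List with `par`, `value`, `iterations`, `converged`,
#'   `trace` (objective after each sweep, starting value first) and
#'   `n_evals`.
#' @examples
#' powell_minimize(function(x) sum((x - c(1, -2))^2), c(0, 0))$par
#' @export
powell_minimize <- function(fn, x0, f_tol = 1e-4, max_iterations = 200L) {
  if (!is.numeric(x0) || length(x0) < 1L || anyNA(x0))
    stop_invalid("x0 must be a numeric vector")
  if (!is.numeric(f_tol) || f_tol <= 0) stop_invalid("f_tol must be positive")
  n <- length(x0)
  evals <- 0L
  f <- function(x) { evals <<- evals + 1L; fn(x) }

  # Brent line minimization along direction d from point p, with outward
  # bracket expansion when the minimum sits on the search boundary.
  line_min <- function(p, d, fp) {
    g <- function(t) f(p + t * d)
    lo <- -1; hi <- 1
    for (k in 1:60) {
      opt <- stats::optimize(g, c(lo, hi), tol = 1e-8 * (hi - lo) + 1e-10)
      span <- hi - lo
      if (opt$minimum - lo < 0.01 * span) {
        hi <- lo + 0.1 * span; lo <- lo - 3 * span
      } else if (hi - opt$minimum < 0.01 * span) {
        lo <- hi - 0.1 * span; hi <- hi + 3 * span
      } else break
    }
    if (opt$objective < fp) list(p = p + opt$minimum * d, f = opt$objective, t = opt$minimum)
    else list(p = p, f = fp, t = 0)
  }

  dirs <- diag(n)
  x <- x0
  fx <- f(x)
  trace <- fx
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    x_start <- x
    f_start <- fx
    biggest_drop <- 0
    i_big <- 1L
    for (i in seq_len(n)) {
      res <- line_min(x, dirs[, i], fx)
      if (fx - res$f > biggest_drop) { biggest_drop <- fx - res$f; i_big <- i }
      x <- res$p; fx <- res$f
    }
    trace <- c(trace, fx)
    if (2 * (f_start - fx) <= f_tol * (abs(f_start) + abs(fx)) + 1e-25) {
      converged <- TRUE
      break
    }
    # Powell's direction-replacement test on the extrapolated point
    x_ext <- 2 * x - x_start
    f_ext <- f(x_ext)
    if (f_ext < f_start) {
      t1 <- 2 * (f_start - 2 * fx + f_ext) * (f_start - fx - biggest_drop)^2
      t2 <- biggest_drop * (f_start - f_ext)^2
      if (t1 < t2) {
        d_new <- x - x_start
        if (sum(d_new^2) > 0) {
          res <- line_min(x, d_new, fx)
          x <- res$p; fx <- res$f
          dirs[, i_big] <- dirs[, n]
          dirs[, n] <- d_new
        }
      }
    }
  }
  list(par = x, value = fx, iterations = iter, converged = converged,
       trace = trace, n_evals = evals)
}
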