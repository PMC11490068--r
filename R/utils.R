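#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the global RNG to `seed`, evaluates `expr`, and restores the previous
#' RNG state so callers never perturb the session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically maps a master seed and a stream index to a distinct
#' 31-bit seed, so independent stochastic stages (case status, case effects,
#' reader pools, random pairing, Bernoulli decisions, bootstrap) each get
#' their own stream.
#'
#' @param seed Master integer seed.
#' @param stream Positive integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647  # 2^31 - 1, Mersenne prime (minimal standard modulus)
  s <- (abs(as.numeric(seed)) %% m)
  # two multiplicative steps so nearby (seed, stream) pairs decorrelate
  s <- (s * 48271) %% m
  s <- (s + as.numeric(stream) * 69621) %% m
  s <- (s * 16807) %% m
  as.integer(s %% (m - 2) + 1)
}

stop_invalid <- function(...) {
  stop(structure(class = c("doubleread_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_malformed <- function(...) {
  stop(structure(class = c("doubleread_malformed_data", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_invalid(name, " must be a probability in [0, 1]")
  invisible(x)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_invalid(name, " must be finite numeric")
  invisible(x)
}
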