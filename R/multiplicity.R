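#' Estimate the null proportion pi0 from a p-value set
#'
#' pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) over the lambda grid; a
#' cubic smoothing spline (3 degrees of freedom) through (lambda,
#' pi0(lambda)) is evaluated at the largest lambda and clamped to [0, 1].
#' For small families (m < 100) the spline is unstable and the estimate
#' falls back to the conservative pi0 = 1, which makes the q-values equal
#' to Benjamini-Hochberg adjusted p-values.
#'
#' @param p P-values in [0, 1].
#' @param lambda Grid (default seq(0.05, 0.90, 0.05)).
#' @return pi0 estimate in (0, 1].
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.90, by = 0.05)) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("invalid input: p-values must lie in [0, 1]")
  m <- length(p)
  if (m < 100) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Storey positive-FDR q-values
#'
#' With p ordered ascending, q_(m) = min(pi0 p_(m), 1) and
#' q_(i) = min(pi0 m p_(i) / i, q_(i+1)); results are returned in input
#' order. With pi0 = 1 this reduces exactly to Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p P-values in [0, 1].
#' @param pi0 Null proportion; estimated via [estimate_pi0()] when NULL.
#' @return Numeric vector of q-values in input order.
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("invalid input: p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (is.null(pi0)) pi0 <- estimate_pi0(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(pi0 * m * ps / seq_len(m), 1)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Full q-value result object
#'
#' @inheritParams storey_qvalues
#' @param lambda pi0 estimation grid.
#' @return List with p_values, lambda, pi0_lambda, pi0, q_values.
#' @export
qvalue_result <- function(p, lambda = seq(0.05, 0.90, by = 0.05)) {
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- estimate_pi0(p, lambda)
  list(p_values = p, lambda = lambda, pi0_lambda = pi0_l, pi0 = pi0,
       q_values = storey_qvalues(p, pi0))
}
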