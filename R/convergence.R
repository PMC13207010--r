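# Draw-based summaries and convergence metrics. Draws from the Laplace
# approximation are independent, so R-hat and ESS are trivially healthy;
# they are still computed so that any alternative sampler plugged in
# behind tick_fit() is held to the same contract.

#' Summarize posterior draws
#'
#' Mean, sample SD and equal-tailed credible interval (empirical
#' quantiles, linear interpolation) for a vector of draws or each column
#' of a draw matrix.
#'
#' @param draws Numeric vector, or matrix with one column per quantity.
#' @param ci Credible level in (0, 1), default 0.95.
#' @return A data.frame with columns `mean`, `sd`, `lower`, `upper`.
#' @examples
#' summarize_draws(c(1, 2, 3))  # mean 2, sd 1
#' @export
summarize_draws <- function(draws, ci = 0.95) {
  stopifnot(ci > 0, ci < 1)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  a <- (1 - ci) / 2
  out <- data.frame(
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    lower = apply(draws, 2, quantile, probs = a, names = FALSE),
    upper = apply(draws, 2, quantile, probs = 1 - a, names = FALSE)
  )
  if (!is.null(colnames(draws)) && anyDuplicated(colnames(draws)) == 0)
    rownames(out) <- colnames(draws)
  out
}

#' Precisions and correlations implied by a location covariance
#'
#' Reports the per-stage precisions `tau_j = 1/Sigma_jj` and the
#' cross-stage correlations `rho_jk = Sigma_jk / sqrt(Sigma_jj Sigma_kk)`.
#'
#' @param Sigma A 3 x 3 covariance matrix.
#' @return A named list with `tau` (length 3) and `rho`
#'   (`rho_LN`, `rho_LA`, `rho_NA`).
#' @export
sigma_to_tau_rho <- function(Sigma) {
  d <- diag(Sigma)
  s <- sqrt(d)
  list(tau = setNames(1 / d, paste0("tau_loc_", c("L", "N", "A"))),
       rho = c(rho_LN = Sigma[1, 2] / (s[1] * s[2]),
               rho_LA = Sigma[1, 3] / (s[1] * s[3]),
               rho_NA = Sigma[2, 3] / (s[2] * s[3])))
}

#' Split R-hat of a draw vector
#'
#' Potential scale reduction factor computed by splitting the draws into
#' `n_split` consecutive pseudo-chains.
#' @param x Numeric vector of draws.
#' @param n_split Number of segments (default 4).
#' @return The split R-hat (1 for well-mixed / independent draws).
#' @export
split_rhat <- function(x, n_split = 4) {
  n <- floor(length(x) / n_split)
  if (n < 2) return(NA_real_)
  ch <- matrix(x[seq_len(n * n_split)], nrow = n)
  m <- colMeans(ch)
  W <- mean(apply(ch, 2, var))
  B <- n * var(m)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of a draw vector
#'
#' Standard initial-positive-sequence autocorrelation estimator; for
#' independent draws the estimate is close to the number of draws.
#' @param x Numeric vector of draws.
#' @return Estimated effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}
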