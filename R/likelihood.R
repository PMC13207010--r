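# Observation-model primitives. The NB uses the mean/size
# parameterization with Var = mu + mu^2/phi, so small phi means extreme
# overdispersion (the larval phi ~ 0.08 regime implies a
# variance-to-mean ratio in the thousands at typical larval means).

#' Negative binomial log pmf (mean/size parameterization)
#'
#' `P(Y = y) = Gamma(y+phi)/(Gamma(phi) y!) (phi/(phi+mu))^phi
#' (mu/(phi+mu))^y`, with `E(Y) = mu` and `Var(Y) = mu + mu^2/phi`.
#' Computed on the log scale via `lgamma`, stable for very large counts
#' and very small `phi`.
#'
#' @param y Non-negative integer count(s).
#' @param mu Positive mean(s).
#' @param phi Positive size (inverse-overdispersion) parameter(s).
#' @return Log probability mass, vectorized over arguments.
#' @examples
#' nb_log_pmf(0, 1, 1)  # log(0.5)
#' @export
nb_log_pmf <- function(y, mu, phi) {
  if (any(mu <= 0) || any(phi <= 0))
    stop("mu and phi must be positive", call. = FALSE)
  if (any(y < 0) || any(y != round(y)))
    stop("y must be a non-negative integer", call. = FALSE)
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    phi * (log(phi) - log(phi + mu)) + y * (log(mu) - log(phi + mu))
}

#' Zero-inflated negative binomial log pmf
#'
#' Mixture of a point mass at zero (structural-zero probability `pi`)
#' and the NB component: `log(pi * 1(y == 0) + (1 - pi) * NB(y; mu, phi))`.
#'
#' @inheritParams nb_log_pmf
#' @param pi Structural-zero probability in `[0, 1)`.
#' @return Log probability mass, vectorized.
#' @export
zinb_log_pmf <- function(y, mu, phi, pi) {
  if (any(pi < 0) || any(pi >= 1))
    stop("pi must lie in [0, 1)", call. = FALSE)
  nb <- nb_log_pmf(y, mu, phi)
  n <- max(length(y), length(mu), length(phi), length(pi))
  y <- rep_len(y, n); pi <- rep_len(pi, n); nb <- rep_len(nb, n)
  out <- log1p(-pi) + nb
  if (any(y == 0)) {
    i <- y == 0
    # log(pi + (1-pi) nb0), stable via log-sum-exp
    a <- log(pmax(pi[i], .Machine$double.xmin))
    b <- log1p(-pi[i]) + nb[i]
    m <- pmax(a, b)
    out[i] <- ifelse(pi[i] == 0, b, m + log(exp(a - m) + exp(b - m)))
  }
  out
}

#' NB / ZINB cumulative distribution function
#'
#' @inheritParams zinb_log_pmf
#' @param q Quantile(s); `F(q) = 0` for `q < 0`.
#' @return `P(Y <= q)` under NB (`pi = 0`) or ZINB.
#' @export
zinb_cdf <- function(q, mu, phi, pi = 0) {
  base <- pnbinom(pmax(floor(q), -1), mu = mu, size = phi)
  out <- pi + (1 - pi) * base
  out[q < 0] <- 0
  out
}

#' Stage-wise linear predictors
#'
#' Evaluates the joint model's linear predictor for each stage:
#' larvae get intercept + harmonics + habitat + year + location effects;
#' nymphs add `beta_lagL * lag_log_larvae`; adults add
#' `beta_lagN * lag_log_nymphs`. Each stage uses its own intercept,
#' harmonic coefficients and location effect; habitat and lag
#' coefficients are shared across stages.
#'
#' @param rows A data.frame with design columns (`sin_term`, `cos_term`,
#'   `grass_ind`, `woods_ind`, `lag_log_larvae`, `lag_log_nymphs`,
#'   `year_index`, `location_index`), e.g. `build_design(panel)$X`.
#' @param params A list with elements `alpha` (3), `beta_sin` (3),
#'   `beta_cos` (3), `beta_grass`, `beta_woods`, `beta_lagL`, `beta_lagN`,
#'   and optionally `gamma` (per-year effects, indexed by
#'   `year_index + 1`), `u` (locations x 3 matrix), `offset`.
#' @return An n x 3 matrix of linear predictors eta; `mu = exp(eta)`.
#'   Nymph/adult entries are `NA` where the required lag is missing.
#' @export
linear_predictor <- function(rows, params) {
  n <- nrow(rows)
  gam <- if (!is.null(params$gamma)) params$gamma[rows$year_index + 1L] else 0
  off <- if (!is.null(params$offset)) params$offset else 0
  u <- params$u
  eta <- matrix(NA_real_, n, 3, dimnames = list(NULL, tick_stages()))
  for (j in 1:3) {
    uj <- if (!is.null(u)) u[rows$location_index + 1L, j] else 0
    e <- params$alpha[j] +
      params$beta_sin[j] * rows$sin_term +
      params$beta_cos[j] * rows$cos_term +
      params$beta_grass * rows$grass_ind +
      params$beta_woods * rows$woods_ind +
      gam + uj + off
    if (j == 2) e <- e + params$beta_lagL * rows$lag_log_larvae
    if (j == 3) e <- e + params$beta_lagN * rows$lag_log_nymphs
    eta[, j] <- e
  }
  eta
}
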