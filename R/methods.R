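# S3 methods for tick_fit objects.

#' @export
print.tick_fit <- function(x, ...) {
  cat(sprintf("Joint %s tick life-stage model (%s priors, %s year effect)\n",
              x$family, x$prior$name, x$year_effect))
  cat(sprintf("  %d monthly observations, %d locations, years %d-%d\n",
              nrow(x$panel), length(x$design$locations),
              min(x$design$years), max(x$design$years)))
  cat(sprintf("  %d posterior draws from the Laplace approximation%s\n",
              x$ndraws,
              if (x$converged) "" else "  [convergence warning]"))
  fx <- x$summary[1:10, c("mean", "sd")]
  cat("Fixed effects (posterior mean, SD):\n")
  print(round(fx, 3))
  invisible(x)
}

#' Posterior summary table for a fitted model
#'
#' Mean, SD, equal-tailed credible interval, split R-hat and effective
#' sample size for every reported parameter: stage-specific harmonic
#' coefficients, shared habitat and lag effects, intercepts, dispersions
#' `phi_j`, year-effect precision `tau_year`, location precisions
#' `tau_loc_j = 1/Sigma_jj`, cross-stage correlations `rho_jk` (computed
#' per draw from the covariance, then summarized), and structural-zero
#' probabilities `pi_j` for the ZINB. Model-fit criteria (DIC, WAIC) are
#' attached as an attribute and printed below the table.
#'
#' @param object A `tick_fit`.
#' @param ... Unused.
#' @return A data.frame (class `summary.tick_fit`), one row per parameter.
#' @export
summary.tick_fit <- function(object, ...) {
  out <- object$summary
  crit <- fit_criteria(object)
  attr(out, "criteria") <- crit
  attr(out, "family") <- object$family
  class(out) <- c("summary.tick_fit", "data.frame")
  out
}

#' @export
print.summary.tick_fit <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$`95% CI` <- sprintf("[%.*f, %.*f]", digits, df$lower, digits, df$upper)
  print(cbind(round(df[, c("mean", "sd")], digits), df["95% CI"],
              round(df[, c("rhat", "ess")], 2)))
  crit <- attr(x, "criteria")
  cat(sprintf("\nDIC %.2f (p_dic %.1f)   WAIC %.2f (p_waic %.1f)\n",
              crit$dic, crit$p_dic, crit$waic, crit$p_waic))
  invisible(x)
}

#' @export
coef.tick_fit <- function(object, ...) {
  setNames(object$summary$mean, rownames(object$summary))
}

#' Posterior-mean predictions
#'
#' @param object A `tick_fit`.
#' @param type `"response"` (expected counts, the NB mean; for ZINB the
#'   marginal mean `(1-pi) mu`) or `"link"` (posterior mean linear
#'   predictor).
#' @param ... Unused.
#' @return An n x 3 matrix (stages in columns) aligned with the panel
#'   rows; entries excluded from the likelihood (missing lag) are `NA`.
#' @export
predict.tick_fit <- function(object, type = c("response", "link"), ...) {
  type <- match.arg(type)
  n <- nrow(object$panel)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, tick_stages()))
  for (j in 1:3) {
    keep <- object$design$include[, j] == 1
    etaj <- rowMeans(object$eta_draws[[j]])
    if (type == "link") out[keep, j] <- etaj[keep]
    else {
      mu <- exp(etaj)
      if (object$family == "ZINB") mu <- (1 - mean(object$pars$pi[j, ])) * mu
      out[keep, j] <- mu[keep]
    }
  }
  out
}

#' Posterior predictive count simulations
#'
#' Draws replicated panels from the posterior predictive distribution:
#' for each simulation a posterior draw is selected and counts are drawn
#' from its NB (or ZINB) observation model at the stored linear
#' predictors.
#'
#' @param object A `tick_fit`.
#' @param nsim Number of replicated datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` n x 3 count matrices (NA where excluded).
#' @export
simulate.tick_fit <- function(object, nsim = 1, seed = NULL, ...) {
  runner <- function() {
    D <- object$ndraws
    lapply(seq_len(nsim), function(s) {
      d <- sample.int(D, 1)
      out <- matrix(NA_real_, nrow(object$panel), 3,
                    dimnames = list(NULL, tick_stages()))
      for (j in 1:3) {
        keep <- which(object$design$include[, j] == 1)
        mu <- exp(object$eta_draws[[j]][keep, d])
        y <- rnbinom(length(keep), mu = mu, size = object$pars$phi[j, d])
        if (object$family == "ZINB")
          y[runif(length(keep)) < object$pars$pi[j, d]] <- 0
        out[keep, j] <- y
      }
      out
    })
  }
  if (is.null(seed)) runner() else .with_seed(seed, runner())
}

#' Randomized quantile residuals
#'
#' Dunn-Smyth residuals: the randomized PIT of each retained observation
#' under its posterior predictive distribution, mapped through the
#' standard normal quantile function. Approximately N(0,1) under a
#' well-calibrated model.
#'
#' @param object A `tick_fit`.
#' @param seed Seed for the PIT randomization (independent of the
#'   sampler seed).
#' @param ... Unused.
#' @return An n x 3 matrix of residuals (NA where excluded).
#' @export
residuals.tick_fit <- function(object, seed = 1, ...) {
  pit <- pit_tick_fit(object, seed = seed)
  out <- matrix(NA_real_, nrow(object$panel), 3,
                dimnames = list(NULL, tick_stages()))
  u <- pmin(pmax(pit$pit_values, 1e-12), 1 - 1e-12)
  for (k in seq_len(nrow(object$loglik_obs)))
    out[object$loglik_obs$obs[k],
        as.character(object$loglik_obs$stage[k])] <- qnorm(u[k])
  out
}

#' Plot observed vs posterior predictive monthly curves
#'
#' One panel per life stage: mean observed count per calendar month
#' (points/line) against the posterior predictive mean with its
#' predictive band.
#'
#' @param x A `tick_fit`.
#' @param nsim Posterior predictive replicates for the band.
#' @param seed Seed for the predictive simulations.
#' @param ... Passed to [graphics::plot()].
#' @return The curve table from [posterior_predictive_monthly()],
#'   invisibly.
#' @export
plot.tick_fit <- function(x, nsim = 200, seed = 1, ...) {
  pp <- posterior_predictive_monthly(x, nsim = nsim, seed = seed)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (st in tick_stages()) {
    d <- pp[pp$stage == st, ]
    ylim <- range(c(d$observed, d$upper), na.rm = TRUE)
    graphics::plot(d$month, d$observed, type = "b", pch = 16,
                   xlab = "month", ylab = "mean count", main = st,
                   ylim = ylim, ...)
    graphics::polygon(c(d$month, rev(d$month)), c(d$lower, rev(d$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(d$month, d$predicted, col = "steelblue", lwd = 2)
  }
  invisible(pp)
}
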