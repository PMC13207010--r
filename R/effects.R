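# Derived effect summaries: seasonal-effect curves and peak months, the
# shared year-effect trajectory, and peak-timing ordering across stages.

#' Seasonal-effect curve for one life stage
#'
#' Evaluates `effect(M) = beta_sin * sin(2 pi M / 12) +
#' beta_cos * cos(2 pi M / 12)` on the integer month grid. The peak month
#' is the argmax over the grid (ties resolved to the earliest month); the
#' amplitude is `sqrt(beta_sin^2 + beta_cos^2)` and the continuous-phase
#' peak (from atan2) is reported for completeness.
#'
#' @param beta_sin,beta_cos Harmonic coefficients (log scale).
#' @param months Month grid (default 1:12).
#' @param stage Optional stage label carried in the result.
#' @return A `seasonal_curve` list with `stage`, `months`, `effect`,
#'   `peak_month`, `amplitude`, `peak_month_continuous`.
#' @export
seasonal_effect <- function(beta_sin, beta_cos, months = 1:12,
                            stage = NA_character_) {
  stopifnot(is.finite(beta_sin), is.finite(beta_cos))
  eff <- beta_sin * sin(2 * pi * months / 12) +
    beta_cos * cos(2 * pi * months / 12)
  amp <- sqrt(beta_sin^2 + beta_cos^2)
  # effect(M) = amp * cos(2 pi M/12 - phase), phase = atan2(beta_sin, beta_cos)
  phase <- atan2(beta_sin, beta_cos)
  cont <- (phase %% (2 * pi)) * 12 / (2 * pi)
  if (cont == 0) cont <- 12
  structure(list(stage = stage, months = months, effect = eff,
                 peak_month = months[which.max(eff)], amplitude = amp,
                 peak_month_continuous = cont),
            class = "seasonal_curve")
}

#' @export
print.seasonal_curve <- function(x, ...) {
  cat(sprintf("Seasonal curve%s: peak month %d (continuous %.2f), amplitude %.3f\n",
              if (is.na(x$stage)) "" else paste0(" [", x$stage, "]"),
              x$peak_month, x$peak_month_continuous, x$amplitude))
  invisible(x)
}

#' Seasonal curves for all stages of a fitted model
#'
#' @param fit A `tick_fit`.
#' @return A named list of three `seasonal_curve` objects (posterior-mean
#'   coefficients).
#' @export
seasonal_curves <- function(fit) {
  bs <- rowMeans(fit$pars$beta_sin)
  bc <- rowMeans(fit$pars$beta_cos)
  setNames(lapply(1:3, function(j)
    seasonal_effect(bs[j], bc[j], stage = tick_stages()[j])), tick_stages())
}

#' Order life stages by seasonal peak timing
#'
#' Sorts the per-stage curves by integer-grid peak month (stable on
#' ties) and reports whether the canonical phenological ordering holds:
#' adults no later than nymphs, larvae strictly after both.
#'
#' @param curves A list of three `seasonal_curve`s (larvae, nymphs,
#'   adults order, as from [seasonal_curves()]).
#' @return A list with `ordering` (data.frame stage/peak_month sorted by
#'   peak) and `canonical` (logical: adults <= nymphs < larvae).
#' @export
peak_ordering <- function(curves) {
  stopifnot(length(curves) == 3)
  peaks <- vapply(curves, function(cv) cv$peak_month, numeric(1))
  stages <- vapply(seq_along(curves), function(i) {
    s <- curves[[i]]$stage
    if (is.na(s)) tick_stages()[i] else s
  }, character(1))
  ord <- order(peaks)  # stable, preserves input order on ties
  df <- data.frame(stage = stages[ord], peak_month = peaks[ord])
  pl <- setNames(peaks, stages)
  canonical <- pl["adults"] <= pl["nymphs"] && pl["nymphs"] < pl["larvae"]
  list(ordering = df, canonical = unname(canonical))
}

#' Shared year-effect trajectory
#'
#' Posterior mean and equal-tailed credible interval of the shared year
#' effect, per panel year. Draws are centred (sum-to-zero) before
#' summarizing, so the reported series has mean zero; years whose CI
#' excludes zero are flagged.
#'
#' @param fit A `tick_fit`.
#' @param ci Credible level (defaults to the fit's level).
#' @return A `year_effect_series` data.frame with columns `year`, `mean`,
#'   `lower`, `upper`, `excludes_zero`.
#' @export
year_effect_series <- function(fit, ci = fit$ci) {
  g <- fit$pars$gamma                      # n_years x draws
  g <- sweep(g, 2, colMeans(g))            # exact sum-to-zero per draw
  s <- summarize_draws(t(g), ci = ci)
  out <- data.frame(year = fit$design$years, mean = s$mean,
                    lower = s$lower, upper = s$upper)
  out$excludes_zero <- out$lower > 0 | out$upper < 0
  class(out) <- c("year_effect_series", "data.frame")
  out
}
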