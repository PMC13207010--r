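# Descriptive diagnostics for count panels: per-stage mean, variance,
# variance-to-mean ratio, observed zero proportion and the zero
# proportion a Poisson model with the same mean would predict. A VMR
# far above 1 with an observed zero fraction far above exp(-mean) is the
# signature of overdispersed, zero-heavy ecological counts.

#' Poisson-expected probability of a zero count
#'
#' Under a Poisson model with the given mean, `P(Y = 0) = exp(-mean)`.
#' Comparing this against the observed zero proportion is the standard
#' first check for zero excess.
#'
#' @param mean_count Non-negative mean count(s).
#' @return `exp(-mean_count)`, vectorized.
#' @export
poisson_zero_prob <- function(mean_count) {
  stopifnot(all(mean_count >= 0))
  exp(-mean_count)
}

#' Variance-to-mean ratio
#'
#' @param variance,mean_count Scalars or vectors; `mean_count` must be
#'   positive.
#' @return `variance / mean_count`.
#' @export
vmr <- function(variance, mean_count) {
  stopifnot(all(mean_count > 0))
  variance / mean_count
}

#' Per-stage summary diagnostics of a monthly panel
#'
#' @param panel A monthly panel.
#' @return A data.frame with one row per life stage: `mean`, `variance`,
#'   `vmr`, `prop_zero`, `expected_zero_poisson`.
#' @export
stage_summary <- function(panel) {
  out <- do.call(rbind, lapply(tick_stages(), function(st) {
    y <- panel[[st]]
    m <- mean(y); v <- var(y)
    data.frame(stage = st, mean = m, variance = v, vmr = vmr(v, m),
               prop_zero = mean(y == 0),
               expected_zero_poisson = poisson_zero_prob(m))
  }))
  rownames(out) <- NULL
  out
}
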