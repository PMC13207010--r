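# Synthetic monthly panels drawn from the model's own generative
# structure, so every downstream stage (design, fitting, diagnostics,
# effect summaries) is testable without field data. The default truth is
# the fitted regime of a decade-long Virginia lone star tick survey:
# strong stage-specific phenology, lower abundance in grass and higher
# in woods than edge, positive lag coupling between successive stages,
# extreme larval overdispersion, and a gently declining shared year
# effect.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

.rmvnorm <- function(n, Sigma) {
  p <- ncol(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, p))
  R <- chol(Sigma)
  matrix(rnorm(n * p), n, p) %*% R
}

#' Build a location covariance from stage precisions and correlations
#'
#' @param tau_loc Length-3 positive precisions; the implied stage
#'   variances are `1/tau_loc`.
#' @param rho Length-3 correlations `(rho_LN, rho_LA, rho_NA)`.
#' @return A 3 x 3 positive-definite covariance matrix.
#' @export
make_sigma_loc <- function(tau_loc, rho) {
  stopifnot(length(tau_loc) == 3, all(tau_loc > 0),
            length(rho) == 3, all(abs(rho) < 1))
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- rho[1]
  R[1, 3] <- R[3, 1] <- rho[2]
  R[2, 3] <- R[3, 2] <- rho[3]
  s <- sqrt(1 / tau_loc)
  Sigma <- R * (s %o% s)
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("Sigma_loc is not positive definite", call. = FALSE)
  Sigma
}

#' Default simulation truth
#'
#' The default parameter values for [simulate_panel()]: harmonic, habitat
#' and lag coefficients, dispersions, year-effect precision and the
#' correlated location covariance are set to the posterior-mean regime of
#' a multi-site lone star tick survey fitted with this model class
#' (weakly informative priors). Stage intercepts are a package choice
#' (`alpha = (2.0, 0.5, 0.0)`) pinning realistic abundance scales;
#' structural-zero probabilities default to the covariate-driven-zeros
#' regime (high for larvae, negligible for nymphs and adults) and only
#' act under `family = "ZINB"`.
#'
#' @return A `tick_truth` list with elements `alpha`, `beta_sin`,
#'   `beta_cos`, `beta_grass`, `beta_woods`, `beta_lagL`, `beta_lagN`,
#'   `phi`, `tau_year`, `Sigma_loc`, `pi`, `year_effect_mode`, `gamma`
#'   (used by mode `"fixed_vector"`, else `NULL`).
#' @export
default_truth <- function() {
  structure(list(
    alpha = c(larvae = 2.0, nymphs = 0.5, adults = 0.0),
    beta_sin = c(larvae = -5.285, nymphs = -0.430, adults = 1.154),
    beta_cos = c(larvae = -2.483, nymphs = -3.624, adults = -5.093),
    beta_grass = -1.298,
    beta_woods = 0.496,
    beta_lagL = 0.212,
    beta_lagN = 0.107,
    phi = c(larvae = 0.077, nymphs = 0.467, adults = 1.061),
    tau_year = 6.912,
    Sigma_loc = make_sigma_loc(c(1.601, 1.749, 0.263),
                               c(0.667, 0.456, 0.787)),
    pi = c(larvae = 0.605, nymphs = 0.010, adults = 0.012),
    year_effect_mode = "linear_decline",
    gamma = NULL
  ), class = "tick_truth")
}

.default_habitats <- function(locations) {
  # mimic the study's design: one site lacks woods, one lacks edge
  hab <- rep(list(tick_habitats()), length(locations))
  names(hab) <- locations
  if (length(locations) >= 2) {
    hab[[1]] <- c("edge", "grass")
    hab[[2]] <- c("grass", "woods")
  }
  hab
}

#' Simulate a monthly multistage panel
#'
#' Draws a panel from the joint NB/ZINB model: one trivariate location
#' effect per location, a shared year effect, stage-specific harmonics,
#' habitat effects, and self-consistent lag propagation (the nymph
#' equation sees the previously *simulated* larval count, the adult
#' equation the previously simulated nymphal count). The first simulated
#' month of each (location, habitat) series uses a zero lag predictor and
#' is flagged `burn_in`.
#'
#' @param n_locations Number of locations (default 6). Ignored when
#'   `habitats` is given.
#' @param years Integer vector of consecutive years (default 2009:2018).
#' @param months Months sampled within each year (default 1:12).
#' @param truth A `tick_truth` list, see [default_truth()].
#' @param family `"NB"` or `"ZINB"` (structural zeros drawn independently
#'   per observation and stage with probabilities `truth$pi`).
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @param habitats Optional named list mapping location code to its
#'   sampled habitat subset; defaults to all three habitats except that
#'   the first location lacks woods and the second lacks edge, mirroring
#'   an unbalanced field design.
#' @return A monthly panel data.frame (as from [attach_lags()]) with an
#'   extra logical `burn_in` column, plus attributes `latents` (list with
#'   `u`, `gamma`, `eta`) and `truth`.
#' @export
simulate_panel <- function(n_locations = 6, years = 2009:2018,
                           months = 1:12, truth = default_truth(),
                           family = c("NB", "ZINB"), seed = 1,
                           habitats = NULL) {
  family <- match.arg(family)
  stopifnot(length(years) >= 1, all(months %in% 1:12))
  if (is.null(habitats)) {
    locations <- sprintf("S%02d", seq_len(n_locations))
    habitats <- .default_habitats(locations)
  } else {
    locations <- names(habitats)
    if (is.null(locations)) stop("habitats must be a named list", call. = FALSE)
  }
  if (any(lengths(habitats) == 0))
    stop("every location needs at least one habitat", call. = FALSE)
  Sigma <- truth$Sigma_loc
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < 0)
    stop("Sigma_loc is not positive semi-definite", call. = FALSE)

  .with_seed(seed, {
    n_loc <- length(locations)
    u <- .rmvnorm(n_loc, Sigma)
    rownames(u) <- locations
    colnames(u) <- tick_stages()
    ny <- length(years)
    gamma <- switch(truth$year_effect_mode,
      linear_decline = if (ny == 1) 0 else seq(0.4, -0.4, length.out = ny),
      rw1 = {
        g <- cumsum(c(0, rnorm(ny - 1, 0, sqrt(1 / truth$tau_year))))
        g - mean(g)
      },
      fixed_vector = {
        if (is.null(truth$gamma) || length(truth$gamma) != ny)
          stop("fixed_vector mode needs truth$gamma of length ", ny,
               call. = FALSE)
        truth$gamma
      },
      stop("unknown year_effect_mode: ", truth$year_effect_mode,
           call. = FALSE))
    names(gamma) <- years

    grid <- expand.grid(month = sort(months), year = years,
                        stringsAsFactors = FALSE)
    out <- vector("list", 0)
    for (loc in locations) {
      for (hab in habitats[[loc]]) {
        harm <- encode_harmonics(grid$month)
        hd <- encode_habitat(rep(hab, nrow(grid)))
        cnt <- matrix(0L, nrow(grid), 3)
        eta_all <- matrix(NA_real_, nrow(grid), 3)
        prevL <- NA_real_; prevN <- NA_real_
        contiguous <- c(FALSE, diff(grid$year * 12 + grid$month) == 1)
        for (r in seq_len(nrow(grid))) {
          lagL <- if (contiguous[r]) log(prevL + 1) else 0
          lagN <- if (contiguous[r]) log(prevN + 1) else 0
          for (j in 1:3) {
            eta <- truth$alpha[j] +
              truth$beta_sin[j] * harm[r, 1] + truth$beta_cos[j] * harm[r, 2] +
              truth$beta_grass * hd[r, 1] + truth$beta_woods * hd[r, 2] +
              gamma[as.character(grid$year[r])] + u[loc, j]
            if (j == 2) eta <- eta + truth$beta_lagL * lagL
            if (j == 3) eta <- eta + truth$beta_lagN * lagN
            y <- rnbinom(1, mu = exp(eta), size = truth$phi[j])
            if (family == "ZINB" && runif(1) < truth$pi[j]) y <- 0L
            cnt[r, j] <- y
            eta_all[r, j] <- eta
          }
          prevL <- cnt[r, 1]; prevN <- cnt[r, 2]
        }
        out[[length(out) + 1]] <- data.frame(
          location = loc, habitat = hab, year = grid$year,
          month = grid$month, n_visits = 1L,
          larvae = cnt[, 1], nymphs = cnt[, 2], adults = cnt[, 3],
          burn_in = !contiguous,
          eta_larvae = eta_all[, 1], eta_nymphs = eta_all[, 2],
          eta_adults = eta_all[, 3])
      }
    }
    panel <- do.call(rbind, out)
    panel$habitat <- factor(panel$habitat, levels = tick_habitats())
    panel <- panel[order(panel$location, as.integer(panel$habitat),
                         panel$year, panel$month), ]
    rownames(panel) <- NULL
    eta <- as.matrix(panel[, c("eta_larvae", "eta_nymphs", "eta_adults")])
    colnames(eta) <- tick_stages()
    panel <- panel[, c("location", "habitat", "year", "month", "n_visits",
                       "larvae", "nymphs", "adults", "burn_in")]
    panel$lag_log_larvae <- NA_real_
    panel$lag_log_nymphs <- NA_real_
    panel <- attach_lags(panel)
    attr(panel, "latents") <- list(u = u, gamma = gamma, eta = eta)
    attr(panel, "truth") <- truth
    panel
  })
}
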