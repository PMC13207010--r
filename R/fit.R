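# Model fitting. The joint negative log posterior (likelihood + priors
# over fixed effects, random effects and transformed hyperparameters) is
# implemented in src/tickstages.cpp; TMB supplies derivatives and the
# Laplace approximation over the year and location random effects. The
# posterior is then approximated by a Gaussian centred at the joint mode
# with the joint Hessian as precision, and independent draws from that
# Gaussian drive every downstream summary (credible intervals, WAIC/DIC,
# PIT, posterior predictive checks).

.fit_data <- function(design, family, year_effect, prior, include_offset) {
  X <- design$X
  list(
    Y = unname(design$Y),
    sin_t = X$sin_term, cos_t = X$cos_term,
    grass = X$grass_ind, woods = X$woods_ind,
    lagL = ifelse(is.na(X$lag_log_larvae), 0, X$lag_log_larvae),
    lagN = ifelse(is.na(X$lag_log_nymphs), 0, X$lag_log_nymphs),
    offs = if (include_offset) X$log_n_visits else rep(0, nrow(X)),
    year_i = X$year_index, loc_i = X$location_index,
    incl = unname(design$include),
    family = if (family == "ZINB") 1L else 0L,
    year_mode = if (year_effect == "iid") 1L else 0L,
    beta_sd = prior$fixed_sd,
    tau_shape = prior$tau_year_shape, tau_rate = prior$tau_year_rate,
    phi_shape = prior$phi_shape, phi_rate = prior$phi_rate,
    iw_df = prior$sigma_df, iw_scale = prior$sigma_scale,
    pi_a = prior$pi_a, pi_b = prior$pi_b
  )
}

.fit_init <- function(design) {
  Y <- design$Y
  list(
    alpha = log(colMeans(Y) + 0.5),
    beta_sin = rep(0, 3), beta_cos = rep(0, 3),
    beta_grass = 0, beta_woods = 0, beta_lagL = 0, beta_lagN = 0,
    log_phi = rep(log(0.5), 3),
    log_tau_year = log(5),
    chol_diag = rep(log(0.7), 3),
    chol_off = rep(0, 3),
    logit_pi = rep(qlogis(0.1), 3),
    gamma = rep(0, length(design$years)),
    u = matrix(0, length(design$locations), 3)
  )
}

.idx_by_name <- function(nms) split(seq_along(nms), factor(nms, unique(nms)))

#' Fit the joint tick life-stage abundance model
#'
#' Fits the multivariate NB or ZINB model to a prepared monthly panel:
#' stage-specific intercepts and annual harmonics, shared habitat effects
#' (edge reference), lagged `log(count+1)` cross-stage predictors,
#' a shared year random effect (RW1 with sum-to-zero, or iid), and one
#' trivariate normal location effect per location with a common
#' covariance. Inference is a Laplace (Gaussian) approximation to the
#' joint posterior; `ndraws` independent draws from that approximation
#' are stored along with the per-observation log-likelihood matrix.
#'
#' Observations whose required lag predictor is missing are dropped from
#' the nymph/adult likelihood contributions but kept for the larval
#' equation.
#'
#' @param panel A monthly panel with lags attached ([attach_lags()] or
#'   [simulate_panel()]).
#' @param family `"NB"` or `"ZINB"`.
#' @param prior A prior set name (`"set1"`, `"set2"`, `"set3"`) or a
#'   `prior_config` from [build_prior_set()].
#' @param year_effect `"rw1"` (default; smooth trend) or `"iid"`.
#' @param include_offset If `TRUE`, adds `log(n_visits)` as an offset.
#' @param ndraws Number of posterior draws to store (default 1000).
#' @param seed Seed for the posterior draws (and nothing else; the
#'   Laplace mode is deterministic).
#' @param ci Credible level for reported intervals.
#' @param pi_fixed Optional: fix the ZINB structural-zero probabilities
#'   at this value instead of estimating them (e.g. `0` makes the ZINB
#'   likelihood collapse to the NB).
#' @param verbose Print optimizer progress.
#' @return An object of class `tick_fit`; see [summary.tick_fit()],
#'   [coef.tick_fit()], [predict.tick_fit()], [simulate.tick_fit()],
#'   [residuals.tick_fit()], [plot.tick_fit()].
#' @export
tick_fit <- function(panel, family = c("NB", "ZINB"), prior = "set1",
                     year_effect = c("rw1", "iid"), include_offset = FALSE,
                     ndraws = 1000, seed = 1, ci = 0.95, pi_fixed = NULL,
                     verbose = FALSE) {
  family <- match.arg(family)
  year_effect <- match.arg(year_effect)
  prior <- .as_prior(prior)
  stopifnot(ndraws >= 8, ci > 0, ci < 1)
  design <- build_design(panel)
  zero_stage <- colSums(design$Y) == 0
  if (any(zero_stage))
    warning("stage(s) with all-zero counts: ",
            paste(tick_stages()[zero_stage], collapse = ", "),
            " (a zero-inflated family may be more appropriate)",
            call. = FALSE)

  dat <- .fit_data(design, family, year_effect, prior, include_offset)
  par0 <- .fit_init(design)
  map <- list()
  if (family == "NB") {
    par0$logit_pi <- rep(-20, 3)
    map$logit_pi <- factor(rep(NA, 3))
  } else if (!is.null(pi_fixed)) {
    p <- pmin(pmax(pi_fixed, 1e-9), 1 - 1e-9)
    par0$logit_pi <- rep_len(qlogis(p), 3)
    map$logit_pi <- factor(rep(NA, 3))
  }

  obj <- TMB::MakeADFun(data = dat, parameters = par0,
                        random = c("gamma", "u"), map = map,
                        DLL = "tickstages", silent = !verbose)
  opt <- nlminb(obj$par, obj$fn, obj$gr,
                control = list(iter.max = 1000, eval.max = 2000))
  # one polishing restart from the first optimum
  opt2 <- try(nlminb(opt$par, obj$fn, obj$gr,
                     control = list(iter.max = 500, eval.max = 1000)),
              silent = TRUE)
  if (!inherits(opt2, "try-error") && is.finite(opt2$objective) &&
      opt2$objective <= opt$objective) opt <- opt2
  rep <- TMB::sdreport(obj, getJointPrecision = TRUE)
  # judge convergence by the stationarity conditions, not nlminb's code
  # (its "false convergence" fires even at negligible gradients)
  grad_max <- max(abs(rep$gradient.fixed))
  converged <- isTRUE(rep$pdHess) && grad_max < 0.1
  if (!converged)
    warning(sprintf(
      "fit may not have converged (nlminb: %s, pdHess %s, max|grad| %.3g)",
      opt$message, rep$pdHess, grad_max), call. = FALSE)

  mode <- obj$env$last.par.best
  Q <- rep$jointPrecision
  if (is.null(Q) || nrow(Q) != length(mode))
    stop("could not obtain the joint precision of the Laplace approximation",
         call. = FALSE)
  R <- chol(as.matrix(Q))
  draws_mat <- .with_seed(seed, {
    Z <- matrix(rnorm(length(mode) * ndraws), length(mode), ndraws)
    mode + backsolve(R, Z)
  })
  rownames(draws_mat) <- names(mode)
  idx <- .idx_by_name(names(mode))

  fit <- structure(list(
    panel = panel, design = design, family = family, prior = prior,
    year_effect = year_effect, include_offset = include_offset,
    ndraws = ndraws, seed = seed, ci = ci,
    pi_fixed = if (family == "ZINB" && !is.null(pi_fixed)) pi_fixed else NULL,
    opt = opt, converged = converged, grad_max = grad_max,
    mode = mode, draws_mat = draws_mat, idx = idx
  ), class = "tick_fit")
  fit <- .fit_postprocess(fit)
  fit
}

# Transform raw draws into interpretable parameter draws, the
# per-observation linear predictors, and the log-likelihood matrix.
.fit_postprocess <- function(fit) {
  dm <- fit$draws_mat; idx <- fit$idx
  D <- ncol(dm)
  g <- function(nm) dm[idx[[nm]], , drop = FALSE]
  pars <- list(
    alpha = g("alpha"), beta_sin = g("beta_sin"), beta_cos = g("beta_cos"),
    beta_grass = g("beta_grass"), beta_woods = g("beta_woods"),
    beta_lagL = g("beta_lagL"), beta_lagN = g("beta_lagN"),
    phi = exp(g("log_phi")), tau_year = exp(g("log_tau_year")),
    chol_diag = g("chol_diag"), chol_off = g("chol_off"),
    gamma = g("gamma"), u = g("u")
  )
  if (fit$family == "ZINB") {
    pars$pi <- if ("logit_pi" %in% names(idx)) plogis(g("logit_pi"))
               else matrix(rep(pmin(pmax(rep_len(fit$pi_fixed, 3), 0), 1 - 1e-12),
                               D), 3, D)
  }
  # Sigma-derived quantities per draw
  tau_loc <- matrix(NA_real_, 3, D)
  rho <- matrix(NA_real_, 3, D)
  for (s in seq_len(D)) {
    L <- matrix(0, 3, 3)
    diag(L) <- exp(pars$chol_diag[, s])
    L[2, 1] <- pars$chol_off[1, s]
    L[3, 1] <- pars$chol_off[2, s]
    L[3, 2] <- pars$chol_off[3, s]
    Sg <- L %*% t(L)
    tr <- sigma_to_tau_rho(Sg)
    tau_loc[, s] <- tr$tau
    rho[, s] <- tr$rho
  }
  pars$tau_loc <- tau_loc
  pars$rho <- rho
  fit$pars <- pars

  # linear predictors, n x D per stage
  X <- fit$design$X
  n <- nrow(X)
  n_loc <- length(fit$design$locations)
  offs <- if (fit$include_offset) X$log_n_visits else rep(0, n)
  eta <- vector("list", 3)
  for (j in 1:3) {
    uj <- pars$u[(j - 1) * n_loc + (X$location_index + 1L), , drop = FALSE]
    e <- tcrossprod(cbind(1, X$sin_term, X$cos_term, X$grass_ind, X$woods_ind),
                    t(rbind(pars$alpha[j, ], pars$beta_sin[j, ],
                            pars$beta_cos[j, ], pars$beta_grass,
                            pars$beta_woods)))
    e <- e + pars$gamma[X$year_index + 1L, , drop = FALSE] + uj + offs
    if (j == 2) {
      lag <- ifelse(is.na(X$lag_log_larvae), 0, X$lag_log_larvae)
      e <- e + lag %o% pars$beta_lagL[1, ]
    }
    if (j == 3) {
      lag <- ifelse(is.na(X$lag_log_nymphs), 0, X$lag_log_nymphs)
      e <- e + lag %o% pars$beta_lagN[1, ]
    }
    eta[[j]] <- e
  }
  names(eta) <- tick_stages()
  fit$eta_draws <- eta

  # per-observation log-likelihood matrix (draws x retained obs-stage)
  incl <- fit$design$include
  Y <- fit$design$Y
  ll_list <- list()
  obs_tab <- list()
  for (j in 1:3) {
    keep <- which(incl[, j] == 1)
    if (length(keep) == 0) next
    mu <- exp(eta[[j]][keep, , drop = FALSE])
    y <- Y[keep, j]
    phij <- matrix(pars$phi[j, ], length(keep), D, byrow = TRUE)
    ll <- nb_log_pmf(y, mu, phij)
    if (fit$family == "ZINB") {
      pij <- matrix(pars$pi[j, ], length(keep), D, byrow = TRUE)
      is0 <- y == 0
      ll <- log1p(-pij) + ll
      if (any(is0)) {
        a <- log(pij[is0, , drop = FALSE])
        b <- ll[is0, , drop = FALSE]
        m <- pmax(a, b)
        ll[is0, ] <- m + log(exp(a - m) + exp(b - m))
      }
    }
    ll_list[[length(ll_list) + 1]] <- ll
    obs_tab[[length(obs_tab) + 1]] <-
      data.frame(obs = keep, stage = tick_stages()[j])
  }
  fit$loglik <- t(do.call(rbind, ll_list))        # draws x K
  fit$loglik_obs <- do.call(rbind, obs_tab)

  # plug-in log-likelihood at posterior means (conditional focus:
  # posterior means of per-observation eta and of the hyperparameters)
  ll_hat <- numeric(0)
  phi_mean <- rowMeans(pars$phi)
  pi_mean <- if (fit$family == "ZINB") rowMeans(pars$pi) else NULL
  for (j in 1:3) {
    keep <- which(incl[, j] == 1)
    if (length(keep) == 0) next
    mu_hat <- exp(rowMeans(eta[[j]][keep, , drop = FALSE]))
    y <- Y[keep, j]
    lh <- if (fit$family == "ZINB")
      zinb_log_pmf(y, mu_hat, phi_mean[j], pi_mean[j])
    else nb_log_pmf(y, mu_hat, phi_mean[j])
    ll_hat <- c(ll_hat, lh)
  }
  fit$loglik_at_mean <- ll_hat

  fit$summary <- .fit_summary_table(fit)
  fit
}

.fit_summary_table <- function(fit) {
  p <- fit$pars
  rows <- list(
    beta_sin_L = p$beta_sin[1, ], beta_sin_N = p$beta_sin[2, ],
    beta_sin_A = p$beta_sin[3, ],
    beta_cos_L = p$beta_cos[1, ], beta_cos_N = p$beta_cos[2, ],
    beta_cos_A = p$beta_cos[3, ],
    beta_grass = p$beta_grass[1, ], beta_woods = p$beta_woods[1, ],
    beta_lagL = p$beta_lagL[1, ], beta_lagN = p$beta_lagN[1, ],
    alpha_L = p$alpha[1, ], alpha_N = p$alpha[2, ], alpha_A = p$alpha[3, ],
    phi_L = p$phi[1, ], phi_N = p$phi[2, ], phi_A = p$phi[3, ],
    tau_year = p$tau_year[1, ],
    tau_loc_L = p$tau_loc[1, ], tau_loc_N = p$tau_loc[2, ],
    tau_loc_A = p$tau_loc[3, ],
    rho_LN = p$rho[1, ], rho_LA = p$rho[2, ], rho_NA = p$rho[3, ]
  )
  if (fit$family == "ZINB") {
    rows$pi_L <- p$pi[1, ]; rows$pi_N <- p$pi[2, ]; rows$pi_A <- p$pi[3, ]
  }
  m <- do.call(cbind, rows)
  out <- summarize_draws(m, ci = fit$ci)
  out$rhat <- apply(m, 2, split_rhat)
  out$ess <- apply(m, 2, ess)
  bad <- !is.na(out$rhat) & (out$rhat > 1.01 | out$ess < min(400, fit$ndraws / 2))
  if (any(bad))
    warning("convergence contract violated for: ",
            paste(rownames(out)[bad], collapse = ", "), call. = FALSE)
  out
}
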