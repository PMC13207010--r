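test_that("the NB fit recovers the generating fixed effects", {
  fit <- cached_nb_fit()
  tr <- attr(fit$panel, "truth")
  sm <- fit$summary
  # each fixed effect within 3 posterior SDs of its truth
  truths <- c(beta_sin_L = tr$beta_sin[[1]], beta_sin_N = tr$beta_sin[[2]],
              beta_sin_A = tr$beta_sin[[3]], beta_cos_L = tr$beta_cos[[1]],
              beta_cos_N = tr$beta_cos[[2]], beta_cos_A = tr$beta_cos[[3]],
              beta_grass = tr$beta_grass, beta_woods = tr$beta_woods,
              beta_lagL = tr$beta_lagL, beta_lagN = tr$beta_lagN)
  z <- abs(sm[names(truths), "mean"] - truths) / sm[names(truths), "sd"]
  expect_lt(max(z), 4)
  expect_gt(mean(z < 3), 0.8)
  # structure of the summary
  expect_true(all(sm$lower <= sm$upper))
  expect_true(all(sm[c("phi_L", "phi_N", "phi_A", "tau_year"), "mean"] > 0))
  expect_true(all(abs(sm[c("rho_LN", "rho_LA", "rho_NA"), "mean"]) < 1))
  expect_false("pi_L" %in% rownames(sm))   # NB reports no zero-inflation
})

test_that("stored pointwise log-likelihoods match an independent oracle", {
  fit <- cached_nb_fit()
  K <- nrow(fit$loglik_obs)
  expect_equal(ncol(fit$loglik), K)
  expect_equal(K, sum(fit$design$include))
  s <- 7  # one arbitrary draw
  ll <- numeric(K)
  for (k in seq_len(K)) {
    j <- match(fit$loglik_obs$stage[k], tick_stages())
    o <- fit$loglik_obs$obs[k]
    ll[k] <- dnbinom(fit$design$Y[o, j],
                     mu = exp(fit$eta_draws[[j]][o, s]),
                     size = fit$pars$phi[j, s], log = TRUE)
  }
  expect_equal(unname(fit$loglik[s, ]), ll, tolerance = 1e-10)
})

test_that("ZINB with zero-pinned mixture reproduces the NB posterior", {
  panel <- simulate_panel(years = 2014:2015, seed = 42)
  f_nb <- suppressWarnings(tick_fit(panel, family = "NB", ndraws = 500,
                                    seed = 1))
  f_zp <- suppressWarnings(tick_fit(panel, family = "ZINB", pi_fixed = 0,
                                    ndraws = 500, seed = 2))
  for (par in c("beta_grass", "beta_woods", "beta_sin_L", "phi_L")) {
    ks <- suppressWarnings(ks.test(
      .draws_for(f_nb, par), .draws_for(f_zp, par)))$statistic
    expect_lt(unname(ks), 0.1)
  }
})

test_that("relabeling locations leaves the coefficient posteriors unchanged", {
  panel <- simulate_panel(years = 2014:2015, seed = 42)
  perm <- panel
  relab <- c(S01 = "Z9", S02 = "A1", S03 = "M5", S04 = "B2", S05 = "Q7",
             S06 = "C3")
  perm$location <- unname(relab[perm$location])
  f1 <- suppressWarnings(tick_fit(panel, ndraws = 500, seed = 1))
  f2 <- suppressWarnings(tick_fit(perm, ndraws = 500, seed = 1))
  fx <- rownames(f1$summary)[1:10]
  expect_equal(f1$summary[fx, "mean"], f2$summary[fx, "mean"],
               tolerance = 0.05)
})

test_that("an all-zero stage triggers the zero-inflation advisory", {
  panel <- simulate_panel(years = 2014, seed = 3)
  panel$adults <- 0L
  # the advisory fires before the (degenerate) optimization starts
  w <- tryCatch(tick_fit(panel, ndraws = 100, seed = 1),
                warning = function(w) conditionMessage(w))
  expect_match(w, "all-zero")
})

test_that("Laplace posterior agrees with an MCMC fit of the same model", {
  skip_if_not_installed("rjags")
  panel <- simulate_panel(years = 2014:2015, seed = 42)
  fit <- cached_nb_fit()
  d <- build_design(panel)
  jd <- list(
    n = nrow(d$X),
    sin_t = d$X$sin_term, cos_t = d$X$cos_term,
    grass = d$X$grass_ind, woods = d$X$woods_ind,
    lagL = ifelse(is.na(d$X$lag_log_larvae), 0, d$X$lag_log_larvae),
    lagN = ifelse(is.na(d$X$lag_log_nymphs), 0, d$X$lag_log_nymphs),
    incl = unname(d$include),
    year = d$X$year_index + 1L, loc = d$X$location_index + 1L,
    ny = length(d$years), nl = length(d$locations),
    I3 = diag(3), zeros3 = rep(0, 3), zero = 0)
  model <- "
  model {
    for (o in 1:n) {
      for (j in 1:3) {
        eta[o,j] <- alpha[j] + bsin[j]*sin_t[o] + bcos[j]*cos_t[o] +
          bg*grass[o] + bw*woods[o] + g[year[o]] + u[loc[o],j] +
          equals(j,2)*blagL*lagL[o] + equals(j,3)*blagN*lagN[o]
        # NB(mu, phi) as a Poisson-Gamma mixture
        gmix[o,j] ~ dgamma(phi[j], phi[j])
        Yobs[o,j] ~ dpois(incl[o,j] * exp(eta[o,j]) * gmix[o,j] + 1.0E-10)
      }
    }
    for (j in 1:3) {
      alpha[j] ~ dnorm(0, 0.001)
      bsin[j] ~ dnorm(0, 0.001)
      bcos[j] ~ dnorm(0, 0.001)
      phi[j] ~ dgamma(1, 5.0E-5)
    }
    bg ~ dnorm(0, 0.001); bw ~ dnorm(0, 0.001)
    blagL ~ dnorm(0, 0.001); blagN ~ dnorm(0, 0.001)
    tau ~ dgamma(1, 5.0E-5)
    g[1] ~ dnorm(0, 0.01)
    for (t in 2:ny) { g[t] ~ dnorm(g[t-1], tau) }
    zero ~ dnorm(sum(g), 1.0E6)
    Omega ~ dwish(I3, 4)
    for (i in 1:nl) { u[i,1:3] ~ dmnorm(zeros3, Omega) }
  }"
  # excluded observation-stage terms enter with mu = 0 (p = 1), i.e. a
  # point mass at zero: make the observed value 0 there so the term is
  # a likelihood constant
  jd$Yobs <- unname(d$Y) * jd$incl
  jm <- suppressWarnings(
    rjags::jags.model(textConnection(model), data = jd,
                      n.chains = 1, n.adapt = 300, quiet = TRUE))
  sm <- rjags::coda.samples(jm, c("bg", "bw", "blagL"), n.iter = 1500)
  mc <- colMeans(as.matrix(sm))
  lap <- fit$summary[c("beta_lagL", "beta_grass", "beta_woods"), ]
  expect_lt(abs(mc[["bg"]] - lap["beta_grass", "mean"]),
            4 * lap["beta_grass", "sd"])
  expect_lt(abs(mc[["bw"]] - lap["beta_woods", "mean"]),
            4 * lap["beta_woods", "sd"])
  expect_lt(abs(mc[["blagL"]] - lap["beta_lagL", "mean"]),
            4 * lap["beta_lagL", "sd"])
})

test_that("draw summaries and covariance transforms follow reporting conventions", {
  s <- summarize_draws(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)   # sample SD
  expect_true(s$lower <= s$mean && s$mean <= s$upper)
  # identity covariance: unit precisions, zero correlations
  tr0 <- sigma_to_tau_rho(diag(3))
  expect_equal(unname(tr0$tau), c(1, 1, 1))
  expect_equal(unname(tr0$rho), c(0, 0, 0))
  # off-diagonal 0.5 with unit variances: rho_NA = 0.5
  Sg <- diag(3); Sg[2, 3] <- Sg[3, 2] <- 0.5
  expect_equal(sigma_to_tau_rho(Sg)$rho[["rho_NA"]], 0.5)
})

test_that("prediction, simulation and residual methods are coherent", {
  fit <- cached_nb_fit()
  mu <- predict(fit, type = "response")
  eta <- predict(fit, type = "link")
  keep <- !is.na(mu[, "larvae"])
  expect_equal(mu[keep, "larvae"], exp(eta[keep, "larvae"]))
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_true(all(sims[[1]] >= 0, na.rm = TRUE))
  r <- residuals(fit, seed = 2)
  r <- r[!is.na(r)]
  # randomized quantile residuals are roughly standard normal under fit
  expect_lt(abs(mean(r)), 0.2)
  expect_lt(abs(sd(r) - 1), 0.2)
})
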