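test_that("WAIC matches hand-computed and brute-force evaluations", {
  # two identical draws, one observation
  m <- matrix(log(0.5), 2, 1)
  w <- compute_waic(m)
  expect_equal(w$lppd, log(0.5), tolerance = 1e-12)
  expect_equal(w$p_waic, 0, tolerance = 1e-12)
  expect_equal(w$waic, 2 * log(2), tolerance = 1e-12)

  # two distinct draws
  m2 <- matrix(c(log(0.25), log(0.75)), 2, 1)
  w2 <- compute_waic(m2)
  expect_equal(w2$lppd, log(0.5), tolerance = 1e-12)
  expect_equal(w2$p_waic, var(c(log(0.25), log(0.75))), tolerance = 1e-12)
  expect_equal(w2$waic, -2 * (log(0.5) - var(c(log(0.25), log(0.75)))),
               tolerance = 1e-12)

  # brute-force oracle on a random matrix
  set.seed(1)
  M <- matrix(log(runif(60, 0.01, 1)), 6, 10)
  bf_lppd <- 0; bf_p <- 0
  for (i in 1:10) {
    bf_lppd <- bf_lppd + log(mean(exp(M[, i])))
    bf_p <- bf_p + var(M[, i])
  }
  w3 <- compute_waic(M)
  expect_equal(w3$waic, -2 * (bf_lppd - bf_p), tolerance = 1e-10)
  # invariant linking the pieces
  expect_equal(w3$waic, -2 * (w3$lppd - w3$p_waic), tolerance = 1e-8)

  # additivity over independent observations
  A <- M[, 1:4]; B <- M[, 5:10]
  expect_equal(compute_waic(M)$waic,
               compute_waic(A)$waic + compute_waic(B)$waic,
               tolerance = 1e-10)
  expect_error(compute_waic(M[1, , drop = FALSE]), "2 draws")
})

test_that("DIC matches hand evaluation and is order-invariant", {
  # degenerate posterior: all draws equal
  m <- matrix(rep(c(-1.3, -0.4), each = 3), 3, 2)
  d <- compute_dic(m, c(-1.3, -0.4))
  expect_equal(d$p_dic, 0, tolerance = 1e-12)
  expect_equal(d$dic, d$Dhat, tolerance = 1e-12)

  # hand-built 2-draw, 1-observation case
  m2 <- matrix(c(-2, -1), 2, 1)
  d2 <- compute_dic(m2, -1.2)
  Dbar <- mean(c(4, 2)); Dhat <- 2.4
  expect_equal(d2$dic, Dhat + 2 * (Dbar - Dhat), tolerance = 1e-10)

  # permutation of observations
  set.seed(2)
  M <- matrix(-abs(rnorm(40)), 4, 10)
  ph <- -abs(rnorm(10))
  perm <- sample(10)
  expect_equal(compute_dic(M, ph)$dic,
               compute_dic(M[, perm], ph[perm])$dic, tolerance = 1e-12)
  expect_error(compute_dic(M, ph[1:3]), "match")
})

test_that("randomized PIT is uniform for calibrated predictives", {
  # degenerate predictive: all mass at the observed value -> u ~ U(0,1)
  n <- 2000
  y <- rep(5, n)
  cdf <- function(q) as.numeric(q >= 5)
  pit <- compute_pit(y, cdf, seed = 1)
  expect_true(all(pit$pit_values >= 0 & pit$pit_values <= 1))
  expect_gt(pit$ks_p, 0.01)

  # counts drawn from their own NB predictive
  set.seed(3)
  mu <- exp(runif(n, 0, 4)); phi <- 0.5
  y <- rnbinom(n, mu = mu, size = phi)
  cdf <- function(q) zinb_cdf(q, mu, phi)
  expect_gt(compute_pit(y, cdf, seed = 2)$ks_p, 0.01)

  # systematically underestimated counts pile PIT mass near 1
  y_big <- rnbinom(n, mu = 4 * mu, size = phi)
  pit_b <- compute_pit(y_big, cdf, seed = 2)
  expect_lt(pit_b$ks_p, 0.01)
  expect_gt(mean(pit_b$pit_values), 0.55)

  expect_error(compute_pit(c(1, 2), function(q) q * 2), "CDF")
})

test_that("posterior predictive monthly curves cover the observed curve", {
  fit <- cached_nb_fit()
  pp <- posterior_predictive_monthly(fit, nsim = 200, seed = 4)
  expect_equal(nrow(pp), 36)   # 12 months x 3 stages
  for (st in tick_stages()) {
    d <- pp[pp$stage == st, ]
    expect_equal(sort(d$month), 1:12)
    covered <- mean(d$observed >= d$lower & d$observed <= d$upper)
    expect_gte(covered, 11 / 12)
  }
})

test_that("zero profiles count zeros by habitat, month and their crossing", {
  p <- toy_panel()
  p$larvae <- c(0L, 0L, 5L)
  zp <- zero_profile(p)
  g <- zp$by_habitat
  expect_equal(g$prop_zero[g$stage == "larvae" & g$habitat == "grass"], 2 / 3)
  expect_equal(g$n[g$stage == "larvae" & g$habitat == "grass"], 3)
  p2 <- toy_panel()
  p2$larvae <- c(1L, 2L, 3L); p2$nymphs <- c(1L, 1L, 1L); p2$adults <- c(2L, 1L, 4L)
  expect_true(all(zero_profile(p2)$by_month$prop_zero == 0))
  hm <- zp$by_habitat_month
  expect_true(all(c("habitat", "month", "prop_zero", "n", "stage") %in% names(hm)))
})

test_that("model comparison reports criterion deltas and guards inputs", {
  a <- structure(list(dic = 11251.57, waic = 11280.74, n_obs = 100),
                 class = "fit_criteria")
  b <- structure(list(dic = 11242.28, waic = 11271.14, n_obs = 100),
                 class = "fit_criteria")
  cmp <- compare_models(a, b)
  expect_equal(cmp$delta_dic, 9.29, tolerance = 1e-9)
  expect_equal(cmp$delta_waic, 9.60, tolerance = 1e-9)
  expect_match(cmp$note, "calibration")
  same <- compare_models(a, a)
  expect_equal(same$delta_dic, 0)
  b$n_obs <- 99
  expect_error(compare_models(a, b), "different observation sets")
})
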