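test_that("seasonal-effect curves evaluate the harmonic and locate peaks", {
  flat <- seasonal_effect(0, 0)
  expect_equal(flat$effect, rep(0, 12))
  expect_equal(flat$amplitude, 0)

  adult <- seasonal_effect(1.154, -5.093, stage = "adults")
  expect_equal(adult$effect[adult$months == 6], 5.093, tolerance = 1e-12)
  expect_equal(adult$peak_month, 6)

  larva <- seasonal_effect(-5.285, -2.483, stage = "larvae")
  expect_equal(larva$peak_month, 8)
  expect_equal(larva$effect[larva$months == 8], 5.818, tolerance = 1e-3)

  # amplitude bounds the curve
  for (cv in list(adult, larva))
    expect_gte(cv$amplitude + 1e-12, max(abs(cv$effect)))
  # periodicity through the continuous representation
  expect_equal(adult$effect,
               1.154 * sin(2 * pi * (13:24) / 12) -
                 5.093 * cos(2 * pi * (13:24) / 12), tolerance = 1e-12)
})

test_that("integer-grid peaks track the continuous phase within one month", {
  set.seed(7)
  for (r in 1:50) {
    bs <- runif(1, -6, 6); bc <- runif(1, -6, 6)
    if (abs(bs) + abs(bc) < 0.1) next
    cv <- seasonal_effect(bs, bc)
    fine <- seq(1, 12.99, by = 0.01)
    eff <- bs * sin(2 * pi * fine / 12) + bc * cos(2 * pi * fine / 12)
    peak_fine <- fine[which.max(eff)]
    dist <- min(abs(cv$peak_month - peak_fine),
                12 - abs(cv$peak_month - peak_fine))
    expect_lte(dist, 1)
  }
})

test_that("stage peak ordering reproduces the phenological sequence", {
  tr <- default_truth()
  curves <- lapply(1:3, function(j)
    seasonal_effect(tr$beta_sin[[j]], tr$beta_cos[[j]],
                    stage = tick_stages()[j]))
  po <- peak_ordering(curves)
  peaks <- setNames(po$ordering$peak_month, po$ordering$stage)
  expect_equal(unname(peaks[c("adults", "nymphs", "larvae")]), c(6, 6, 8))
  expect_true(po$canonical)
  # ties keep stable input order
  same <- lapply(1:3, function(j)
    seasonal_effect(1, 0, stage = tick_stages()[j]))
  po2 <- peak_ordering(same)
  expect_equal(po2$ordering$stage, tick_stages())
})

test_that("a shifted harmonic truth is recovered in peak ordering", {
  tr <- default_truth()
  # move the larval peak to June and the adult peak to October
  tr$beta_sin[1] <- 0; tr$beta_cos[1] <- -5
  tr$beta_sin[3] <- -3; tr$beta_cos[3] <- 3
  panel <- simulate_panel(years = 2014:2015, truth = tr, seed = 6)
  fit <- suppressWarnings(tick_fit(panel, ndraws = 400, seed = 1))
  curves <- seasonal_curves(fit)
  expect_lte(abs(curves$larvae$peak_month - 6), 1)
  expect_lte(abs(curves$adults$peak_month - 10), 1)
})

test_that("year-effect series is centred with one entry per year", {
  fit <- cached_nb_fit()
  ys <- year_effect_series(fit)
  expect_equal(ys$year, fit$design$years)
  expect_equal(mean(ys$mean), 0, tolerance = 1e-8)
  expect_true(all(ys$lower <= ys$mean & ys$mean <= ys$upper))
})

test_that("a declining year-effect truth is tracked by the fitted series", {
  tr <- default_truth()
  rhos <- replicate(5, NA_real_)
  for (r in 1:5) {
    panel <- simulate_panel(years = 2011:2016, truth = tr, seed = 30 + r)
    fit <- suppressWarnings(tick_fit(panel, ndraws = 300, seed = r))
    ys <- year_effect_series(fit)
    truth_g <- attr(panel, "latents")$gamma
    rhos[r] <- cor(ys$mean, truth_g, method = "spearman")
  }
  expect_gt(median(rhos), 0.8)
})

test_that("a null year effect is rarely flagged as excluding zero", {
  tr <- default_truth()
  tr$year_effect_mode <- "fixed_vector"
  tr$gamma <- rep(0, 4)
  ok <- logical(5)
  for (r in 1:5) {
    panel <- simulate_panel(years = 2012:2015, truth = tr, seed = 50 + r)
    fit <- suppressWarnings(tick_fit(panel, ndraws = 300, seed = r))
    ys <- year_effect_series(fit)
    ok[r] <- !any(ys$excludes_zero)
  }
  expect_gte(sum(ok), 4)
})

test_that("instability flags trip on inflated credible intervals only", {
  w <- c(set1 = 8.924 - 5.198, set2 = 110.488 - 0.835, set3 = 10.375 - 4.423)
  fl <- instability_flags(w)
  expect_equal(unname(fl), c(FALSE, TRUE, FALSE))
  # invariant to set order
  fl2 <- instability_flags(w[c(3, 1, 2)])
  expect_equal(fl2[names(w)], fl)
  # identical posteriors: nothing flagged
  expect_false(any(instability_flags(c(a = 2, b = 2, c = 2))))
  # matrix form, one row per parameter
  m <- rbind(tau_year = w, beta = c(0.37, 0.37, 0.37))
  fm <- instability_flags(m)
  expect_equal(unname(fm["tau_year", ]), c(FALSE, TRUE, FALSE))
  expect_false(any(fm["beta", ]))
})

test_that("the sensitivity harness fits all prior sets and flags none of the betas", {
  panel <- simulate_panel(years = 2014:2015, seed = 42)
  sens <- suppressWarnings(
    sensitivity_run(panel, family = "NB", ndraws = 300, seed = 1))
  expect_equal(names(sens$fits), c("set1", "set2", "set3"))
  tab <- sens$table
  expect_true(all(c("mean_set1", "mean_set2", "mean_set3", "unstable")
                  %in% names(tab)))
  beta_rows <- grepl("^beta_", tab$parameter)
  # fixed effects are data-dominated: stable across prior sets
  expect_false(any(tab$unstable[beta_rows]))
  agree <- abs(tab$mean_set1[beta_rows] - tab$mean_set3[beta_rows])
  expect_lt(max(agree), 0.15)
})
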