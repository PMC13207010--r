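# Shared fixtures, built in code at test time.

# Write a small visit-level CSV and return its path.
toy_visits_csv <- function(lines = c(
  "location,habitat,year,month,larvae,nymphs,adults",
  "KP,woods,2012,6,14,3,2",
  "KP,woods,2012,6,3,1,0",
  "KP,grass,2012,6,0,0,1",
  "BB,edge,2012,6,5,2,0")) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# A tiny hand-made panel for counting-style checks.
toy_panel <- function() {
  p <- data.frame(
    location = "KP", habitat = "grass",
    year = c(2009, 2009, 2010),
    month = c(11, 12, 1),
    n_visits = 1L,
    larvae = c(2L, 0L, 5L), nymphs = c(1L, 0L, 2L), adults = c(0L, 1L, 3L),
    lag_log_larvae = NA_real_, lag_log_nymphs = NA_real_)
  p$habitat <- factor(p$habitat, levels = tick_habitats())
  p
}

# Pull the raw draw vector behind a summary row.
.draws_for <- function(fit, par) {
  p <- fit$pars
  switch(par,
         beta_grass = p$beta_grass[1, ], beta_woods = p$beta_woods[1, ],
         beta_sin_L = p$beta_sin[1, ], beta_cos_L = p$beta_cos[1, ],
         beta_lagL = p$beta_lagL[1, ], phi_L = p$phi[1, ],
         tau_year = p$tau_year[1, ],
         stop("unknown parameter ", par))
}

# One small fitted model, shared across test files (a fit is by far the
# most expensive fixture; ~400 panel rows, 500 Laplace draws).
cached_nb_fit <- local({
  env <- new.env()
  function() {
    if (is.null(env$fit)) {
      panel <- simulate_panel(years = 2014:2015, seed = 42)
      env$fit <- suppressWarnings(
        tick_fit(panel, family = "NB", ndraws = 500, seed = 1))
    }
    env$fit
  }
})
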