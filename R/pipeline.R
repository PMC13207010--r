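# End-to-end pipeline: YAML-configured prepare -> (simulate) -> fit ->
# diagnose -> effects -> report, with a run manifest and a plain-text
# log. Figures are regenerable views of the written CSVs, never the data
# of record.

.pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  writeLines(line, con)
  message(line)
}

.pipeline_fail <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the full modelling pipeline from a configuration
#'
#' Executes prepare (read or simulate, aggregate, filter, lags) -> fit
#' (per family and prior set) -> diagnose (criteria, PIT, zero profiles,
#' posterior predictive curves) -> effects (seasonal curves, peak
#' ordering, year-effect series, sensitivity when several prior sets are
#' requested) and writes all tables as CSV, criteria and a manifest as
#' JSON, optional PNG figures, and a timestamped log.
#'
#' Configuration keys (YAML file or R list): one of `input` (visit-level
#' CSV path) or `simulate` (list passed to [simulate_panel()]:
#' `n_locations`, `years` as `[first, last]`, `family`, `seed`, ...);
#' optional `min_visits` (default 104, only applied to real input),
#' `families` (default `["NB"]`), `prior_sets` (default `["set1"]`),
#' `year_effect`, `ndraws`, `seed`, `figures` (default `TRUE`).
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @return The output directory path, invisibly; side effect: artifact
#'   files under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = "tickstages-run") {
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  } else cfg_path <- NULL
  if (is.null(config$input) && is.null(config$simulate))
    stop("config needs either 'input' (CSV path) or a 'simulate' block",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  run_id <- format(Sys.time(), "%Y%m%d%H%M%S")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  families <- toupper(if (is.null(config$families)) "NB" else config$families)
  prior_sets <- if (is.null(config$prior_sets)) "set1" else config$prior_sets
  year_effect <- if (is.null(config$year_effect)) "rw1" else config$year_effect
  ndraws <- if (is.null(config$ndraws)) 1000 else config$ndraws
  figures <- if (is.null(config$figures)) TRUE else isTRUE(config$figures)

  # --- prepare ---------------------------------------------------------
  panel <- tryCatch({
    if (!is.null(config$input)) {
      .pipeline_log(con, "prepare", paste("reading", config$input))
      rec <- read_survey_csv(config$input)
      p <- aggregate_monthly(rec)
      mv <- if (is.null(config$min_visits)) 104 else config$min_visits
      p <- filter_well_sampled(p, min_visits = mv)
      attach_lags(p)
    } else {
      sb <- config$simulate
      .pipeline_log(con, "simulate", "generating synthetic panel")
      yrs <- if (is.null(sb$years)) 2009:2018
             else seq(sb$years[[1]], sb$years[[length(sb$years)]])
      simulate_panel(
        n_locations = if (is.null(sb$n_locations)) 6 else sb$n_locations,
        years = yrs,
        family = toupper(if (is.null(sb$family)) "NB" else sb$family),
        seed = if (is.null(sb$seed)) seed else sb$seed)
    }
  }, error = function(e) .pipeline_fail("prepare", e))
  if (nrow(panel) == 0)
    stop("pipeline stage 'prepare' failed: empty panel", call. = FALSE)
  write_panel_csv(panel, file.path(out_dir, "panel.csv"))
  write.csv(stage_summary(panel), file.path(out_dir, "stage_summary.csv"),
            row.names = FALSE)
  zp <- zero_profile(panel)
  for (nm in names(zp))
    write.csv(zp[[nm]], file.path(out_dir, paste0("zero_", nm, ".csv")),
              row.names = FALSE)
  .pipeline_log(con, "prepare", sprintf("panel: %d rows, %d locations",
                                        nrow(panel),
                                        length(unique(panel$location))))

  # --- fit / diagnose / effects ---------------------------------------
  fits <- list(); criteria <- list()
  for (fam in families) {
    tryCatch({
      if (length(prior_sets) > 1) {
        .pipeline_log(con, "fit", sprintf("%s under %d prior sets", fam,
                                          length(prior_sets)))
        sens <- sensitivity_run(panel, family = fam, sets = prior_sets,
                                year_effect = year_effect, ndraws = ndraws,
                                seed = seed)
        write.csv(sens$table,
                  file.path(out_dir, paste0("sensitivity_", fam, ".csv")),
                  row.names = FALSE)
        fits[[fam]] <- sens$fits[[1]]
        criteria[[fam]] <- sens$criteria[[1]]
      } else {
        .pipeline_log(con, "fit", sprintf("%s, prior %s", fam, prior_sets))
        fits[[fam]] <- tick_fit(panel, family = fam, prior = prior_sets,
                                year_effect = year_effect, ndraws = ndraws,
                                seed = seed)
        criteria[[fam]] <- fit_criteria(fits[[fam]])
      }
      f <- fits[[fam]]
      write.csv(cbind(parameter = rownames(f$summary), f$summary),
                file.path(out_dir, paste0("posterior_summary_", fam, ".csv")),
                row.names = FALSE)
    }, error = function(e) .pipeline_fail("fit", e))
    tryCatch({
      f <- fits[[fam]]
      pit <- pit_tick_fit(f, seed = seed + 1)
      ppc <- posterior_predictive_monthly(f, seed = seed + 2)
      write.csv(ppc, file.path(out_dir, paste0("ppc_monthly_", fam, ".csv")),
                row.names = FALSE)
      .pipeline_log(con, "diagnose",
                    sprintf("%s: DIC %.2f WAIC %.2f PIT-KS p %.3g", fam,
                            criteria[[fam]]$dic, criteria[[fam]]$waic,
                            pit$ks_p))
      if (figures) {
        grDevices::png(file.path(out_dir, paste0("ppc_", fam, ".png")),
                       width = 1200, height = 400)
        plot(f, seed = seed + 2)
        grDevices::dev.off()
        grDevices::png(file.path(out_dir, paste0("pit_", fam, ".png")),
                       width = 500, height = 400)
        graphics::hist(pit$pit_values, breaks = 10, main =
                         paste("Randomized PIT,", fam), xlab = "PIT")
        grDevices::dev.off()
      }
    }, error = function(e) .pipeline_fail("diagnose", e))
    tryCatch({
      f <- fits[[fam]]
      cv <- seasonal_curves(f)
      eff <- do.call(rbind, lapply(cv, function(s)
        data.frame(stage = s$stage, month = s$months, effect = s$effect,
                   peak_month = s$peak_month, amplitude = s$amplitude)))
      write.csv(eff, file.path(out_dir, paste0("seasonal_effects_", fam, ".csv")),
                row.names = FALSE)
      ys <- year_effect_series(f)
      write.csv(as.data.frame(ys),
                file.path(out_dir, paste0("year_effects_", fam, ".csv")),
                row.names = FALSE)
      po <- peak_ordering(cv)
      .pipeline_log(con, "effects",
                    sprintf("%s peaks: %s (canonical ordering: %s)", fam,
                            paste(sprintf("%s=%d", po$ordering$stage,
                                          po$ordering$peak_month),
                                  collapse = " "), po$canonical))
    }, error = function(e) .pipeline_fail("effects", e))
  }

  # --- report ----------------------------------------------------------
  tryCatch({
    crit_out <- lapply(criteria, function(cr)
      list(dic = cr$dic, p_dic = cr$p_dic, waic = cr$waic,
           p_waic = cr$p_waic))
    if (all(c("NB", "ZINB") %in% names(criteria))) {
      cmp <- compare_models(criteria$NB, criteria$ZINB)
      crit_out$comparison <- list(delta_dic = cmp$delta_dic,
                                  delta_waic = cmp$delta_waic)
    }
    jsonlite::write_json(crit_out, file.path(out_dir, "criteria.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      run_id = run_id, seed = seed, families = families,
      prior_sets = prior_sets, year_effect = year_effect, ndraws = ndraws,
      n_panel_rows = nrow(panel),
      config_md5 = if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path))
                   else NA,
      package_version = as.character(utils::packageVersion("tickstages")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    .pipeline_log(con, "report", paste("artifacts written to", out_dir))
  }, error = function(e) .pipeline_fail("report", e))
  invisible(out_dir)
}
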