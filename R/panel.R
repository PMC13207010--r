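# Survey records and the monthly panel.
#
# A visit-level record is one flagging visit to one habitat patch; the
# model consumes a monthly panel with exactly one row per
# (location, habitat, year, month) and per-stage counts summed over
# visits. Lag columns hold log(count+1) of the preceding calendar month
# of the preceding life stage, and are NA when that month was not
# sampled.

.stage_cols <- c("larvae", "nymphs", "adults")

.check_counts <- function(df, rows = seq_len(nrow(df))) {
  for (col in .stage_cols) {
    v <- df[[col]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0)
      stop(sprintf("invalid %s count at row %d: must be a non-negative integer",
                   col, rows[bad[1]]), call. = FALSE)
  }
  invisible(df)
}

.normalize_habitat <- function(x, rows = seq_along(x)) {
  h <- tolower(trimws(as.character(x)))
  # accept the common synonyms seen in field sheets
  h[h %in% c("wooded", "wood")] <- "woods"
  h[h %in% c("grassy")] <- "grass"
  bad <- which(!h %in% tick_habitats())
  if (length(bad) > 0)
    stop(sprintf("unknown habitat level '%s' at row %d (expected edge, grass or woods)",
                 x[bad[1]], rows[bad[1]]), call. = FALSE)
  factor(h, levels = tick_habitats())
}

#' Read visit-level tick survey records
#'
#' Reads a CSV of flagging-visit records with columns `location`,
#' `habitat`, `year`, `month`, `larvae`, `nymphs`, `adults`. Habitat
#' strings are normalized case-insensitively to the three levels
#' edge/grass/woods (accepting "wooded" and "grassy" synonyms).
#'
#' @param path Path to the CSV file.
#' @return A data.frame of survey records, one row per visit.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("location,habitat,year,month,larvae,nymphs,adults",
#'              "KP,woods,2012,6,14,3,2"), f)
#' read_survey_csv(f)
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("location", "habitat", "year", "month", .stage_cols)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing columns in survey CSV: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  if (nrow(df) == 0) {
    df$habitat <- factor(character(0), levels = tick_habitats())
    return(df)
  }
  rows <- seq_len(nrow(df)) + 1L  # header is line 1
  df$location <- as.character(df$location)
  df$habitat <- .normalize_habitat(df$habitat, rows)
  for (col in c("year", "month", .stage_cols)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop(sprintf("malformed value in column '%s' at row %d", col, rows[bad[1]]),
           call. = FALSE)
    df[[col]] <- v
  }
  bad <- which(df$month < 1 | df$month > 12 | df$month != round(df$month))
  if (length(bad) > 0)
    stop(sprintf("month out of range 1..12 at row %d", rows[bad[1]]), call. = FALSE)
  .check_counts(df, rows)
  df$year <- as.integer(df$year)
  df$month <- as.integer(df$month)
  for (col in .stage_cols) df[[col]] <- as.integer(df[[col]])
  df
}

#' Aggregate visit records to the monthly panel
#'
#' Sums per-stage counts over all visits within each
#' (location, habitat, year, month) cell and records the number of
#' contributing visits in `n_visits`. The output is sorted by location,
#' habitat, year, month; lag columns are initialised to `NA`.
#'
#' @param records A data.frame of visit-level records as returned by
#'   [read_survey_csv()].
#' @return A monthly panel data.frame with columns `location`, `habitat`,
#'   `year`, `month`, `n_visits`, `larvae`, `nymphs`, `adults`,
#'   `lag_log_larvae`, `lag_log_nymphs`.
#' @export
aggregate_monthly <- function(records) {
  if (nrow(records) == 0) stop("no survey records to aggregate", call. = FALSE)
  records$habitat <- .normalize_habitat(records$habitat)
  .check_counts(records)
  key <- list(location = records$location, habitat = records$habitat,
              year = records$year, month = records$month)
  agg <- aggregate(records[, .stage_cols], by = key, FUN = sum)
  nv <- aggregate(list(n_visits = rep(1L, nrow(records))), by = key, FUN = sum)
  panel <- merge(agg, nv, by = c("location", "habitat", "year", "month"))
  panel <- panel[order(panel$location, as.integer(panel$habitat),
                       panel$year, panel$month), ]
  panel <- panel[, c("location", "habitat", "year", "month", "n_visits",
                     .stage_cols)]
  panel$lag_log_larvae <- NA_real_
  panel$lag_log_nymphs <- NA_real_
  rownames(panel) <- NULL
  panel
}

#' Drop locations with too few sampling visits
#'
#' Retains only observations from locations whose total number of visits,
#' summed over habitats, years and months, reaches `min_visits`. Sparse
#' locations destabilize the multivariate fit, so the default threshold
#' keeps only consistently sampled sites.
#'
#' @param panel A monthly panel from [aggregate_monthly()].
#' @param min_visits Minimum total visits per location (default 104).
#' @return The filtered panel; dropped locations are reported via
#'   `message()`, and a warning is raised if nothing survives.
#' @export
filter_well_sampled <- function(panel, min_visits = 104) {
  stopifnot(min_visits >= 1)
  totals <- tapply(panel$n_visits, panel$location, sum)
  keep <- names(totals)[totals >= min_visits]
  dropped <- setdiff(names(totals), keep)
  if (length(dropped) > 0)
    message("dropping under-sampled locations: ",
            paste(sprintf("%s (%d visits)", dropped, totals[dropped]),
                  collapse = ", "))
  out <- panel[panel$location %in% keep, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no location reaches min_visits = ", min_visits,
            "; the panel is empty", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Attach lagged log-abundance predictors
#'
#' For each (location, habitat) series, sets `lag_log_larvae` to
#' `log(larvae[t-1] + 1)` and `lag_log_nymphs` to `log(nymphs[t-1] + 1)`
#' where `t-1` is the immediately preceding calendar month (December to
#' January transitions included). Observations without a sampled
#' preceding month keep `NA` lags; the fitting routine drops those rows
#' from the nymph/adult likelihood contributions but keeps them for the
#' larval equation.
#'
#' @param panel A monthly panel from [aggregate_monthly()].
#' @return The panel with lag columns filled; idempotent.
#' @export
attach_lags <- function(panel) {
  if (nrow(panel) == 0) return(panel)
  midx <- panel$year * 12L + (panel$month - 1L)  # absolute month index
  key <- paste(panel$location, panel$habitat, sep = "\r")
  prev <- match(paste(key, midx - 1L, sep = "\r"),
                paste(key, midx, sep = "\r"))
  panel$lag_log_larvae <- ifelse(is.na(prev), NA_real_,
                                 log(panel$larvae[prev] + 1))
  panel$lag_log_nymphs <- ifelse(is.na(prev), NA_real_,
                                 log(panel$nymphs[prev] + 1))
  panel
}

#' Write / read a monthly panel CSV
#'
#' Stable CSV dialect for prepared panels: UTF-8, header row, missing
#' lags as empty fields, lag values at full double precision.
#'
#' @param panel A monthly panel.
#' @param path Output path.
#' @return `write_panel_csv()` returns `path` invisibly;
#'   `read_panel_csv()` returns the panel.
#' @export
write_panel_csv <- function(panel, path) {
  out <- panel
  out$habitat <- as.character(out$habitat)
  for (col in c("lag_log_larvae", "lag_log_nymphs"))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 17, format = "g"))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$habitat <- .normalize_habitat(df$habitat)
  for (col in c("lag_log_larvae", "lag_log_nymphs"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df
}

#' Validate monthly panel invariants
#'
#' Checks uniqueness of (location, habitat, year, month), count
#' integrality and non-negative lags. Used internally before fitting.
#'
#' @param panel A monthly panel.
#' @return The panel, invisibly; stops on violation.
#' @export
validate_panel <- function(panel) {
  key <- paste(panel$location, panel$habitat, panel$year, panel$month)
  if (anyDuplicated(key) > 0)
    stop("panel has duplicate (location, habitat, year, month) cells",
         call. = FALSE)
  .check_counts(panel)
  for (col in c("lag_log_larvae", "lag_log_nymphs")) {
    v <- panel[[col]]
    if (any(!is.na(v) & v < 0)) stop("negative lag value", call. = FALSE)
  }
  invisible(panel)
}
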