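# Covariate construction: one annual harmonic per stage, habitat dummies
# with edge as reference, lagged log-abundance predictors, and label
# encodings for year and location.

#' Annual harmonic terms for a calendar month
#'
#' Encodes month `M` (1 = January) as `(sin(2*pi*M/12), cos(2*pi*M/12))`,
#' the single annual harmonic used to capture tick phenology. Values are
#' rounded to clean exact multiples of the quarter period (sin(pi) etc.)
#' to within double precision.
#'
#' @param month Integer vector of months in 1..12 (values outside are
#'   rejected; periodic extension is available via `month %% 12`).
#' @return A two-column matrix with columns `sin_term`, `cos_term`.
#' @examples
#' encode_harmonics(3)   # c(1, 0)
#' encode_harmonics(6)   # c(0, -1)
#' @export
encode_harmonics <- function(month) {
  if (any(is.na(month)) || any(month < 1 | month > 12 | month != round(month)))
    stop("month must be an integer in 1..12", call. = FALSE)
  ang <- 2 * pi * month / 12
  cbind(sin_term = sin(ang), cos_term = cos(ang))
}

#' Habitat dummy coding with edge reference
#'
#' @param habitat Character or factor vector of habitat levels.
#' @return A two-column 0/1 matrix with columns `grass_ind`, `woods_ind`;
#'   edge maps to (0, 0).
#' @export
encode_habitat <- function(habitat) {
  h <- .normalize_habitat(habitat)
  cbind(grass_ind = as.numeric(h == "grass"),
        woods_ind = as.numeric(h == "woods"))
}

#' Build the model design from a monthly panel
#'
#' Expands a prepared panel (lags attached) into the per-stage design the
#' likelihood consumes: harmonic terms, habitat indicators, lag
#' predictors, 0-based year and location indices, and per-stage inclusion
#' flags. Nymph rows require `lag_log_larvae` and adult rows require
#' `lag_log_nymphs`; rows lacking the needed lag are flagged excluded for
#' that stage only (the larval equation uses every row).
#'
#' @param panel A monthly panel with lag columns (see [attach_lags()]).
#' @return A list with elements:
#'   \describe{
#'     \item{rows}{long-format data.frame, one row per (observation, stage),
#'       with the design columns, a `stage` factor and an `included` flag;}
#'     \item{Y}{n x 3 count matrix (larvae, nymphs, adults);}
#'     \item{X}{n-row data.frame of the shared covariates;}
#'     \item{include}{n x 3 0/1 inclusion matrix;}
#'     \item{years, locations}{the level tables behind `year_index` and
#'       `location_index`.}
#'   }
#' @export
build_design <- function(panel) {
  if (nrow(panel) == 0) stop("empty panel", call. = FALSE)
  validate_panel(panel)
  harm <- encode_harmonics(panel$month)
  hab <- encode_habitat(panel$habitat)
  years <- sort(unique(panel$year))
  locations <- sort(unique(panel$location))
  X <- data.frame(
    sin_term = harm[, "sin_term"],
    cos_term = harm[, "cos_term"],
    grass_ind = hab[, "grass_ind"],
    woods_ind = hab[, "woods_ind"],
    lag_log_larvae = panel$lag_log_larvae,
    lag_log_nymphs = panel$lag_log_nymphs,
    year_index = match(panel$year, years) - 1L,
    location_index = match(panel$location, locations) - 1L,
    log_n_visits = log(panel$n_visits)
  )
  Y <- as.matrix(panel[, .stage_cols])
  colnames(Y) <- .stage_cols
  include <- cbind(
    larvae = rep(1, nrow(panel)),
    nymphs = as.numeric(!is.na(panel$lag_log_larvae)),
    adults = as.numeric(!is.na(panel$lag_log_nymphs))
  )
  stages <- tick_stages()
  rows <- do.call(rbind, lapply(seq_along(stages), function(j) {
    data.frame(stage = stages[j], X, y = Y[, j],
               included = include[, j] == 1)
  }))
  rows$stage <- factor(rows$stage, levels = stages)
  list(rows = rows, Y = Y, X = X, include = include,
       years = years, locations = locations)
}
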