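#' Quality-filter a county yield table
#'
#' Applies, in order, the three quality rules used for the US county yield
#' series: (1) drop records published only as combined multi-county
#' aggregates (`combined_flag`); (2) drop counties whose yield series is
#' missing or discontinuous over the table's year range: fewer than
#' `min_years` usable years, or a run of more than `max_gap` consecutive
#' missing years (isolated one-year gaps are tolerated, as they routinely
#' arise from survey skips and from outlier removal); (3) within each
#' surviving county, drop records farther than two standard deviations from
#' that county's own mean (mean and SD over the county's full series; sample
#' SD, so a county with a constant series removes nothing).
#'
#' The filter is a single pass: statistics are computed once on the input of
#' the call, not re-estimated after removals.
#'
#' @param yields A `yield_table`.
#' @param year_range Years against which continuity is assessed; defaults to
#'   the full range present in `yields`.
#' @param min_years Minimum usable years per county (default 3).
#' @param max_gap Longest tolerated run of missing years (default 1).
#' @return List with `yields` (filtered `yield_table`) and `report`, a
#'   `filter_report` with counts `n_input`, `n_removed_combined`,
#'   `n_removed_missing`, `n_removed_outlier`, the surviving row count and the
#'   removed record ids.
#' @export
filter_yields <- function(yields, year_range = NULL, min_years = 3,
                          max_gap = 1) {
  yields <- as_yield_table(yields)
  if (!nrow(yields)) stop("yield table is empty", call. = FALSE)
  n_input <- nrow(yields)
  removed <- character(0)
  rec_id <- function(df) paste(df$county_id, df$year, sep = ":")

  combined <- yields$combined_flag
  removed_combined <- rec_id(yields[combined, ])
  kept <- yields[!combined, ]

  if (is.null(year_range)) {
    year_range <- seq(min(kept$year), max(kept$year))
  }
  longest_gap <- function(y) {
    missing <- setdiff(year_range, y)
    if (!length(missing)) return(0L)
    runs <- rle(diff(sort(missing)) == 1)
    max(c(1L, runs$lengths[runs$values] + 1L))
  }
  cover <- tapply(kept$year, kept$county_id, function(y) {
    length(y) >= min_years && longest_gap(y) <= max_gap
  })
  bad_counties <- names(cover)[!cover]
  removed_missing <- rec_id(kept[kept$county_id %in% bad_counties, ])
  kept <- kept[!kept$county_id %in% bad_counties, ]

  removed_outlier <- character(0)
  if (nrow(kept)) {
    mu <- tapply(kept$yield_bu_ac, kept$county_id, mean)
    sdv <- tapply(kept$yield_bu_ac, kept$county_id, stats::sd)
    dev <- abs(kept$yield_bu_ac - mu[kept$county_id])
    out <- dev > 2 * sdv[kept$county_id] & sdv[kept$county_id] > 0
    removed_outlier <- rec_id(kept[out, ])
    kept <- kept[!out, ]
  }

  report <- structure(list(
    n_input = n_input,
    n_removed_combined = length(removed_combined),
    n_removed_missing = length(removed_missing),
    n_removed_outlier = length(removed_outlier),
    n_kept = nrow(kept),
    removed_ids = list(combined = removed_combined,
                       missing = removed_missing,
                       outlier = removed_outlier)
  ), class = "filter_report")
  stopifnot(report$n_input - report$n_removed_combined -
              report$n_removed_missing - report$n_removed_outlier ==
              report$n_kept)
  rownames(kept) <- NULL
  list(yields = as_yield_table(kept), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("yield filter report\n",
      "  input records:   ", x$n_input, "\n",
      "  removed combined:", x$n_removed_combined, "\n",
      "  removed missing: ", x$n_removed_missing, "\n",
      "  removed outlier: ", x$n_removed_outlier, "\n",
      "  kept:            ", x$n_kept, "\n", sep = "")
  invisible(x)
}

#' Aggregate sub-monthly observations to the four-month panel slice
#'
#' Averages timestamped observations of each variable into calendar-month
#' values for May--August of one county-year. A month with no observation for
#' some variable is a hard error in strict mode and is linearly interpolated
#' from the neighbouring months in lenient mode (endpoints carried).
#'
#' @param obs Data frame with columns `month` (5--8; or `date`, from which the
#'   month is taken), `variable` and `value`.
#' @param county_id,year Identifiers used in error messages.
#' @param policy `"strict"` (default) or `"interpolate"`.
#' @return Data frame with `county_id`, `year`, `month` (5:8) and one column
#'   per variable, suitable for row-binding into a feature panel.
#' @export
aggregate_to_monthly <- function(obs, county_id, year,
                                 policy = c("strict", "interpolate")) {
  policy <- match.arg(policy)
  if (!"month" %in% names(obs)) {
    if (!"date" %in% names(obs)) {
      stop("observations need a month or date column", call. = FALSE)
    }
    obs$month <- as.integer(format(as.Date(obs$date), "%m"))
  }
  if (!all(obs$month %in% 5:8)) {
    stop("observations must fall in May..August", call. = FALSE)
  }
  vars <- unique(obs$variable)
  out <- data.frame(county_id = county_id, year = year, month = 5:8,
                    stringsAsFactors = FALSE)
  for (v in vars) {
    sub <- obs[obs$variable == v, ]
    m <- tapply(sub$value, factor(sub$month, levels = 5:8), mean)
    if (anyNA(m)) {
      miss <- (5:8)[is.na(m)]
      if (policy == "strict") {
        stop(sprintf(
          "no observations for county %s year %s variable %s in month(s) %s",
          county_id, year, v, paste(miss, collapse = ", ")), call. = FALSE)
      }
      m <- stats::approx(x = (5:8)[!is.na(m)], y = m[!is.na(m)], xout = 5:8,
                         rule = 2)$y
    }
    out[[v]] <- as.numeric(m)
  }
  out
}

#' Fit a per-variable min-max scaler on training years
#'
#' The minima and maxima are learned from training-year records only and
#' reused unchanged on test years, so no test information leaks into the
#' normalization; transformed test values may legitimately fall outside
#' \[0, 1\] and are not clipped.
#'
#' @param panel A `feature_panel`.
#' @param training_years Years whose records define the ranges.
#' @return Object of class `minmax_scaler`.
#' @export
fit_scaler <- function(panel, training_years) {
  panel <- as_feature_panel(panel)
  if (!any(panel$year %in% training_years)) {
    stop("no training-year records in panel", call. = FALSE)
  }
  tr <- panel[panel$year %in% training_years, ]
  vars <- setdiff(names(panel), c("county_id", "year", "month"))
  structure(list(
    variables = vars,
    min = vapply(tr[vars], min, numeric(1)),
    max = vapply(tr[vars], max, numeric(1)),
    training_years = sort(unique(tr$year))
  ), class = "minmax_scaler")
}

#' Apply (or invert) a min-max scaler
#'
#' @param panel A `feature_panel` containing the scaler's variables.
#' @param scaler A [fit_scaler()] object.
#' @param invert If `TRUE`, map \[0, 1\]-scaled values back to the original
#'   units.
#' @return The transformed panel. A variable with zero training range maps to
#'   0 with a warning (and inverts to its constant training value).
#' @export
apply_scaler <- function(panel, scaler, invert = FALSE) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  panel <- as_feature_panel(panel)
  for (v in scaler$variables) {
    rng <- scaler$max[[v]] - scaler$min[[v]]
    if (rng == 0) {
      warning("variable '", v, "' is constant in training years; ",
              "scaled values set to 0", call. = FALSE)
      panel[[v]] <- if (invert) rep(scaler$min[[v]], nrow(panel)) else
        rep(0, nrow(panel))
    } else {
      panel[[v]] <- if (invert) panel[[v]] * rng + scaler$min[[v]] else
        (panel[[v]] - scaler$min[[v]]) / rng
    }
  }
  panel
}

#' Assemble model tensors from a panel and yield table
#'
#' Restricts the variable axis to the union of the requested groups (in
#' registry order), aligns county-years between panel and yields, and stacks
#' the monthly values into the `(records, 4 months, k variables)` array the
#' sequence models consume. Panel county-years with no matching yield are
#' dropped (recorded in the alignment manifest).
#'
#' @param panel A `feature_panel` (normally already scaled).
#' @param yields A `yield_table`.
#' @param groups Subset of `c("SV", "ED", "PP")`; default all three (k = 21).
#' @return List with `x` (numeric array n x 4 x k), `y` (yields, bu/ac),
#'   `variables`, and `manifest` (data frame of aligned county-years plus an
#'   attribute `dropped` listing unmatched panel county-years).
#' @export
assemble_inputs <- function(panel, yields, groups = c("SV", "ED", "PP")) {
  if (!length(groups)) stop("groups must be nonempty", call. = FALSE)
  vars <- group_variables(groups)
  panel <- as_feature_panel(panel)
  miss <- setdiff(vars, names(panel))
  if (length(miss)) {
    stop("panel lacks variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  yields <- as_yield_table(yields)
  pkey <- unique(panel[c("county_id", "year")])
  ykey <- paste(yields$county_id, yields$year)
  keep <- paste(pkey$county_id, pkey$year) %in% ykey
  dropped <- pkey[!keep, ]
  if (nrow(dropped)) {
    message(nrow(dropped), " county-year(s) in panel without yield dropped")
  }
  manifest <- pkey[keep, ]
  if (!nrow(manifest)) {
    stop("panel and yield table share no county-years", call. = FALSE)
  }
  manifest <- manifest[order(manifest$county_id, manifest$year), ]
  rownames(manifest) <- NULL

  n <- nrow(manifest)
  x <- array(NA_real_, dim = c(n, 4L, length(vars)),
             dimnames = list(NULL, month = 5:8, variable = vars))
  panel_key <- paste(panel$county_id, panel$year)
  man_key <- paste(manifest$county_id, manifest$year)
  for (m in 1:4) {
    rows <- panel[panel$month == m + 4L, ]
    idx <- match(man_key, paste(rows$county_id, rows$year))
    x[, m, ] <- as.matrix(rows[idx, vars, drop = FALSE])
  }
  stopifnot(!anyNA(x))
  y <- yields$yield_bu_ac[match(man_key, ykey)]
  attr(manifest, "dropped") <- dropped
  list(x = x, y = y, variables = vars, manifest = manifest)
}
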