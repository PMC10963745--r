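#' Validate and classify a monthly feature panel
#'
#' A feature panel is a long-format data frame with one row per county, year
#' and month (May--August, coded 5--8) and one column per registry variable.
#' Every (county, year) present must carry all four months, and the variable
#' columns must match the registry exactly (aliases are renamed on the way in).
#'
#' @param df Data frame with columns `county_id`, `year`, `month`, then the 21
#'   registry variables (or an ablation subset in registry order).
#' @param registry Registry data frame; defaults to [yield_registry()].
#' @param require_complete If `TRUE` (default) refuse panels with missing
#'   values in the variable columns.
#' @return `df` with class `feature_panel` prepended, rows ordered by county,
#'   year, month and variable columns in registry order.
#' @export
as_feature_panel <- function(df, registry = yield_registry(),
                             require_complete = TRUE) {
  stopifnot(is.data.frame(df))
  names(df) <- canonical_variable_names(names(df))
  meta <- c("county_id", "year", "month")
  if (!all(meta %in% names(df))) {
    stop("feature panel needs columns county_id, year, month", call. = FALSE)
  }
  vars <- registry$name[registry$name %in% names(df)]
  extra <- setdiff(names(df), c(meta, registry$name))
  if (length(extra)) {
    stop("unknown variable column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!length(vars)) stop("no registry variables present", call. = FALSE)
  if (!all(df$month %in% 5:8)) {
    stop("month must be coded 5..8 (May..August)", call. = FALSE)
  }
  counts <- table(paste(df$county_id, df$year))
  if (any(counts != 4L)) {
    stop("every (county, year) must have exactly the 4 months May..August",
         call. = FALSE)
  }
  if (require_complete && anyNA(df[vars])) {
    stop("feature panel contains missing values; apply the missing-data ",
         "policy before building a panel", call. = FALSE)
  }
  df <- df[order(df$county_id, df$year, df$month), c(meta, vars)]
  rownames(df) <- NULL
  class(df) <- c("feature_panel", "data.frame")
  df
}

#' Validate a county-year yield table
#'
#' @param df Data frame with columns `county_id`, `year`, `yield_bu_ac` and
#'   optionally `combined_flag` (records published only as combined
#'   multi-county aggregates; defaults to `FALSE`).
#' @return `df` with class `yield_table` prepended.
#' @export
as_yield_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("county_id", "year", "yield_bu_ac")
  if (!all(need %in% names(df))) {
    stop("yield table needs columns county_id, year, yield_bu_ac",
         call. = FALSE)
  }
  if (is.null(df$combined_flag)) df$combined_flag <- FALSE
  if (any(df$yield_bu_ac < 0, na.rm = TRUE)) {
    stop("yield_bu_ac must be nonnegative", call. = FALSE)
  }
  if (anyDuplicated(df[c("county_id", "year")])) {
    stop("(county_id, year) pairs must be unique", call. = FALSE)
  }
  df <- df[order(df$county_id, df$year),
           c("county_id", "year", "yield_bu_ac", "combined_flag")]
  rownames(df) <- NULL
  class(df) <- c("yield_table", "data.frame")
  df
}

#' Season means of a feature panel
#'
#' Collapses the four monthly values of each variable to their May--August
#' mean, one row per county-year. This is the representation under which the
#' generator's variable-yield correlations are calibrated.
#'
#' @param panel A [as_feature_panel()] panel.
#' @return Data frame with `county_id`, `year` and one season-mean column per
#'   variable.
#' @export
season_means <- function(panel) {
  panel <- as_feature_panel(panel)
  vars <- setdiff(names(panel), c("county_id", "year", "month"))
  key <- interaction(panel$county_id, panel$year, drop = TRUE)
  out <- stats::aggregate(panel[vars], by = list(key = key), FUN = mean)
  ids <- panel[!duplicated(key), c("county_id", "year")]
  ids <- ids[match(out$key, unique(key)), ]
  res <- cbind(ids, out[vars])
  res <- res[order(res$county_id, res$year), ]
  rownames(res) <- NULL
  res
}

#' Read and write the canonical delimited formats
#'
#' The feature CSV is long format (`county_id, year, month, <variables...>`);
#' the yield CSV has `county_id, year, yield_bu_ac, combined_flag`.
#'
#' @param path File path.
#' @param panel,yields Objects to write.
#' @return Readers return validated `feature_panel` / `yield_table` objects;
#'   writers return `path` invisibly.
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
read_feature_panel <- function(path) {
  as_feature_panel(utils::read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = c(county_id = "character")))
}

#' @rdname panel_io
#' @export
write_feature_panel <- function(panel, path) {
  utils::write.csv(as_feature_panel(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_yield_table <- function(path) {
  as_yield_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = c(county_id = "character")))
}

#' @rdname panel_io
#' @export
write_yield_table <- function(yields, path) {
  utils::write.csv(as_yield_table(yields), path, row.names = FALSE)
  invisible(path)
}
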