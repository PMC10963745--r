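#' Canonical registry of the 21 remote-sensing predictors
#'
#' The yield models consume 21 county-level monthly variables organised in
#' three groups: `SV` (seven MODIS surface-reflectance bands plus the NDVI and
#' EVI vegetation indices), `ED` (day/night land-surface temperature and five
#' TerraClimate variables), and `PP` (five photosynthesis-related parameters).
#' This registry is the single authoritative vocabulary: every file reader,
#' tensor assembler and importance table uses these names in this order, so a
#' column mismatch fails loudly instead of silently reordering predictors.
#'
#' @return A data frame with columns `name`, `group` (one of `"SV"`, `"ED"`,
#'   `"PP"`) and `units`, with exactly 21 rows in canonical order.
#' @examples
#' reg <- yield_registry()
#' table(reg$group)
#' @export
yield_registry <- function() {
  reg <- data.frame(
    name = c(
      paste0("Sur_Refl_b0", 1:7), "NDVI", "EVI",
      "LST_Day", "LST_Night", "Pdsi", "Pr", "Soil", "Vap", "Vpd",
      "Sif", "Fpar", "Lai", "Gpp", "PsnNet"
    ),
    group = c(rep("SV", 9), rep("ED", 7), rep("PP", 5)),
    units = c(
      rep("reflectance", 7), "index", "index",
      "K", "K", "index", "mm", "mm", "kPa", "kPa",
      "mW m-2 nm-1 sr-1", "fraction", "m2 m-2", "kg C m-2", "kg C m-2"
    ),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(reg) == 21L, !anyDuplicated(reg$name))
  reg
}

# Table-of-origin spellings mapped onto the canonical identifiers, so files
# exported from upstream processing chains load without manual renaming.
.variable_aliases <- c(
  LST_Day_1km = "LST_Day",
  LST_Night_1km = "LST_Night",
  Ndvi = "NDVI",
  Evi = "EVI",
  LSTDay = "LST_Day",
  LSTNight = "LST_Night"
)

#' Map external variable spellings to canonical registry names
#'
#' @param names Character vector of column names as found in an input file.
#' @return Character vector of the same length with known aliases (e.g.
#'   `"LST_Day_1km"`) replaced by canonical registry names.
#' @export
canonical_variable_names <- function(names) {
  hit <- names %in% names(.variable_aliases)
  names[hit] <- unname(.variable_aliases[names[hit]])
  names
}

#' Variables belonging to a set of registry groups
#'
#' @param groups Character vector, subset of `c("SV", "ED", "PP")`.
#' @param registry Registry data frame, by default [yield_registry()].
#' @return Character vector of variable names in registry order.
#' @examples
#' group_variables("PP")
#' @export
group_variables <- function(groups, registry = yield_registry()) {
  groups <- unique(groups)
  bad <- setdiff(groups, unique(registry$group))
  if (length(bad)) {
    stop("unknown variable group(s): ", paste(bad, collapse = ", "),
         "; valid groups are SV, ED, PP", call. = FALSE)
  }
  registry$name[registry$group %in% groups]
}

#' Convert soybean yield from bushels per acre to kilograms per hectare
#'
#' One bushel per acre of soybean corresponds to 67.25 kg per hectare.
#'
#' @param value_bu_ac Nonnegative numeric vector of yields in bushels/acre.
#' @return Numeric vector of yields in kg/ha.
#' @examples
#' convert_yield_units(1)    # 67.25
#' convert_yield_units(40)   # 2690
#' @export
convert_yield_units <- function(value_bu_ac) {
  if (!is.numeric(value_bu_ac)) {
    stop("yield must be numeric", call. = FALSE)
  }
  if (any(value_bu_ac < 0, na.rm = TRUE)) {
    stop("yield in bushels/acre must be nonnegative", call. = FALSE)
  }
  value_bu_ac * 67.25
}
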