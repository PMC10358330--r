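# Reading and validating every table the pipeline touches. All files are
# UTF-8, comma-delimited, one header row, "." decimal point. Missing
# blue-water factors are empty fields, never 0 (0 m3/kg is a legal value).

read_csv_utf8 <- function(path, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path), "dietimpact_io_error")
  }
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  check.names = FALSE)
}

validate_roster <- function(roster) {
  check_columns(roster, c("household_id", "member_id", "age", "sex",
                          "activity_level", "region", "wealth_quintile"),
                "household roster")
  if (any(is.na(roster$age)) || any(roster$age < 0)) {
    abort("roster ages must be non-negative", "dietimpact_validation_error")
  }
  check_vocab(roster$sex, sex_levels(), "roster sex")
  check_vocab(roster$activity_level, activity_levels(),
              "roster activity_level")
  check_vocab(roster$region, survey_regions(), "roster region")
  if (!all(roster$wealth_quintile %in% 1:5)) {
    abort("wealth_quintile must lie in 1..5", "dietimpact_validation_error")
  }
  # household-level attributes must be constant within a household
  for (col in c("region", "wealth_quintile")) {
    n_distinct <- tapply(roster[[col]], roster$household_id,
                         function(v) length(unique(v)))
    if (any(n_distinct > 1L)) {
      abort(sprintf(
        "household(s) with conflicting %s: %s", col,
        paste(names(n_distinct)[n_distinct > 1L], collapse = ", ")),
        "dietimpact_validation_error")
    }
  }
  invisible(roster)
}

validate_consumption <- function(consumption, roster = NULL) {
  check_columns(consumption, c("household_id", "item_code", "grams_raw"),
                "consumption log")
  if (any(is.na(consumption$grams_raw)) || any(consumption$grams_raw < 0)) {
    abort("consumption grams_raw must be non-negative",
          "dietimpact_validation_error")
  }
  if (!is.null(roster)) {
    unknown <- setdiff(unique(consumption$household_id),
                       unique(roster$household_id))
    if (length(unknown) > 0L) {
      abort(sprintf(
        "consumption references household(s) absent from the roster: %s",
        paste(unknown, collapse = ", ")), "dietimpact_referential_error")
    }
  }
  invisible(consumption)
}

#' Read the household roster and consumption log
#'
#' @param roster_path CSV with columns `household_id`, `member_id`, `age`,
#'   `sex`, `activity_level`, `region`, `wealth_quintile` (one row per
#'   household member; region and wealth constant within a household).
#' @param consumption_path CSV with columns `household_id`, `item_code`,
#'   `grams_raw` (grams of raw, uncooked food per day for the whole
#'   household; long format, one row per household x item).
#' @return A list with elements `roster` and `consumption`, validated and
#'   cross-referenced (every consumed household must appear in the roster).
#' @export
read_survey <- function(roster_path, consumption_path) {
  roster <- validate_roster(read_csv_utf8(roster_path, "roster"))
  consumption <- validate_consumption(
    read_csv_utf8(consumption_path, "consumption"), roster)
  list(roster = roster, consumption = consumption)
}

validate_fct <- function(fct, nutrients = default_nutrients()) {
  dens_cols <- paste0(nutrients, "_per_100g")
  ret_cols <- paste0("ret_", nutrients)
  check_columns(fct, c("item_code", "name", "energy_kcal_100g",
                       dens_cols, ret_cols), "food composition table")
  if (any(fct$energy_kcal_100g < 0)) {
    abort("energy densities must be non-negative",
          "dietimpact_validation_error")
  }
  for (col in dens_cols) {
    if (any(fct[[col]] < 0)) {
      abort(sprintf("nutrient density column %s has negative values", col),
            "dietimpact_validation_error")
    }
  }
  for (col in ret_cols) {
    if (any(fct[[col]] < 0 | fct[[col]] > 1)) {
      abort(sprintf("retention column %s must lie in [0,1]", col),
            "dietimpact_validation_error")
    }
  }
  if (anyDuplicated(fct$item_code)) {
    abort("duplicate item_code in food composition table",
          "dietimpact_validation_error")
  }
  invisible(fct)
}

validate_groupmap <- function(groupmap) {
  check_columns(groupmap, c("item_code", "pattern_group", "mddw_group"),
                "group map")
  check_vocab(groupmap$pattern_group, pattern_groups(),
              "group map pattern_group")
  mddw <- groupmap$mddw_group
  mddw[mddw %in% c("", "none")] <- NA_character_
  groupmap$mddw_group <- mddw
  check_vocab(mddw, mddw_groups(), "group map mddw_group")
  if (anyDuplicated(groupmap$item_code)) {
    abort("duplicate item_code in group map", "dietimpact_validation_error")
  }
  invisible(groupmap)
}

validate_footprints <- function(footprint, groupmap = NULL) {
  check_columns(footprint, c("item_code", "ghge_kgco2e_per_kg",
                             "bluewater_m3_per_kg"), "footprint table")
  if (any(is.na(footprint$ghge_kgco2e_per_kg)) ||
      any(footprint$ghge_kgco2e_per_kg < 0)) {
    abort("GHGE factors must be present and non-negative",
          "dietimpact_validation_error")
  }
  bw <- footprint$bluewater_m3_per_kg
  if (any(!is.na(bw) & bw < 0)) {
    abort("blue-water factors must be non-negative when present",
          "dietimpact_validation_error")
  }
  if (!is.null(groupmap)) {
    grp <- groupmap$pattern_group[match(footprint$item_code,
                                        groupmap$item_code)]
    excluded <- grp %in% bwu_excluded_groups()
    bad <- footprint$item_code[excluded & !is.na(bw)]
    if (length(bad) > 0L) {
      abort(sprintf(
        paste("item(s) in blue-water-excluded groups (condiments, sweet",
              "foods, liquor/alcohol) must not carry blue-water values: %s"),
        paste(bad, collapse = ", ")), "dietimpact_validation_error")
    }
  }
  invisible(footprint)
}

#' Read and cross-validate the reference tables
#'
#' Loads the food composition table, the item-to-group map and the
#' footprint factor table, then enforces referential closure: every mapped
#' item must resolve in the composition table, and items mapped to the
#' blue-water-excluded groups must carry an empty blue-water field.
#'
#' @param fct_path CSV: `item_code`, `name`, `energy_kcal_100g`,
#'   `<nutrient>_per_100g`..., `ret_<nutrient>`....
#' @param groupmap_path CSV: `item_code`, `pattern_group`, `mddw_group`
#'   (empty or `none` when the item counts towards no MDD-W group).
#' @param footprint_path CSV: `item_code`, `ghge_kgco2e_per_kg`,
#'   `bluewater_m3_per_kg` (empty field = no factor).
#' @param nutrients Nutrient vocabulary expected in the composition table.
#' @return List with elements `fct`, `groupmap`, `footprint`.
#' @export
read_reference_tables <- function(fct_path, groupmap_path, footprint_path,
                                  nutrients = default_nutrients()) {
  fct <- validate_fct(read_csv_utf8(fct_path, "food composition"), nutrients)
  groupmap <- read_csv_utf8(groupmap_path, "group map")
  validate_groupmap(groupmap)
  groupmap$mddw_group[groupmap$mddw_group %in% c("", "none")] <- NA_character_
  footprint <- validate_footprints(
    read_csv_utf8(footprint_path, "footprint"), groupmap)
  dangling <- setdiff(groupmap$item_code, fct$item_code)
  if (length(dangling) > 0L) {
    abort(sprintf("group map references item(s) absent from the FCT: %s",
                  paste(dangling, collapse = ", ")),
          "dietimpact_referential_error")
  }
  dangling_fp <- setdiff(footprint$item_code, fct$item_code)
  if (length(dangling_fp) > 0L) {
    abort(sprintf("footprint table references item(s) absent from the FCT: %s",
                  paste(dangling_fp, collapse = ", ")),
          "dietimpact_referential_error")
  }
  list(fct = fct, groupmap = groupmap, footprint = footprint)
}

#' Write a result table to delimited text
#'
#' UTF-8 CSV with stable column order; re-reading with [read_results()]
#' reproduces integers exactly and reals to at least 12 significant
#' digits (numbers are serialised at R's full double precision).
#'
#' @param results A data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  ok <- tryCatch({
    # file() warns and then errors on an unwritable path; the error is
    # what we act on
    con <- suppressWarnings(file(path, open = "w", encoding = "UTF-8"))
    on.exit(close(con))
    utils::write.csv(format_for_csv(results), con, row.names = FALSE,
                     na = "", quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("cannot write results to '%s': %s", path,
                  conditionMessage(ok)), "dietimpact_io_error")
  }
  invisible(path)
}

# Serialise doubles at 17 significant digits so the write/read round-trip
# is lossless; leave integers and strings alone.
format_for_csv <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) {
      out <- vapply(col, function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 17,
                                                scientific = FALSE)
      }, character(1))
      out
    } else {
      col
    }
  }), check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a result table written by [write_results()]
#'
#' @param path CSV file.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  read_csv_utf8(path, "results")
}
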