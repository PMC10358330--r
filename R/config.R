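# Pipeline configuration: energy requirements, nutrient requirements,
# thresholds. Everything here is a documented, user-replaceable default;
# nothing is treated as ground truth from any particular national table.

#' Default energy-requirement table
#'
#' Daily energy requirements (kcal/day) by sex, age band and physical
#' activity level, used only to form adult-female-equivalent (AFE) ratios.
#' The reference profile is a female of 20-30 years with moderate activity
#' (2,200 kcal/day, the conventional average requirement for adult women);
#' all other strata are FAO-style values with light/heavy activity at
#' roughly -10%/+15% of moderate. Only the ratios to the reference matter,
#' so moderate rescaling of the whole table leaves AFE unchanged.
#'
#' @return A data.frame with columns `sex`, `age_min`, `age_max`,
#'   `activity_level`, `kcal`.
#' @export
default_energy_requirements <- function() {
  bands <- data.frame(
    age_min = c(0, 3, 6, 10, 14, 20, 31, 60),
    age_max = c(2, 5, 9, 13, 19, 30, 59, 130)
  )
  moderate <- list(
    female = c(900, 1300, 1600, 1900, 2100, 2200, 2100, 1800),
    male   = c(950, 1400, 1750, 2100, 2500, 2600, 2500, 2100)
  )
  out <- do.call(rbind, lapply(sex_levels(), function(sx) {
    do.call(rbind, lapply(seq_len(nrow(bands)), function(i) {
      base <- moderate[[sx]][i]
      data.frame(sex = sx,
                 age_min = bands$age_min[i], age_max = bands$age_max[i],
                 activity_level = activity_levels(),
                 kcal = round(base * c(0.90, 1.00, 1.15)))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Construct an energy-requirement table
#'
#' Validates the stratum table and resolves the reference requirement (the
#' female 20-30 y, moderate-activity stratum, whose AFE is 1 by
#' definition).
#'
#' @param df Data.frame with columns `sex`, `age_min`, `age_max`,
#'   `activity_level`, `kcal`; bands must not overlap within a sex.
#' @return An object of class `energy_requirement_table`.
#' @export
energy_requirement_table <- function(df = default_energy_requirements()) {
  check_columns(df, c("sex", "age_min", "age_max", "activity_level", "kcal"),
                "energy-requirement table")
  check_vocab(df$sex, sex_levels(), "energy-requirement table sex")
  check_vocab(df$activity_level, activity_levels(),
              "energy-requirement table activity_level")
  if (any(df$kcal <= 0)) {
    abort("energy requirements must be strictly positive",
          "dietimpact_validation_error")
  }
  ref <- df$kcal[df$sex == "female" & df$age_min <= 25 & df$age_max >= 25 &
                   df$activity_level == "moderate"]
  if (length(ref) != 1L) {
    abort(paste("energy-requirement table must contain exactly one stratum",
                "covering the reference female (20-30 y, moderate activity)"),
          "dietimpact_validation_error")
  }
  structure(list(table = df, reference_requirement = ref),
            class = "energy_requirement_table")
}

#' @export
print.energy_requirement_table <- function(x, ...) {
  cat("Energy-requirement table:", nrow(x$table), "strata;",
      "reference (female 20-30 y, moderate) =", x$reference_requirement,
      "kcal/day\n")
  invisible(x)
}

#' Define a nutrient requirement for probability-of-adequacy scoring
#'
#' Exactly one of three requirement kinds:
#' \describe{
#'   \item{`normal_ear`}{normally distributed requirement centred on the
#'     EAR with SD = `cv` x EAR; PA is the normal CDF of the intake.}
#'   \item{`iron_full_probability`}{the full-probability treatment of iron
#'     for menstruating women: the absorbed-iron requirement is skewed and
#'     modelled log-normal (median `median_absorbed_req`, log-scale SD
#'     `log_sd`); observed intake is scaled by `bioavailability` before
#'     comparison.}
#'   \item{`ai_threshold`}{a binary comparison to an adequate intake (AI),
#'     used for calcium.}
#' }
#'
#' @param nutrient Nutrient identifier.
#' @param kind One of `"normal_ear"`, `"iron_full_probability"`,
#'   `"ai_threshold"`.
#' @param ear Estimated average requirement, units/day (normal_ear).
#' @param cv Coefficient of variation of the requirement, in (0, 0.5].
#' @param ai Adequate intake threshold, units/day (ai_threshold).
#' @param median_absorbed_req Median absorbed requirement, mg/day (iron).
#' @param log_sd Log-scale SD of the absorbed requirement (iron).
#' @param bioavailability Fraction of ingested iron absorbed; 0.05 is the
#'   regional default for monotonous cereal-based diets.
#' @return An object of class `nutrient_requirement`.
#' @export
nutrient_requirement <- function(nutrient, kind,
                                 ear = NULL, cv = NULL, ai = NULL,
                                 median_absorbed_req = NULL, log_sd = NULL,
                                 bioavailability = 0.05) {
  kind <- match.arg(kind,
                    c("normal_ear", "iron_full_probability", "ai_threshold"))
  if (kind == "normal_ear") {
    if (is.null(ear) || ear <= 0) {
      abort(sprintf("nutrient '%s': normal_ear requires ear > 0", nutrient),
            "dietimpact_validation_error")
    }
    if (is.null(cv) || cv <= 0 || cv > 0.5) {
      abort(sprintf("nutrient '%s': cv must lie in (0, 0.5]", nutrient),
            "dietimpact_validation_error")
    }
  } else if (kind == "iron_full_probability") {
    if (is.null(median_absorbed_req) || median_absorbed_req <= 0 ||
        is.null(log_sd) || log_sd <= 0) {
      abort(sprintf(
        "nutrient '%s': iron_full_probability requires median_absorbed_req > 0 and log_sd > 0",
        nutrient), "dietimpact_validation_error")
    }
    if (bioavailability <= 0 || bioavailability > 1) {
      abort(sprintf("nutrient '%s': bioavailability must lie in (0, 1]",
                    nutrient), "dietimpact_validation_error")
    }
  } else {
    if (is.null(ai) || ai <= 0) {
      abort(sprintf("nutrient '%s': ai_threshold requires ai > 0", nutrient),
            "dietimpact_validation_error")
    }
  }
  structure(list(nutrient = nutrient, kind = kind, ear = ear, cv = cv,
                 ai = ai, median_absorbed_req = median_absorbed_req,
                 log_sd = log_sd, bioavailability = bioavailability),
            class = "nutrient_requirement")
}

#' Default nutrient-requirement set
#'
#' Requirements for the 11 default nutrients, for non-pregnant
#' non-lactating adult women. Where only an RDA is conventionally tabled
#' the EAR is RDA/1.2 (the standard EAR-RDA relation at 10% CV); CV
#' defaults to 0.10 for all normally treated nutrients. Iron uses the
#' full-probability approach (log-normal absorbed requirement, median 1.46
#' mg/day, log-SD 0.42, bioavailability 5%); calcium compares against an
#' adequate intake of 1,000 mg. All values are replaceable defaults, not
#' survey-specific ground truth.
#'
#' @return Named list of [nutrient_requirement()] objects.
#' @export
default_nutrient_requirements <- function() {
  reqs <- list(
    nutrient_requirement("protein", "normal_ear", ear = 39.2, cv = 0.10),
    nutrient_requirement("vitamin_a", "normal_ear", ear = 500, cv = 0.10),
    nutrient_requirement("vitamin_c", "normal_ear", ear = 58.3, cv = 0.10),
    nutrient_requirement("vitamin_b6", "normal_ear", ear = 1.08, cv = 0.10),
    nutrient_requirement("vitamin_b12", "normal_ear", ear = 2.0, cv = 0.10),
    nutrient_requirement("vitamin_e", "normal_ear", ear = 10.0, cv = 0.10),
    nutrient_requirement("folate", "normal_ear", ear = 320, cv = 0.10),
    nutrient_requirement("iron", "iron_full_probability",
                         median_absorbed_req = 1.46, log_sd = 0.42,
                         bioavailability = 0.05),
    nutrient_requirement("zinc", "normal_ear", ear = 6.7, cv = 0.10),
    nutrient_requirement("calcium", "ai_threshold", ai = 1000),
    nutrient_requirement("magnesium", "normal_ear", ear = 255, cv = 0.10)
  )
  names(reqs) <- vapply(reqs, `[[`, character(1), "nutrient")
  reqs
}

#' Default pipeline configuration
#'
#' The single object holding every tunable: the nutrient list, the
#' requirement set, the energy-requirement table, and the analysis
#' thresholds (2,000-kcal standardisation base, MPA cut-off 0.5, MDD-W
#' 15 g rule with the >= 5 group cut-off, 0.20 loading display threshold).
#'
#' @return Nested list of class `dietimpact_config`.
#' @export
default_config <- function() {
  structure(list(
    nutrients = default_nutrients(),
    nutrient_requirements = default_nutrient_requirements(),
    energy_requirements = energy_requirement_table(),
    thresholds = list(
      energy_standard_kcal = 2000,
      mpa_cutoff = 0.5,
      mddw_min_grams = 15,
      mddw_min_groups = 5,
      loading_display = 0.20,
      eigenvalue_retention = 1
    )
  ), class = "dietimpact_config")
}

#' Write a configuration to a JSON file
#'
#' @param config A `dietimpact_config` list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  plain <- unclass(config)
  plain$nutrient_requirements <- lapply(plain$nutrient_requirements, unclass)
  plain$energy_requirements <- plain$energy_requirements$table
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a configuration from a JSON file
#'
#' @param path JSON file produced by [write_config()] (or hand-written in
#'   the same layout).
#' @return A `dietimpact_config` list with rebuilt requirement objects.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), "dietimpact_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  reqs <- lapply(raw$nutrient_requirements, function(r) {
    nutrient_requirement(r$nutrient, r$kind,
                         ear = r$ear, cv = r$cv, ai = r$ai,
                         median_absorbed_req = r$median_absorbed_req,
                         log_sd = r$log_sd,
                         bioavailability = r$bioavailability %||% 0.05)
  })
  structure(list(
    nutrients = raw$nutrients,
    nutrient_requirements = reqs,
    energy_requirements = energy_requirement_table(
      as.data.frame(raw$energy_requirements)),
    thresholds = as.list(raw$thresholds)
  ), class = "dietimpact_config")
}
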