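# Diet quality: per-nutrient probability of adequacy (PA), their mean
# (MPA) on intakes standardised to 2,000 kcal, and the MDD-W dietary
# diversity score.

#' Standardise an intake to 2,000 kcal
#'
#' Nutrient-density scaling: `intake x 2000 / energy`. Applied per
#' household before any averaging, so adequacy compares diet *quality*
#' rather than quantity.
#'
#' @param intake Amount per day (any unit).
#' @param energy Energy intake, kcal/day; must be strictly positive.
#' @param base Standardisation base, kcal (default 2000).
#' @return Amount per `base` kcal.
#' @export
standardize_to_2000 <- function(intake, energy, base = 2000) {
  if (any(energy <= 0)) {
    abort("energy intake must be strictly positive to standardise",
          "dietimpact_degenerate_diet_error")
  }
  intake * base / energy
}

#' Probability of adequacy, normal requirement
#'
#' \eqn{PA = \Phi((\bar y - r) / SD)} with r the EAR and SD = cv x EAR:
#' the probability that a normally distributed requirement falls below
#' the observed intake.
#'
#' @param intake Observed intake, units/day (vectorised).
#' @param req A [nutrient_requirement()] of kind `normal_ear`.
#' @return Probability in \[0, 1\].
#' @export
pa_normal <- function(intake, req) {
  stopifnot(inherits(req, "nutrient_requirement"), req$kind == "normal_ear")
  stats::pnorm((intake - req$ear) / (req$cv * req$ear))
}

#' Probability of adequacy, full-probability iron
#'
#' The absorbed-iron requirement of menstruating women is right-skewed,
#' so a normal CDF understates inadequacy; the full-probability approach
#' integrates the requirement distribution directly. Here the absorbed
#' requirement is log-normal (median `median_absorbed_req`, log-scale SD
#' `log_sd`) and observed intake is scaled by `bioavailability` before
#' comparison: \eqn{PA = P(R \le intake \times b)}.
#'
#' @param intake Iron intake, mg/day (vectorised).
#' @param req A [nutrient_requirement()] of kind `iron_full_probability`.
#' @return Probability in \[0, 1\].
#' @export
pa_iron <- function(intake, req) {
  stopifnot(inherits(req, "nutrient_requirement"),
            req$kind == "iron_full_probability")
  absorbed <- intake * req$bioavailability
  stats::plnorm(absorbed, meanlog = log(req$median_absorbed_req),
                sdlog = req$log_sd)
}

#' Probability of adequacy, adequate-intake threshold
#'
#' Binary comparison to an adequate intake (AI): PA is 1 when intake is
#' at or above the AI, 0 otherwise. Used for calcium (AI 1,000 mg).
#'
#' @param intake Intake, units/day (vectorised).
#' @param req A [nutrient_requirement()] of kind `ai_threshold`.
#' @return 0 or 1.
#' @export
pa_ai <- function(intake, req) {
  stopifnot(inherits(req, "nutrient_requirement"),
            req$kind == "ai_threshold")
  as.numeric(intake >= req$ai)
}

pa_dispatch <- function(intake, req) {
  switch(req$kind,
         normal_ear = pa_normal(intake, req),
         iron_full_probability = pa_iron(intake, req),
         ai_threshold = pa_ai(intake, req))
}

#' Mean probability of adequacy for one household
#'
#' Each configured nutrient's intake is standardised to 2,000 kcal, then
#' dispatched to the requirement-kind-specific PA; MPA is the unweighted
#' mean. MPA below the 0.5 cut-off flags low micronutrient adequacy.
#'
#' @param per_afe A `per_afe_intake` (see [per_afe_intake()]).
#' @param requirements Named list of [nutrient_requirement()] objects
#'   covering every configured nutrient.
#' @param nutrients Nutrient list to average over.
#' @param mpa_cutoff Low-adequacy threshold (default 0.5).
#' @return List with `pa` (named vector), `mpa`, `low_mpa`.
#' @export
mpa <- function(per_afe, requirements = default_nutrient_requirements(),
                nutrients = default_nutrients(), mpa_cutoff = 0.5) {
  stopifnot(inherits(per_afe, "per_afe_intake"))
  missing_req <- setdiff(nutrients, names(requirements))
  if (length(missing_req) > 0L) {
    abort(sprintf("no requirement configured for nutrient(s): %s",
                  paste(missing_req, collapse = ", ")),
          "dietimpact_config_error")
  }
  pa <- vapply(nutrients, function(n) {
    std <- standardize_to_2000(per_afe$nutrient_intake[[n]], per_afe$energy)
    pa_dispatch(std, requirements[[n]])
  }, numeric(1))
  m <- mean(pa)
  list(pa = pa, mpa = m, low_mpa = m < mpa_cutoff)
}

#' MDD-W dietary diversity score for one household
#'
#' Per-AFE grams are summed within each of the 10 MDD-W food groups; the
#' score counts groups reaching 15 g or more, and minimum dietary
#' diversity is met at 5 or more groups. Items with no MDD-W group
#' (condiments, oils, alcohol, ...) contribute to no group.
#'
#' @param per_afe A `per_afe_intake`.
#' @param groupmap Group map data.frame (`item_code`, `mddw_group`).
#' @param min_grams Group counting threshold, g (default 15).
#' @param min_groups Minimum-diversity cut-off (default 5).
#' @return List with `dds` (integer 0..10), `mdd_met`, `group_grams`
#'   (named length-10 vector).
#' @export
dds <- function(per_afe, groupmap, min_grams = 15, min_groups = 5) {
  stopifnot(inherits(per_afe, "per_afe_intake"))
  mg <- groupmap$mddw_group[match(names(per_afe$item_intake),
                                  groupmap$item_code)]
  grams <- stats::setNames(numeric(10), mddw_groups())
  keep <- !is.na(mg)
  if (any(keep)) {
    sums <- tapply(per_afe$item_intake[keep], mg[keep], sum)
    grams[names(sums)] <- sums
  }
  score <- sum(grams >= min_grams)
  list(dds = as.integer(score), mdd_met = score >= min_groups,
       group_grams = grams)
}

#' Diet-quality table for a whole population
#'
#' Vectorised MPA + DDS over every household of a [per_afe_table()].
#'
#' @param tab A `per_afe_table`.
#' @param groupmap Group map data.frame.
#' @param requirements Named list of [nutrient_requirement()] objects.
#' @param nutrients Nutrient list to average over.
#' @param mpa_cutoff,min_grams,min_groups Thresholds as in [mpa()] and
#'   [dds()].
#' @return Data.frame with one row per household: `household_id`,
#'   `energy_kcal`, `pa_<nutrient>`..., `mpa`, `low_mpa`, `dds`,
#'   `mdd_met`.
#' @export
diet_quality_table <- function(tab, groupmap,
                               requirements = default_nutrient_requirements(),
                               nutrients = default_nutrients(),
                               mpa_cutoff = 0.5, min_grams = 15,
                               min_groups = 5) {
  stopifnot(inherits(tab, "per_afe_table"))
  missing_req <- setdiff(nutrients, names(requirements))
  if (length(missing_req) > 0L) {
    abort(sprintf("no requirement configured for nutrient(s): %s",
                  paste(missing_req, collapse = ", ")),
          "dietimpact_config_error")
  }
  if (any(tab$energy <= 0)) {
    abort("household(s) with non-positive energy intake cannot be scored",
          "dietimpact_degenerate_diet_error")
  }
  pa_mat <- vapply(nutrients, function(n) {
    std <- tab$nutrients[, n] * 2000 / tab$energy
    pa_dispatch(std, requirements[[n]])
  }, numeric(length(tab$households)))
  if (length(tab$households) == 1L) {
    pa_mat <- matrix(pa_mat, nrow = 1, dimnames = list(NULL, nutrients))
  }
  mpa_vec <- rowMeans(pa_mat)

  # DDS: sum per-AFE grams within MDD-W groups, count >= 15 g
  items <- tab$items
  mg <- groupmap$mddw_group[match(items$item_code, groupmap$item_code)]
  keep <- !is.na(mg)
  dds_vec <- integer(length(tab$households))
  if (any(keep)) {
    hh_f <- factor(items$household_id[keep], levels = tab$households)
    grp_f <- factor(mg[keep], levels = mddw_groups())
    sums <- rowsum(items$grams_per_afe[keep],
                   interaction(hh_f, grp_f, drop = TRUE))
    key_hh <- sub("\\.[^.]*$", "", rownames(sums))
    met <- sums[, 1L] >= min_grams
    counts <- tapply(met, key_hh, sum)
    dds_vec[match(names(counts), tab$households)] <- as.integer(counts)
  }

  out <- data.frame(household_id = tab$households,
                    energy_kcal = as.numeric(tab$energy),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (n in nutrients) out[[paste0("pa_", n)]] <- pa_mat[, n]
  out$mpa <- mpa_vec
  out$low_mpa <- mpa_vec < mpa_cutoff
  out$dds <- dds_vec
  out$mdd_met <- dds_vec >= min_groups
  out
}
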