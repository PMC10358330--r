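# Adult-female-equivalent (AFE) conversion: household totals -> per-AFE
# daily intakes. Each member counts as the ratio of their energy
# requirement to the reference female's; household intake divided by the
# summed ratios gives the per-AFE diet analysed downstream.

lookup_requirement <- function(age, sex, activity_level, ert) {
  tab <- ert$table
  hit <- tab$sex == sex & tab$activity_level == activity_level &
    tab$age_min <= age & tab$age_max >= age
  if (sum(hit) == 0L) {
    abort(sprintf(
      "no energy-requirement stratum for (sex=%s, age=%s, activity=%s)",
      sex, age, activity_level), "dietimpact_lookup_error")
  }
  tab$kcal[which(hit)[1L]]
}

#' AFE ratio of one household member
#'
#' The member's daily energy requirement divided by the reference
#' female's (20-30 y, moderate activity); the reference member herself
#' has ratio exactly 1.
#'
#' @param member A list or one-row data.frame with `age`, `sex`,
#'   `activity_level`.
#' @param ert An [energy_requirement_table()].
#' @return A strictly positive scalar.
#' @export
afe_ratio <- function(member, ert = energy_requirement_table()) {
  req <- lookup_requirement(member$age[[1L]], member$sex[[1L]],
                            member$activity_level[[1L]], ert)
  req / ert$reference_requirement
}

#' Total AFE of each household
#'
#' Sums per-member AFE ratios within each household.
#'
#' @param roster Roster data.frame (one row per member); see
#'   [read_survey()].
#' @param ert An [energy_requirement_table()].
#' @return Named numeric vector of household AFE totals, one per
#'   household, named by `household_id`.
#' @export
household_afe <- function(roster, ert = energy_requirement_table()) {
  tab <- ert$table
  req <- rep(NA_real_, nrow(roster))
  for (i in seq_len(nrow(tab))) {
    hit <- is.na(req) & roster$sex == tab$sex[i] &
      roster$activity_level == tab$activity_level[i] &
      roster$age >= tab$age_min[i] & roster$age <= tab$age_max[i]
    req[hit] <- tab$kcal[i]
  }
  if (anyNA(req)) {
    j <- which(is.na(req))[1L]
    abort(sprintf(
      "no energy-requirement stratum for (sex=%s, age=%s, activity=%s)",
      roster$sex[j], roster$age[j], roster$activity_level[j]),
      "dietimpact_lookup_error")
  }
  ratios <- req / ert$reference_requirement
  totals <- tapply(ratios, roster$household_id, sum)
  out <- as.numeric(totals)
  names(out) <- names(totals)
  out
}

#' Convert household consumption to per-AFE intakes
#'
#' For every household: divides household grams by total AFE, aggregates
#' items into the 18 pattern food groups, and computes per-AFE energy and
#' post-retention nutrient intakes from the food composition table.
#' Nutrient intake of nutrient n is
#' \eqn{\sum_{items} g_{item} \times density_n(item)/100 \times retention_n(item)};
#' energy is analogous without retention.
#'
#' @param roster,consumption Validated survey tables ([read_survey()]).
#' @param fct,groupmap Reference tables ([read_reference_tables()]).
#' @param ert An [energy_requirement_table()].
#' @param nutrients Nutrient vocabulary (columns of `fct`).
#' @return An object of class `per_afe_table`: a list with
#'   \describe{
#'     \item{households}{character vector of household ids (row order of
#'       all matrices below)}
#'     \item{afe}{numeric vector of household AFE totals}
#'     \item{energy}{kcal/day per AFE}
#'     \item{groups}{n x 18 matrix of g/day per AFE by pattern group}
#'     \item{nutrients}{n x length(nutrients) matrix, post-retention}
#'     \item{items}{long data.frame `household_id`, `item_code`,
#'       `grams_per_afe`}
#'   }
#' @export
per_afe_table <- function(roster, consumption, fct, groupmap,
                          ert = energy_requirement_table(),
                          nutrients = default_nutrients()) {
  validate_consumption(consumption, roster)
  missing_items <- setdiff(unique(consumption$item_code), fct$item_code)
  if (length(missing_items) > 0L) {
    abort(sprintf(
      "consumed item(s) missing from the food composition table: %s",
      paste(missing_items, collapse = ", ")), "dietimpact_linkage_error")
  }
  missing_map <- setdiff(unique(consumption$item_code), groupmap$item_code)
  if (length(missing_map) > 0L) {
    abort(sprintf("consumed item(s) missing from the group map: %s",
                  paste(missing_map, collapse = ", ")),
          "dietimpact_linkage_error")
  }

  afe <- household_afe(roster, ert)
  hh <- names(afe)

  idx_fct <- match(consumption$item_code, fct$item_code)
  grams_per_afe <- consumption$grams_raw / afe[match(consumption$household_id,
                                                     hh)]
  hh_f <- factor(consumption$household_id, levels = hh)

  # sum per household over all factor levels (0 for households with no rows)
  sum_by_hh <- function(v) {
    as.numeric(tapply(v, hh_f, sum, default = 0))
  }

  # energy: kcal per 100 g, no retention
  energy <- sum_by_hh(grams_per_afe * fct$energy_kcal_100g[idx_fct] / 100)

  # nutrients: density per 100 g x retention
  nut_mat <- vapply(nutrients, function(n) {
    dens <- fct[[paste0(n, "_per_100g")]][idx_fct]
    ret <- fct[[paste0("ret_", n)]][idx_fct]
    sum_by_hh(grams_per_afe * dens / 100 * ret)
  }, numeric(length(hh)))
  if (length(hh) == 1L) nut_mat <- matrix(nut_mat, nrow = 1,
                                          dimnames = list(NULL, nutrients))

  # 18 pattern groups
  grp <- factor(groupmap$pattern_group[match(consumption$item_code,
                                             groupmap$item_code)],
                levels = pattern_groups())
  groups <- matrix(0, nrow = length(hh), ncol = length(pattern_groups()),
                   dimnames = list(hh, pattern_groups()))
  agg <- rowsum(grams_per_afe, interaction(hh_f, grp, drop = TRUE))
  # interaction keys are "<household>.<group>"; group names contain no ".",
  # so split at the last dot to stay safe with arbitrary household ids
  key_grp <- sub("^.*\\.", "", rownames(agg))
  key_hh <- sub("\\.[^.]*$", "", rownames(agg))
  groups[cbind(match(key_hh, hh), match(key_grp, pattern_groups()))] <-
    agg[, 1L]

  rownames(nut_mat) <- hh
  structure(list(households = hh, afe = afe, energy = stats::setNames(energy, hh),
                 groups = groups, nutrients = nut_mat,
                 items = data.frame(household_id = consumption$household_id,
                                    item_code = consumption$item_code,
                                    grams_per_afe = as.numeric(grams_per_afe),
                                    stringsAsFactors = FALSE)),
            class = "per_afe_table")
}

#' Per-AFE intake of a single household
#'
#' Convenience wrapper around [per_afe_table()] for one household,
#' returning that household's AFE total, item intakes, group intakes,
#' energy and nutrient intakes.
#'
#' @param household_id Identifier present in the roster.
#' @inheritParams per_afe_table
#' @return An object of class `per_afe_intake` (a list with
#'   `household_id`, `afe_total`, `item_intake` (named g/day vector),
#'   `group_intake` (named length-18 vector), `energy`,
#'   `nutrient_intake`).
#' @export
per_afe_intake <- function(household_id, roster, consumption, fct, groupmap,
                           ert = energy_requirement_table(),
                           nutrients = default_nutrients()) {
  keep_r <- roster$household_id == household_id
  if (!any(keep_r)) {
    abort(sprintf("household '%s' not found in roster", household_id),
          "dietimpact_lookup_error")
  }
  tab <- per_afe_table(roster[keep_r, , drop = FALSE],
                       consumption[consumption$household_id == household_id, ,
                                   drop = FALSE],
                       fct, groupmap, ert, nutrients)
  items <- stats::setNames(tab$items$grams_per_afe, tab$items$item_code)
  structure(list(household_id = household_id,
                 afe_total = unname(tab$afe[1L]),
                 item_intake = items,
                 group_intake = tab$groups[1L, ],
                 energy = unname(tab$energy[1L]),
                 nutrient_intake = tab$nutrients[1L, ]),
            class = "per_afe_intake")
}

#' @export
print.per_afe_table <- function(x, ...) {
  cat("Per-AFE intake table:", length(x$households), "households,",
      ncol(x$nutrients), "nutrients; mean energy",
      round(mean(x$energy)), "kcal/day per AFE\n")
  invisible(x)
}

#' Flatten a per-AFE table to a data.frame
#'
#' One row per household: AFE total, energy, the 18 group intakes and the
#' nutrient intakes. This is the interchange format written between
#' pipeline stages.
#'
#' @param x A `per_afe_table`.
#' @param ... Unused.
#' @return A data.frame.
#' @export
as.data.frame.per_afe_table <- function(x, ...) {
  data.frame(household_id = x$households,
             afe_total = as.numeric(x$afe),
             energy_kcal = as.numeric(x$energy),
             as.data.frame(x$groups),
             as.data.frame(x$nutrients),
             check.names = FALSE, row.names = NULL,
             stringsAsFactors = FALSE)
}
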