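# Environmental footprint linkage: item-level GHGE (kg CO2-eq/kg) and
# blue-water (m3/kg) factors applied to per-AFE consumption. A missing
# GHGE factor for a consumed item is a data defect (every item must be
# matched), never a silent zero; a missing blue-water factor is legal
# only for the excluded groups (condiments, sweet foods, liquor/alcohol),
# whose consumed mass is tracked as `excluded_mass`.

#' Link footprint factors to a population's per-AFE intakes
#'
#' @param tab A [per_afe_table()].
#' @param footprint Footprint factor table (`item_code`,
#'   `ghge_kgco2e_per_kg`, `bluewater_m3_per_kg`).
#' @param groupmap Group map data.frame.
#' @return Object of class `footprint_table`: list with `households`,
#'   `energy`, `ghge_total`, `bwu_total` (per AFE per day),
#'   `ghge_per2000`, `bwu_per2000`, `group_ghge` and `group_bwu`
#'   (n x 18 matrices), `excluded_mass` (g/day per AFE).
#' @export
footprint_table <- function(tab, footprint, groupmap) {
  stopifnot(inherits(tab, "per_afe_table"))
  items <- tab$items
  idx <- match(items$item_code, footprint$item_code)
  no_factor <- unique(items$item_code[is.na(idx)])
  if (length(no_factor) > 0L) {
    abort(sprintf("consumed item(s) with no GHGE factor: %s",
                  paste(no_factor, collapse = ", ")),
          "dietimpact_linkage_error")
  }
  grp <- groupmap$pattern_group[match(items$item_code, groupmap$item_code)]
  if (anyNA(grp)) {
    abort(sprintf("consumed item(s) with no group mapping: %s",
                  paste(unique(items$item_code[is.na(grp)]), collapse = ", ")),
          "dietimpact_linkage_error")
  }
  excluded <- grp %in% bwu_excluded_groups()
  bw <- footprint$bluewater_m3_per_kg[idx]
  bad_bw <- unique(items$item_code[!excluded & is.na(bw)])
  if (length(bad_bw) > 0L) {
    abort(sprintf(
      "consumed item(s) outside the excluded groups with no blue-water factor: %s",
      paste(bad_bw, collapse = ", ")), "dietimpact_linkage_error")
  }

  hh <- tab$households
  hh_f <- factor(items$household_id, levels = hh)
  grp_f <- factor(grp, levels = pattern_groups())
  kg <- items$grams_per_afe / 1000

  ghge_item <- kg * footprint$ghge_kgco2e_per_kg[idx]
  bwu_item <- ifelse(excluded, 0, kg * bw)
  excl_item <- ifelse(excluded, items$grams_per_afe, 0)

  agg_matrix <- function(v) {
    m <- matrix(0, length(hh), 18L, dimnames = list(hh, pattern_groups()))
    s <- rowsum(v, interaction(hh_f, grp_f, drop = TRUE))
    key_grp <- sub("^.*\\.", "", rownames(s))
    key_hh <- sub("\\.[^.]*$", "", rownames(s))
    m[cbind(match(key_hh, hh), match(key_grp, pattern_groups()))] <- s[, 1L]
    m
  }
  group_ghge <- agg_matrix(ghge_item)
  group_bwu <- agg_matrix(bwu_item)
  ghge_total <- rowSums(group_ghge)
  bwu_total <- rowSums(group_bwu)
  excluded_mass <- as.numeric(tapply(excl_item, hh_f, sum, default = 0))

  if (any(tab$energy <= 0)) {
    abort("household(s) with non-positive energy intake cannot be standardised",
          "dietimpact_degenerate_diet_error")
  }
  structure(list(households = hh,
                 energy = tab$energy,
                 ghge_total = ghge_total,
                 bwu_total = bwu_total,
                 ghge_per2000 = ghge_total * 2000 / tab$energy,
                 bwu_per2000 = bwu_total * 2000 / tab$energy,
                 group_ghge = group_ghge,
                 group_bwu = group_bwu,
                 excluded_mass = stats::setNames(excluded_mass, hh)),
            class = "footprint_table")
}

#' Footprint of a single household diet
#'
#' Spec-level wrapper of [footprint_table()] for one `per_afe_intake`.
#'
#' @param per_afe A `per_afe_intake` ([per_afe_intake()]).
#' @param footprint,groupmap Reference tables.
#' @return Object of class `footprint_result`: list with `household_id`,
#'   `ghge_total`, `bwu_total`, `ghge_per2000`, `bwu_per2000`,
#'   `group_ghge`, `group_bwu` (named length-18 vectors),
#'   `excluded_mass`.
#' @export
link_footprints <- function(per_afe, footprint, groupmap) {
  stopifnot(inherits(per_afe, "per_afe_intake"))
  tab <- structure(list(
    households = per_afe$household_id,
    afe = stats::setNames(per_afe$afe_total, per_afe$household_id),
    energy = stats::setNames(per_afe$energy, per_afe$household_id),
    groups = matrix(per_afe$group_intake, 1,
                    dimnames = list(per_afe$household_id, pattern_groups())),
    nutrients = NULL,
    items = data.frame(household_id = per_afe$household_id,
                       item_code = names(per_afe$item_intake),
                       grams_per_afe = as.numeric(per_afe$item_intake),
                       stringsAsFactors = FALSE)),
    class = "per_afe_table")
  ft <- footprint_table(tab, footprint, groupmap)
  structure(list(household_id = per_afe$household_id,
                 ghge_total = unname(ft$ghge_total[1L]),
                 bwu_total = unname(ft$bwu_total[1L]),
                 ghge_per2000 = unname(ft$ghge_per2000[1L]),
                 bwu_per2000 = unname(ft$bwu_per2000[1L]),
                 group_ghge = ft$group_ghge[1L, ],
                 group_bwu = ft$group_bwu[1L, ],
                 excluded_mass = unname(ft$excluded_mass[1L])),
            class = "footprint_result")
}

#' Standardise footprint totals per 2,000 kcal
#'
#' `total x 2000 / energy`, applied per household *before* any population
#' averaging (mean of ratios, never ratio of means -- quintile tables
#' report the mean and SD of household-level standardised values).
#'
#' @param total Footprint total(s) per day.
#' @param energy Energy intake(s), kcal/day; strictly positive.
#' @param base Standardisation base, kcal (default 2000).
#' @return Standardised value(s).
#' @export
per_2000kcal <- function(total, energy, base = 2000) {
  if (any(energy <= 0)) {
    abort("energy intake must be strictly positive to standardise",
          "dietimpact_degenerate_diet_error")
  }
  total * base / energy
}

#' Flatten a footprint table to a data.frame
#'
#' @param x A `footprint_table`.
#' @param ... Unused.
#' @return Data.frame with totals, standardised values and per-group
#'   columns (`ghge_<group>`, `bwu_<group>`).
#' @export
as.data.frame.footprint_table <- function(x, ...) {
  gg <- x$group_ghge; colnames(gg) <- paste0("ghge_", colnames(gg))
  gb <- x$group_bwu; colnames(gb) <- paste0("bwu_", colnames(gb))
  data.frame(household_id = x$households,
             energy_kcal = as.numeric(x$energy),
             ghge_total = as.numeric(x$ghge_total),
             bwu_total = as.numeric(x$bwu_total),
             ghge_per2000 = as.numeric(x$ghge_per2000),
             bwu_per2000 = as.numeric(x$bwu_per2000),
             excluded_mass = as.numeric(x$excluded_mass),
             as.data.frame(gg), as.data.frame(gb),
             check.names = FALSE, row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean per-2,000-kcal food-group contributions by pattern and quintile
#'
#' For each pattern and adherence quintile: the mean standardised
#' contribution of each of the 18 food groups to GHGE and blue-water use
#' (each household's group vector scaled by 2000/energy first). Group
#' means sum to the stratum's mean standardised total, so the table
#' stacks into the conventional contribution bar charts.
#'
#' @param ft A `footprint_table`.
#' @param quintiles Data.frame of quintile labels, one column per pattern
#'   (rows aligned with `ft$households`).
#' @return Tidy data.frame: `pattern`, `quintile`, `group`, `measure`
#'   (`ghge`/`bwu`), `mean_per2000`.
#' @export
group_contribution_table <- function(ft, quintiles) {
  stopifnot(inherits(ft, "footprint_table"))
  quintiles <- as.data.frame(quintiles)
  if (nrow(quintiles) != length(ft$households)) {
    abort("quintile labels do not cover the footprint households",
          "dietimpact_alignment_error")
  }
  scale2000 <- 2000 / ft$energy
  g2000 <- ft$group_ghge * scale2000
  b2000 <- ft$group_bwu * scale2000
  rows <- list()
  for (pat in names(quintiles)) {
    for (q in c(paste0("Q", 1:5), "total")) {
      sel <- if (q == "total") rep(TRUE, nrow(quintiles)) else
        quintiles[[pat]] == q
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = pat, quintile = q, group = pattern_groups(),
        measure = "ghge",
        mean_per2000 = colMeans(g2000[sel, , drop = FALSE]),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = pat, quintile = q, group = pattern_groups(),
        measure = "bwu",
        mean_per2000 = colMeans(b2000[sel, , drop = FALSE]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
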