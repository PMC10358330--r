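# Synthetic survey generator. Emulates the *structure* of a national
# household nutrition survey -- multi-member households in 6 regions and 5
# wealth strata, item-level 24-h consumption with latent dietary-pattern
# signal -- without attempting to match any real survey's marginals.
#
# Generative model, per household i with latent scores z_i ~ N(mu_i, sd):
#   group intake per AFE (g/day) = max(0, baseline + signatures %*% z_i + eps)
# with eps ~ N(0, noise_sd), mu_i = region bias + wealth bias. Group intake
# is split uniformly over that group's items and multiplied by the
# household's total AFE to give household-level grams.

# Loading-shaped default signatures (x100 would give a conventional
# loading table): three planted patterns -- meat-rich "omnivorous",
# rice/vegetable "traditional", fish/condiment "pescatarian". The raw
# shapes are mildly oblique (they share rice, fish and oils); since PCA
# recovers orthogonal directions, the defaults are Gram-Schmidt
# orthogonalised with norms preserved, which changes each shape by
# congruence < 0.02 but makes the planted structure the PCA estimand.
default_signature_shapes <- function() {
  g <- pattern_groups()
  omnivorous <- stats::setNames(numeric(18), g)
  omnivorous[c("rice", "non_rice_staples", "roots_tubers_nuts_seeds",
               "red_meat", "white_meat", "organs", "processed_meat",
               "fish_seafood", "eggs", "milk_dairy", "other_vegetables",
               "fruits", "sweet_foods", "liquor_alcohol")] <-
    c(-0.38, 0.48, 0.23, 0.37, 0.26, 0.42, 0.27, -0.22, 0.23, 0.34,
      0.22, 0.51, 0.34, 0.22)
  traditional <- stats::setNames(numeric(18), g)
  traditional[c("rice", "non_rice_staples", "roots_tubers_nuts_seeds",
                "red_meat", "fish_seafood", "rich_vitamin_vegetables",
                "oils", "fats")] <-
    c(0.47, -0.23, 0.35, 0.31, -0.44, 0.53, -0.32, 0.55)
  pescatarian <- stats::setNames(numeric(18), g)
  pescatarian[c("rice", "fish_seafood", "other_vegetables", "fruits",
                "oils", "condiments")] <-
    c(0.45, 0.51, 0.34, 0.23, 0.54, 0.60)
  S <- cbind(omnivorous = omnivorous, traditional = traditional,
             pescatarian = pescatarian)
  orthogonalize_preserving_norms(S)
}

# Gram-Schmidt in column order, rescaling each orthogonalised column back
# to its original Euclidean norm.
orthogonalize_preserving_norms <- function(S) {
  G <- S
  for (k in seq_len(ncol(S))[-1]) {
    for (j in seq_len(k - 1)) {
      G[, k] <- G[, k] - sum(G[, k] * G[, j]) / sum(G[, j]^2) * G[, j]
    }
  }
  for (k in seq_len(ncol(S))) {
    G[, k] <- G[, k] * sqrt(sum(S[, k]^2) / sum(G[, k]^2))
  }
  G
}

#' Default mean per-AFE group intakes (g/day)
#'
#' Baseline diet of the generator: a rice-dominated Southeast-Asian diet
#' (rice ~365 g, vegetables ~220 g, modest meat and fish, very small
#' oil/fat amounts) whose energy content works out to roughly 1.8-1.9
#' thousand kcal/day per AFE -- deliberately below the 2,000-kcal
#' standardisation base.
#'
#' @return Named length-18 numeric vector.
#' @export
default_baseline_intake <- function() {
  stats::setNames(
    c(365, 36, 32, 54, 13, 12, 2, 65, 12, 10, 109, 112, 49, 5, 3, 18, 5, 8),
    pattern_groups())
}

#' Generator configuration
#'
#' @param n_households Number of households (must be at least 10 per
#'   planted pattern).
#' @param seed Integer seed; a fixed seed makes every output bit-identical.
#' @param pattern_signatures 18 x K matrix: g/day shift of each group per
#'   unit latent score (may be negative). Defaults to three
#'   loading-shaped signatures scaled by `signature_amplitude`.
#' @param signature_amplitude Scale (g/day per unit loading) applied to
#'   the default signature shapes; ignored when `pattern_signatures` is
#'   supplied. Default 20 g, giving planted group shifts of 4-12 g/day
#'   per unit latent score.
#' @param score_sd Per-pattern latent score SDs.
#' @param baseline_intake Length-18 mean g/day per AFE per group.
#' @param noise_sd Independent g/day noise added to every group intake.
#'   Default 4.5 g (about 0.3 x the median baseline intake).
#' @param region_pattern_bias 6 x K matrix of per-region latent-score mean
#'   offsets (rows in [survey_regions()] order).
#' @param wealth_pattern_bias 5 x K matrix of per-wealth-quintile offsets.
#' @param household_size_range Integer `c(min, max)` members per household.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_households = 2000,
                             seed = 1L,
                             pattern_signatures = NULL,
                             signature_amplitude = 20,
                             score_sd = c(1, 1, 1),
                             baseline_intake = default_baseline_intake(),
                             noise_sd = 4.5,
                             region_pattern_bias = NULL,
                             wealth_pattern_bias = NULL,
                             household_size_range = c(2, 6)) {
  if (is.null(pattern_signatures)) {
    pattern_signatures <- default_signature_shapes() * signature_amplitude
    if (length(score_sd) != 3L) {
      abort("score_sd must have one entry per planted pattern",
            "dietimpact_config_error")
    }
  }
  K <- ncol(pattern_signatures)
  if (nrow(pattern_signatures) != 18L) {
    abort("pattern_signatures must have 18 rows (one per food group)",
          "dietimpact_config_error")
  }
  if (length(score_sd) != K) {
    abort("score_sd length must match the number of signatures",
          "dietimpact_config_error")
  }
  if (n_households < 10L * K) {
    abort(sprintf("n_households must be at least 10 x K = %d", 10L * K),
          "dietimpact_config_error")
  }
  if (any(baseline_intake < 0) || length(baseline_intake) != 18L) {
    abort("baseline_intake must be a non-negative length-18 vector",
          "dietimpact_config_error")
  }
  if (is.null(region_pattern_bias)) {
    region_pattern_bias <- matrix(0, 6, K)
    if (K == 3L) {
      # emulate the survey's geography: delta wealth -> omnivorous,
      # mountains -> traditional, coast -> pescatarian
      region_pattern_bias <- rbind(
        c( 0.30, -0.10, -0.10),   # Red river delta
        c(-0.20,  0.50, -0.20),   # Northern mountainous
        c( 0.10, -0.30,  0.30),   # North Central and Coastal
        c( 0.00,  0.00, -0.20),   # Central Highland
        c( 0.30, -0.30,  0.00),   # Southeast
        c( 0.00, -0.20,  0.10))   # Mekong delta
    }
  }
  if (is.null(wealth_pattern_bias)) {
    wealth_pattern_bias <- matrix(0, 5, K)
    if (K == 3L) {
      wealth_pattern_bias <- cbind(seq(-0.4, 0.4, length.out = 5),
                                   seq(0.3, -0.3, length.out = 5),
                                   seq(-0.05, 0.05, length.out = 5))
    }
  }
  if (nrow(region_pattern_bias) != 6L || ncol(region_pattern_bias) != K ||
      nrow(wealth_pattern_bias) != 5L || ncol(wealth_pattern_bias) != K) {
    abort("bias matrices must be 6 x K (region) and 5 x K (wealth)",
          "dietimpact_config_error")
  }
  if (length(household_size_range) != 2L ||
      household_size_range[1] < 1L ||
      household_size_range[2] < household_size_range[1]) {
    abort("household_size_range must be c(min, max) with 1 <= min <= max",
          "dietimpact_config_error")
  }
  structure(list(n_households = as.integer(n_households),
                 seed = as.integer(seed),
                 pattern_signatures = pattern_signatures,
                 score_sd = score_sd,
                 baseline_intake = baseline_intake,
                 noise_sd = noise_sd,
                 region_pattern_bias = region_pattern_bias,
                 wealth_pattern_bias = wealth_pattern_bias,
                 household_size_range = as.integer(household_size_range)),
            class = "generator_config")
}

# Per-group composition template: energy (kcal/100 g) and the 11 default
# nutrient densities per 100 g of raw food. Rows follow pattern_groups().
group_composition_template <- function() {
  cols <- c("energy", default_nutrients())
  m <- matrix(c(
    # energy protein vitA  vitC  B6    B12  vitE  folate iron  zinc  ca   mg
    350, 7.0,    0,   0,  0.16, 0.0, 0.1,   8,  0.8, 1.1,  10,  25,  # rice
    150, 3.0,    0,   5,  0.20, 0.0, 0.2,  20,  0.8, 0.6,  15,  30,  # non-rice staples
    150, 5.0,    2,   8,  0.30, 0.0, 1.5,  40,  1.5, 1.2,  30,  60,  # roots/tubers/nuts
    200, 19.0,  10,   0,  0.40, 2.0, 0.4,   8,  2.2, 3.5,  10,  20,  # red meat
    170, 20.0,  15,   0,  0.50, 0.4, 0.3,   7,  1.0, 1.5,  12,  22,  # white meat
    130, 18.0, 5000, 15,  0.70, 20., 0.5, 200,  6.5, 3.0,   8,  18,  # organs
    250, 14.0,   5,   0,  0.20, 0.8, 0.3,   4,  1.2, 2.0,  12,  14,  # processed meat
    120, 18.0,  30,   0,  0.30, 3.0, 0.8,  12,  1.2, 1.3,  60,  35,  # fish and seafood
    150, 13.0, 160,   0,  0.12, 1.1, 1.0,  47,  1.8, 1.3,  55,  12,  # eggs
     80, 3.5,   45,   1,  0.05, 0.45,0.1,   5,  0.05,0.4, 120,  11,  # milk and dairy
     30, 2.5,  400,  50,  0.15, 0.0, 1.0, 100,  1.8, 0.5,  90,  30,  # rich vitamin veg
     25, 1.5,   20,  20,  0.10, 0.0, 0.3,  40,  0.7, 0.3,  35,  15,  # other vegetables
     50, 0.8,   30,  35,  0.10, 0.0, 0.3,  20,  0.3, 0.1,  15,  12,  # fruits
    884, 0.0,    0,   0,  0.00, 0.0, 12.,   0,  0.0, 0.0,   0,   0,  # oils
    800, 0.5,   60,   0,  0.00, 0.1, 1.5,   0,  0.0, 0.0,   2,   1,  # fats
     50, 5.0,    0,   1,  0.10, 0.3, 0.1,   5,  1.5, 0.4,  30,  20,  # condiments
    350, 2.0,    0,   0,  0.02, 0.0, 0.1,   3,  0.5, 0.3,  15,  10,  # sweet foods
     50, 0.3,    0,   0,  0.01, 0.0, 0.0,   2,  0.05,0.02,  4,   5   # liquor/alcohol
  ), nrow = 18, byrow = TRUE, dimnames = list(pattern_groups(), cols))
  m
}

# Preparation-loss retention factors by nutrient (uniform across items;
# heat/water-sensitive vitamins lose most).
default_retention_factors <- function() {
  c(protein = 1.00, vitamin_a = 0.85, vitamin_c = 0.60, vitamin_b6 = 0.80,
    vitamin_b12 = 0.90, vitamin_e = 0.90, folate = 0.70, iron = 0.90,
    zinc = 0.90, calcium = 0.95, magnesium = 0.95)
}

# Per-group footprint factors: GHGE kg CO2-eq/kg and blue water m3/kg
# (NA for the excluded groups).
group_footprint_template <- function() {
  ghge <- c(rice = 2.7, non_rice_staples = 1.2, roots_tubers_nuts_seeds = 1.5,
            red_meat = 27, white_meat = 7, organs = 10, processed_meat = 12,
            fish_seafood = 6, eggs = 4.7, milk_dairy = 3.2,
            rich_vitamin_vegetables = 2.0, other_vegetables = 2.0,
            fruits = 1.8, oils = 3.6, fats = 10, condiments = 2.5,
            sweet_foods = 3.0, liquor_alcohol = 2.5)
  bw <- c(rice = 0.30, non_rice_staples = 0.10, roots_tubers_nuts_seeds = 0.15,
          red_meat = 0.30, white_meat = 0.20, organs = 0.25,
          processed_meat = 0.25, fish_seafood = 0.10, eggs = 0.15,
          milk_dairy = 0.08, rich_vitamin_vegetables = 0.03,
          other_vegetables = 0.03, fruits = 0.10, oils = 0.30, fats = 0.20,
          condiments = NA, sweet_foods = NA, liquor_alcohol = NA)
  list(ghge = ghge[pattern_groups()], bw = bw[pattern_groups()])
}

# Pattern group -> MDD-W group for whole groups; item-level splits (nuts
# vs roots, vitamin-A fruit) are resolved per item in the generated map.
group_to_mddw <- function() {
  c(rice = "grains_roots_tubers", non_rice_staples = "grains_roots_tubers",
    roots_tubers_nuts_seeds = "nuts_seeds",
    red_meat = "meat_poultry_fish", white_meat = "meat_poultry_fish",
    organs = "meat_poultry_fish", processed_meat = "meat_poultry_fish",
    fish_seafood = "meat_poultry_fish", eggs = "eggs", milk_dairy = "dairy",
    rich_vitamin_vegetables = "dark_green_leafy_veg",
    other_vegetables = "other_vegetables", fruits = "other_fruits",
    oils = NA, fats = NA, condiments = NA, sweet_foods = NA,
    liquor_alcohol = NA)
}

#' Generate synthetic reference tables
#'
#' Builds a food composition table, group map and footprint table with two
#' items per pattern group. Item compositions are the group template
#' scaled by 0.9/1.1 (footprints by 0.8/1.2) so grouped quantities average
#' back to the template; blue-water factors are absent for the excluded
#' groups. Fully deterministic (no RNG).
#'
#' @param config A [generator_config()] (reserved for future knobs; the
#'   tables themselves are config-independent).
#' @return List with `fct`, `groupmap`, `footprint` (the same shapes as
#'   [read_reference_tables()] returns).
#' @export
generate_reference_tables <- function(config = generator_config()) {
  groups <- pattern_groups()
  comp <- group_composition_template()
  ret <- default_retention_factors()
  fp <- group_footprint_template()
  mddw <- group_to_mddw()

  rows_fct <- list(); rows_map <- list(); rows_fp <- list()
  for (g in groups) {
    for (j in 1:2) {
      code <- sprintf("%s_%02d", g, j)
      scale_c <- c(0.9, 1.1)[j]
      scale_f <- c(0.8, 1.2)[j]
      dens <- comp[g, default_nutrients()] * scale_c
      row <- data.frame(item_code = code,
                        name = paste0(pattern_group_labels()[[g]],
                                      " item ", j),
                        energy_kcal_100g = comp[g, "energy"] * scale_c,
                        stringsAsFactors = FALSE)
      for (n in default_nutrients()) row[[paste0(n, "_per_100g")]] <- dens[[n]]
      for (n in default_nutrients()) row[[paste0("ret_", n)]] <- ret[[n]]
      rows_fct[[code]] <- row
      # second roots/nuts item plays the "root/tuber" MDD-W role
      mg <- mddw[[g]]
      if (g == "roots_tubers_nuts_seeds" && j == 2) mg <- "grains_roots_tubers"
      if (g == "fruits" && j == 2) mg <- "other_vitamin_a_fruit_veg"
      if (g == "other_vegetables" && j == 2) mg <- "other_vegetables"
      rows_map[[code]] <- data.frame(item_code = code, pattern_group = g,
                                     mddw_group = ifelse(is.na(mg), "", mg),
                                     stringsAsFactors = FALSE)
      rows_fp[[code]] <- data.frame(
        item_code = code,
        ghge_kgco2e_per_kg = unname(fp$ghge[g]) * scale_f,
        bluewater_m3_per_kg = if (is.na(fp$bw[g])) NA_real_ else
          unname(fp$bw[g]) * scale_f,
        stringsAsFactors = FALSE)
    }
  }
  fct <- do.call(rbind, rows_fct); rownames(fct) <- NULL
  groupmap <- do.call(rbind, rows_map); rownames(groupmap) <- NULL
  groupmap$mddw_group[groupmap$mddw_group == ""] <- NA_character_
  footprint <- do.call(rbind, rows_fp); rownames(footprint) <- NULL
  validate_fct(fct)
  validate_groupmap(groupmap)
  validate_footprints(footprint, groupmap)
  list(fct = fct, groupmap = groupmap, footprint = footprint)
}

#' Generate a synthetic survey population
#'
#' Draws households (region, wealth quintile, members), latent pattern
#' scores with region/wealth mean offsets, per-AFE group intakes from the
#' planted-signature model, and item-level household consumption records.
#' True latent scores are returned for recovery testing.
#'
#' @param config A [generator_config()].
#' @return List with `roster`, `consumption` (the [read_survey()] shapes)
#'   and `truth` (data.frame of household_id, afe_total, and the true
#'   latent scores `z1..zK`).
#' @export
generate_population <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_households
  K <- ncol(config$pattern_signatures)
  groups <- pattern_groups()
  hh_id <- sprintf("H%05d", seq_len(n))

  region_probs <- c(0.169, 0.244, 0.246, 0.071, 0.085, 0.185)
  region_idx <- sample.int(6L, n, replace = TRUE, prob = region_probs)
  wealth <- sample.int(5L, n, replace = TRUE)
  size <- sample(seq(config$household_size_range[1],
                     config$household_size_range[2]), n, replace = TRUE)

  # members: an adult female head plus random other members
  member_rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- size[i]
    age <- c(sample(20:55, 1L),
             if (k > 1L) sample(1:80, k - 1L, replace = TRUE))
    sex <- c("female",
             if (k > 1L) sample(sex_levels(), k - 1L, replace = TRUE))
    act <- sample(activity_levels(), k, replace = TRUE,
                  prob = c(0.25, 0.60, 0.15))
    member_rows[[i]] <- data.frame(
      household_id = hh_id[i],
      member_id = sprintf("%s_M%02d", hh_id[i], seq_len(k)),
      age = age, sex = sex, activity_level = act,
      region = survey_regions()[region_idx[i]],
      wealth_quintile = wealth[i], stringsAsFactors = FALSE)
  }
  roster <- do.call(rbind, member_rows); rownames(roster) <- NULL

  mu <- config$region_pattern_bias[region_idx, , drop = FALSE] +
    config$wealth_pattern_bias[wealth, , drop = FALSE]
  z <- mu + matrix(stats::rnorm(n * K), n, K) %*% diag(config$score_sd, K)

  intake <- matrix(rep(config$baseline_intake, each = n), n, 18,
                   dimnames = list(hh_id, groups)) +
    z %*% t(config$pattern_signatures) +
    matrix(stats::rnorm(n * 18, sd = config$noise_sd), n, 18)
  intake <- pmax(intake, 0)

  afe <- household_afe(roster)
  afe <- afe[hh_id]  # tapply sorts names; restore generation order

  # uniform disaggregation over each group's two items
  refs <- generate_reference_tables(config)
  items_by_group <- split(refs$groupmap$item_code, refs$groupmap$pattern_group)
  cons <- vector("list", 18L)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    codes <- items_by_group[[g]]
    hh_grams <- intake[, gi] * afe
    per_item <- hh_grams / length(codes)
    keep <- per_item > 0
    if (!any(keep)) next
    cons[[gi]] <- data.frame(
      household_id = rep(hh_id[keep], times = length(codes)),
      item_code = rep(codes, each = sum(keep)),
      grams_raw = rep(per_item[keep], times = length(codes)),
      stringsAsFactors = FALSE)
  }
  consumption <- do.call(rbind, cons)
  consumption <- consumption[order(match(consumption$household_id, hh_id),
                                   consumption$item_code), ]
  rownames(consumption) <- NULL

  truth <- data.frame(household_id = hh_id, afe_total = as.numeric(afe),
                      z, stringsAsFactors = FALSE)
  names(truth)[-(1:2)] <- paste0("z", seq_len(K))

  list(roster = roster, consumption = consumption, truth = truth)
}

#' Write a simulated dataset to a directory
#'
#' Writes the five pipeline input CSVs (roster, consumption, fct,
#' groupmap, footprint) plus `truth_scores.csv` with the planted latent
#' scores.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible named vector of file paths.
#' @export
simulate_survey <- function(config = generator_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- generate_population(config)
  refs <- generate_reference_tables(config)
  paths <- c(roster = file.path(out_dir, "roster.csv"),
             consumption = file.path(out_dir, "consumption.csv"),
             fct = file.path(out_dir, "fct.csv"),
             groupmap = file.path(out_dir, "groupmap.csv"),
             footprint = file.path(out_dir, "footprint.csv"),
             truth = file.path(out_dir, "truth_scores.csv"))
  write_results(pop$roster, paths["roster"])
  write_results(pop$consumption, paths["consumption"])
  write_results(refs$fct, paths["fct"])
  write_results(refs$groupmap, paths["groupmap"])
  write_results(refs$footprint, paths["footprint"])
  write_results(pop$truth, paths["truth"])
  invisible(paths)
}
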