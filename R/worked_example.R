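# A hand-written 3-household, 12-item fixture with round numbers, small
# enough that every intermediate quantity can be recomputed on paper. The
# unit tests assert the pipeline against those hand calculations; the
# methods vignette documents them.

#' Hand-checkable worked example
#'
#' Three households and twelve items with simple compositions:
#' \describe{
#'   \item{W1}{a single reference female (AFE exactly 1), so per-AFE
#'     intake equals household intake: rice 365 g, fish 80 g, spinach
#'     100 g, fish sauce 20 g.}
#'   \item{W2}{two reference females (AFE exactly 2): rice 400 g, pork
#'     100 g, eggs 60 g, banana 120 g, cabbage 30 g; per-AFE intakes are
#'     exactly half, putting cabbage exactly at the 15-g MDD-W boundary.}
#'   \item{W3}{a mixed household (reference female, adult man 35 y
#'     moderate, girl 8 y moderate): AFE = 1 + 2500/2200 + 1600/2200.}
#' }
#' Retention factors are 1 except vitamin C (0.5 on the two vegetables),
#' and footprint factors are round numbers, so GHGE/blue-water totals and
#' DDS can be verified by hand.
#'
#' @return List with `roster`, `consumption`, `fct`, `groupmap`,
#'   `footprint` data.frames.
#' @export
make_worked_example <- function() {
  nutr <- default_nutrients()
  item <- function(code, name, energy, protein = 0, vitamin_a = 0,
                   vitamin_c = 0, vitamin_b6 = 0, vitamin_b12 = 0,
                   vitamin_e = 0, folate = 0, iron = 0, zinc = 0,
                   calcium = 0, magnesium = 0, ret_vitamin_c = 1) {
    row <- data.frame(item_code = code, name = name,
                      energy_kcal_100g = energy, stringsAsFactors = FALSE)
    dens <- c(protein = protein, vitamin_a = vitamin_a,
              vitamin_c = vitamin_c, vitamin_b6 = vitamin_b6,
              vitamin_b12 = vitamin_b12, vitamin_e = vitamin_e,
              folate = folate, iron = iron, zinc = zinc,
              calcium = calcium, magnesium = magnesium)
    for (n in nutr) row[[paste0(n, "_per_100g")]] <- dens[[n]]
    for (n in nutr) row[[paste0("ret_", n)]] <-
      if (n == "vitamin_c") ret_vitamin_c else 1
    row
  }
  fct <- rbind(
    item("rice_w", "Rice (worked)", 350, protein = 7, iron = 1,
         zinc = 1, calcium = 10, magnesium = 25, vitamin_b6 = 0.15),
    item("noodle_w", "Wheat noodle (worked)", 150, protein = 4,
         folate = 20, iron = 1),
    item("peanut_w", "Peanut (worked)", 570, protein = 25, iron = 2,
         zinc = 3, magnesium = 170, vitamin_e = 8, folate = 100),
    item("pork_w", "Pork (worked)", 200, protein = 20, iron = 1,
         zinc = 2, vitamin_b12 = 0.7, vitamin_b6 = 0.5),
    item("chicken_w", "Chicken (worked)", 170, protein = 20, iron = 1,
         zinc = 1, vitamin_b12 = 0.3, vitamin_b6 = 0.5),
    item("fish_w", "Freshwater fish (worked)", 120, protein = 18,
         calcium = 50, vitamin_b12 = 2, iron = 1),
    item("egg_w", "Hen egg (worked)", 150, protein = 13, vitamin_a = 160,
         iron = 2, vitamin_b12 = 1, folate = 47, calcium = 55),
    item("milk_w", "Fresh milk (worked)", 60, protein = 3,
         calcium = 120, vitamin_b12 = 0.4, vitamin_a = 45),
    item("spinach_w", "Water spinach (worked)", 30, protein = 3,
         vitamin_a = 400, vitamin_c = 40, folate = 80, iron = 2,
         calcium = 80, ret_vitamin_c = 0.5),
    item("cabbage_w", "Cabbage (worked)", 25, protein = 1,
         vitamin_c = 30, folate = 40, ret_vitamin_c = 0.5),
    item("banana_w", "Banana (worked)", 90, protein = 1, vitamin_c = 10,
         vitamin_b6 = 0.4, magnesium = 27),
    item("fishsauce_w", "Fish sauce (worked)", 50, protein = 5, iron = 1)
  )
  groupmap <- data.frame(
    item_code = c("rice_w", "noodle_w", "peanut_w", "pork_w", "chicken_w",
                  "fish_w", "egg_w", "milk_w", "spinach_w", "cabbage_w",
                  "banana_w", "fishsauce_w"),
    pattern_group = c("rice", "non_rice_staples", "roots_tubers_nuts_seeds",
                      "red_meat", "white_meat", "fish_seafood", "eggs",
                      "milk_dairy", "rich_vitamin_vegetables",
                      "other_vegetables", "fruits", "condiments"),
    mddw_group = c("grains_roots_tubers", "grains_roots_tubers",
                   "nuts_seeds", "meat_poultry_fish", "meat_poultry_fish",
                   "meat_poultry_fish", "eggs", "dairy",
                   "dark_green_leafy_veg", "other_vegetables",
                   "other_fruits", NA),
    stringsAsFactors = FALSE)
  footprint <- data.frame(
    item_code = groupmap$item_code,
    ghge_kgco2e_per_kg = c(2.0, 1.5, 2.5, 6.0, 5.0, 4.0, 4.5, 3.0,
                           2.0, 2.0, 1.5, 2.0),
    bluewater_m3_per_kg = c(0.40, 0.10, 0.20, 0.50, 0.30, 0.10, 0.15,
                            0.10, 0.05, 0.05, 0.10, NA),
    stringsAsFactors = FALSE)
  roster <- data.frame(
    household_id = c("W1", "W2", "W2", "W3", "W3", "W3"),
    member_id = c("W1_M01", "W2_M01", "W2_M02", "W3_M01", "W3_M02",
                  "W3_M03"),
    age = c(25, 25, 28, 25, 35, 8),
    sex = c("female", "female", "female", "female", "male", "female"),
    activity_level = rep("moderate", 6),
    region = c("Red river delta", "Mekong delta", "Mekong delta",
               "Northern mountainous", "Northern mountainous",
               "Northern mountainous"),
    wealth_quintile = c(3L, 4L, 4L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
  consumption <- data.frame(
    household_id = c(rep("W1", 4), rep("W2", 5), rep("W3", 6)),
    item_code = c("rice_w", "fish_w", "spinach_w", "fishsauce_w",
                  "rice_w", "pork_w", "egg_w", "banana_w", "cabbage_w",
                  "rice_w", "noodle_w", "chicken_w", "milk_w", "peanut_w",
                  "fish_w"),
    grams_raw = c(365, 80, 100, 20,
                  400, 100, 60, 120, 30,
                  500, 100, 80, 100, 40, 50),
    stringsAsFactors = FALSE)
  list(roster = roster, consumption = consumption, fct = fct,
       groupmap = groupmap, footprint = footprint)
}
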