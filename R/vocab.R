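# Closed vocabularies shared by every stage of the pipeline.

#' Food-group vocabulary used for dietary-pattern analysis
#'
#' The 18 food groups obtained by disaggregating the 8 main groups of the
#' Vietnamese food pyramid along health and environmental-impact lines
#' (rice split from other staples, the meat/egg/fish block split six ways,
#' fats split from oils, ...). Order is fixed and meaningful: every
#' length-18 vector in the package (baseline intakes, pattern signatures,
#' group footprints) is indexed by this order.
#'
#' @return Character vector of 18 group identifiers.
#' @export
pattern_groups <- function() {
  c("rice", "non_rice_staples", "roots_tubers_nuts_seeds", "red_meat",
    "white_meat", "organs", "processed_meat", "fish_seafood", "eggs",
    "milk_dairy", "rich_vitamin_vegetables", "other_vegetables", "fruits",
    "oils", "fats", "condiments", "sweet_foods", "liquor_alcohol")
}

#' Display names for the 18 pattern food groups
#'
#' @return Named character vector mapping group identifiers to the labels
#'   used in printed tables.
#' @export
pattern_group_labels <- function() {
  c(rice = "Rice",
    non_rice_staples = "Non-rice starchy staples",
    roots_tubers_nuts_seeds = "Root, tubers, nuts, and seeds",
    red_meat = "Red meat",
    white_meat = "White meat",
    organs = "Organs",
    processed_meat = "Processed meat",
    fish_seafood = "Fish and seafood",
    eggs = "Eggs",
    milk_dairy = "Milk and dairy products",
    rich_vitamin_vegetables = "Rich vitamin vegetables",
    other_vegetables = "Other vegetables",
    fruits = "Fruits",
    oils = "Oils",
    fats = "Fats",
    condiments = "Condiments",
    sweet_foods = "Sweet foods",
    liquor_alcohol = "Liquor and alcohol")
}

#' MDD-W food-group vocabulary
#'
#' The ten food groups of the Minimum Dietary Diversity for Women
#' indicator. Items that count towards no MDD-W group (condiments, oils,
#' alcohol, ...) carry an empty `mddw_group` in the group map.
#'
#' @return Character vector of 10 group identifiers.
#' @export
mddw_groups <- function() {
  c("grains_roots_tubers", "pulses", "nuts_seeds", "dairy",
    "meat_poultry_fish", "eggs", "dark_green_leafy_veg",
    "other_vitamin_a_fruit_veg", "other_vegetables", "other_fruits")
}

#' Survey region vocabulary
#'
#' The six ecological regions used to stratify the survey population.
#'
#' @return Character vector of 6 region labels.
#' @export
survey_regions <- function() {
  c("Red river delta", "Northern mountainous", "North Central and Coastal",
    "Central Highland", "Southeast", "Mekong delta")
}

#' Food groups excluded from blue-water accounting
#'
#' Public water-footprint compilations carry no blue-water values for
#' condiments, sweet foods and alcoholic drinks, so these groups are
#' excluded from blue-water totals; their consumed mass is tracked
#' separately as `excluded_mass`.
#'
#' @return Character vector of group identifiers.
#' @export
bwu_excluded_groups <- function() {
  c("condiments", "sweet_foods", "liquor_alcohol")
}

#' Default nutrient vocabulary for adequacy scoring
#'
#' The 11 nutrients scored by default: protein plus ten micronutrients of
#' public-health concern for women of reproductive age in Southeast Asia.
#' The list is configurable (see [default_config()]); identifiers double as
#' column stems of the food-composition table
#' (`<nutrient>_per_100g`, `ret_<nutrient>`).
#'
#' @return Character vector of 11 nutrient identifiers.
#' @export
default_nutrients <- function() {
  c("protein", "vitamin_a", "vitamin_c", "vitamin_b6", "vitamin_b12",
    "vitamin_e", "folate", "iron", "zinc", "calcium", "magnesium")
}

sex_levels <- function() c("female", "male")
activity_levels <- function() c("light", "moderate", "heavy")
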