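# PA calculators are checked against independent oracles: numerical
# integration of the requirement density for the normal path, Monte
# Carlo for the log-normal iron path.

req_n <- function(ear = 10, cv = 0.1) {
  nutrient_requirement("x", "normal_ear", ear = ear, cv = cv)
}
req_fe <- nutrient_requirement("iron", "iron_full_probability",
                               median_absorbed_req = 1.46, log_sd = 0.42,
                               bioavailability = 0.05)
req_ca <- nutrient_requirement("calcium", "ai_threshold", ai = 1000)

test_that("standardisation to 2,000 kcal is linear scaling", {
  expect_equal(standardize_to_2000(10, 1000), 20)
  expect_equal(standardize_to_2000(7.3, 2000), 7.3)
  expect_error(standardize_to_2000(10, 0),
               class = "dietimpact_degenerate_diet_error")
})

test_that("pa_normal matches the integration oracle and its boundaries", {
  r <- req_n(10, 0.1)
  expect_identical(pa_normal(10, r), 0.5)
  expect_equal(pa_normal(10 + 1.645 * 1, r), 0.95, tolerance = 1e-4)
  expect_lt(pa_normal(0, r), 1e-15)

  # oracle: integrate the normal requirement density up to the intake
  oracle <- function(intake, ear, cv) {
    stats::integrate(function(t) stats::dnorm(t, ear, cv * ear),
                     -Inf, intake, rel.tol = 1e-10)$value
  }
  grid <- expand.grid(intake = c(2, 5, 8, 10, 12, 20),
                      ear = c(5, 10), cv = c(0.1, 0.25))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(pa_normal(g$intake, req_n(g$ear, g$cv)),
                 oracle(g$intake, g$ear, g$cv), tolerance = 1e-6)
  }
  # monotone in intake
  expect_true(all(diff(pa_normal(seq(0, 30, by = 0.5), r)) >= 0))
})

test_that("pa_iron matches a Monte-Carlo oracle of the skewed requirement", {
  # absorbed intake at the median requirement -> PA exactly 0.5
  expect_equal(pa_iron(1.46 / 0.05, req_fe), 0.5)
  expect_gt(pa_iron(100 * 1.46 / 0.05, req_fe), 1 - 1e-6)
  expect_identical(pa_iron(0, req_fe), 0)

  set.seed(101)
  draws <- stats::rlnorm(2e5, log(1.46), 0.42)
  for (intake in c(10, 20, 29.2, 40, 60, 100)) {
    expect_equal(pa_iron(intake, req_fe), mean(draws <= intake * 0.05),
                 tolerance = 7e-3, label = paste("iron MC at", intake))
  }
  expect_true(all(diff(pa_iron(seq(0, 200, by = 5), req_fe)) >= 0))
})

test_that("pa_ai is a sharp threshold", {
  expect_identical(pa_ai(1000, req_ca), 1)
  expect_identical(pa_ai(999, req_ca), 0)
  expect_identical(pa_ai(0, req_ca), 0)
})

test_that("MPA averages standardised PAs and flags the 0.5 cut-off", {
  w1 <- per_afe_intake("W1", worked$roster, worked$consumption, worked$fct,
                       worked$groupmap)
  res <- mpa(w1)
  # brute-force oracle: per-nutrient standardise-then-dispatch by hand
  reqs <- default_nutrient_requirements()
  pa_oracle <- vapply(default_nutrients(), function(n) {
    std <- w1$nutrient_intake[[n]] * 2000 / w1$energy
    r <- reqs[[n]]
    switch(r$kind,
           normal_ear = pnorm((std - r$ear) / (r$cv * r$ear)),
           iron_full_probability = plnorm(std * r$bioavailability,
                                          log(r$median_absorbed_req),
                                          r$log_sd),
           ai_threshold = as.numeric(std >= r$ai))
  }, numeric(1))
  expect_equal(res$pa, pa_oracle)
  expect_equal(res$mpa, mean(pa_oracle))
  expect_true(all(res$pa >= 0 & res$pa <= 1))

  # a PA vector averaging exactly to the cut-off
  reqs2 <- list(
    a = nutrient_requirement("a", "ai_threshold", ai = 1),      # -> 1
    b = nutrient_requirement("b", "ai_threshold", ai = 1e9),    # -> 0
    c = nutrient_requirement("c", "normal_ear",
                             ear = w1$nutrient_intake[["protein"]] *
                               2000 / w1$energy, cv = 0.1),     # -> 0.5
    d = nutrient_requirement("d", "normal_ear",
                             ear = w1$nutrient_intake[["iron"]] *
                               2000 / w1$energy, cv = 0.1))     # -> 0.5
  fake <- w1
  fake$nutrient_intake <- c(a = w1$energy / 2000, b = 0,
                            protein = w1$nutrient_intake[["protein"]],
                            iron = w1$nutrient_intake[["iron"]])
  names(fake$nutrient_intake)[3:4] <- c("c", "d")
  res2 <- mpa(fake, reqs2, nutrients = c("a", "b", "c", "d"))
  expect_equal(res2$mpa, 0.5)
  expect_false(res2$low_mpa)  # cut-off is strict: flag only below 0.5

  # permutation invariance over the nutrient list
  res3 <- mpa(w1, nutrients = rev(default_nutrients()))
  expect_equal(res3$mpa, res$mpa)

  # missing requirement -> config error naming the nutrient
  expect_error(mpa(w1, nutrients = c("protein", "selenium")), "selenium",
               class = "dietimpact_config_error")
})

test_that("MPA is invariant to proportional scaling of diet quantity", {
  cfg <- small_gen(n = 80, seed = 31)
  pop <- generate_population(cfg)
  refs <- generate_reference_tables(cfg)
  tab <- per_afe_table(pop$roster, pop$consumption, refs$fct, refs$groupmap)
  q1 <- diet_quality_table(tab, refs$groupmap)
  cons2 <- pop$consumption
  cons2$grams_raw <- cons2$grams_raw * 1.7
  tab2 <- per_afe_table(pop$roster, cons2, refs$fct, refs$groupmap)
  q2 <- diet_quality_table(tab2, refs$groupmap)
  expect_equal(q2$mpa, q1$mpa, tolerance = 1e-12)
})

test_that("DDS flips at exactly 15 g and is stable to sub-threshold items", {
  base <- list(household_id = "T", afe_total = 1,
               item_intake = c(rice_w = 0), group_intake = NULL,
               energy = 2000, nutrient_intake = NULL)
  class(base) <- "per_afe_intake"

  at15 <- base; at15$item_intake <- c(rice_w = 15)
  expect_identical(dds(at15, worked$groupmap)$dds, 1L)
  below <- base; below$item_intake <- c(rice_w = 14.999)
  expect_identical(dds(below, worked$groupmap)$dds, 0L)

  # >= 15 g in all ten groups -> 10, minimum diversity met
  ten_items <- c("rice_w", "peanut_w", "pork_w", "egg_w", "milk_w",
                 "spinach_w", "cabbage_w", "banana_w")
  all10 <- base
  all10$item_intake <- setNames(rep(20, length(ten_items)), ten_items)
  d <- dds(all10, worked$groupmap)
  expect_identical(d$dds, 8L)  # fixture spans 8 of the 10 groups
  # 14.9 g everywhere -> 0
  none <- base
  none$item_intake <- setNames(rep(14.9, length(ten_items)), ten_items)
  expect_identical(dds(none, worked$groupmap)$dds, 0L)

  # adding a sub-threshold item to an empty group never changes DDS;
  # adding >= 15 g changes it by at most +1
  with_small <- all10
  with_small$item_intake <- c(all10$item_intake, fish_w = 5)
  expect_identical(dds(with_small, worked$groupmap)$dds, d$dds)
  with_cond <- all10
  with_cond$item_intake <- c(all10$item_intake, fishsauce_w = 500)
  expect_identical(dds(with_cond, worked$groupmap)$dds, d$dds)
})
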