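w1 <- per_afe_intake("W1", worked$roster, worked$consumption, worked$fct,
                     worked$groupmap)

test_that("footprint linkage is plain arithmetic with strict matching", {
  # 100 g of an item with GHGE 27 kg CO2-eq/kg contributes 2.7 kg
  one <- w1
  one$item_intake <- c(pork_w = 100)
  fp <- worked$footprint
  fp$ghge_kgco2e_per_kg[fp$item_code == "pork_w"] <- 27
  r <- link_footprints(one, fp, worked$groupmap)
  expect_equal(r$ghge_total, 2.7)

  # 500 g of a condiment: zero blue water, mass tracked as excluded
  cond <- w1
  cond$item_intake <- c(fishsauce_w = 500)
  r2 <- link_footprints(cond, worked$footprint, worked$groupmap)
  expect_equal(r2$bwu_total, 0)
  expect_equal(r2$excluded_mass, 500)

  # consumed item with no GHGE factor is a linkage error, never zero
  fp_gap <- worked$footprint[worked$footprint$item_code != "rice_w", ]
  expect_error(link_footprints(w1, fp_gap, worked$groupmap), "rice_w",
               class = "dietimpact_linkage_error")
  # missing blue water outside the excluded groups is likewise an error
  fp_bad <- worked$footprint
  fp_bad$bluewater_m3_per_kg[fp_bad$item_code == "rice_w"] <- NA
  expect_error(link_footprints(w1, fp_bad, worked$groupmap), "rice_w",
               class = "dietimpact_linkage_error")
})

test_that("linearity, conservation and the exclusion rule hold", {
  cfg <- small_gen(n = 60, seed = 17)
  pop <- generate_population(cfg)
  refs <- generate_reference_tables(cfg)
  tab <- per_afe_table(pop$roster, pop$consumption, refs$fct, refs$groupmap)
  ft <- footprint_table(tab, refs$footprint, refs$groupmap)

  # conservation: group vectors sum to totals per household
  expect_equal(rowSums(ft$group_ghge), ft$ghge_total, tolerance = 1e-10)
  expect_equal(rowSums(ft$group_bwu), ft$bwu_total, tolerance = 1e-10)
  expect_true(all(ft$group_bwu[, bwu_excluded_groups()] == 0))

  # linearity: footprint of a doubled diet is twice the footprint
  cons2 <- pop$consumption
  cons2$grams_raw <- cons2$grams_raw * 2
  tab2 <- per_afe_table(pop$roster, cons2, refs$fct, refs$groupmap)
  ft2 <- footprint_table(tab2, refs$footprint, refs$groupmap)
  expect_equal(ft2$ghge_total, 2 * ft$ghge_total)
  expect_equal(ft2$bwu_total, 2 * ft$bwu_total)

  # exclusion rule: perturbing condiment/sweet/alcohol intake leaves BWU
  # untouched but moves excluded mass
  cons3 <- pop$consumption
  grp <- refs$groupmap$pattern_group[match(cons3$item_code,
                                           refs$groupmap$item_code)]
  sel <- grp %in% bwu_excluded_groups()
  cons3$grams_raw[sel] <- cons3$grams_raw[sel] * 10 + 50
  tab3 <- per_afe_table(pop$roster, cons3, refs$fct, refs$groupmap)
  ft3 <- footprint_table(tab3, refs$footprint, refs$groupmap)
  expect_equal(ft3$bwu_total, ft$bwu_total, tolerance = 1e-12)
  expect_true(all(ft3$excluded_mass > ft$excluded_mass))
})

test_that("per-2,000-kcal standardisation is per household, mean of ratios", {
  expect_equal(per_2000kcal(3.0, 1500), 4.0)
  expect_equal(per_2000kcal(5.5, 2000), 5.5)
  expect_error(per_2000kcal(1, 0), class = "dietimpact_degenerate_diet_error")

  # two-household counterexample: mean of ratios != ratio of means
  totals <- c(2, 4); energy <- c(1000, 4000)
  mean_of_ratios <- mean(per_2000kcal(totals, energy))
  ratio_of_means <- mean(totals) * 2000 / mean(energy)
  expect_false(isTRUE(all.equal(mean_of_ratios, ratio_of_means)))
  # the pipeline standardises before averaging
  cfg <- small_gen(n = 60, seed = 17)
  pop <- generate_population(cfg)
  refs <- generate_reference_tables(cfg)
  tab <- per_afe_table(pop$roster, pop$consumption, refs$fct, refs$groupmap)
  ft <- footprint_table(tab, refs$footprint, refs$groupmap)
  expect_equal(ft$ghge_per2000, ft$ghge_total * 2000 / tab$energy)
})

test_that("group contributions stack to stratum means", {
  cfg <- small_gen(n = 400, seed = 23)
  pop <- generate_population(cfg)
  refs <- generate_reference_tables(cfg)
  tab <- per_afe_table(pop$roster, pop$consumption, refs$fct, refs$groupmap)
  ft <- footprint_table(tab, refs$footprint, refs$groupmap)
  model <- fit_patterns(tab$groups, K = 3)
  contrib <- group_contribution_table(ft, model$quintile)

  # stacking: group means sum to the stratum mean total, every stratum
  for (pat in colnames(model$quintile)) {
    for (q in paste0("Q", 1:5)) {
      sel <- model$quintile[[pat]] == q
      stack <- contrib[contrib$pattern == pat & contrib$quintile == q &
                         contrib$measure == "ghge", "mean_per2000"]
      expect_equal(sum(stack), mean(ft$ghge_per2000[sel]),
                   tolerance = 1e-10)
    }
  }

  # single-household stratum equals that household's scaled group vector
  first <- ft$households[1]
  solo <- group_contribution_table(
    structure(list(households = first, energy = ft$energy[1],
                   ghge_total = ft$ghge_total[1], bwu_total = ft$bwu_total[1],
                   ghge_per2000 = ft$ghge_per2000[1],
                   bwu_per2000 = ft$bwu_per2000[1],
                   group_ghge = ft$group_ghge[1, , drop = FALSE],
                   group_bwu = ft$group_bwu[1, , drop = FALSE],
                   excluded_mass = ft$excluded_mass[1]),
              class = "footprint_table"),
    data.frame(p1 = "Q1"))
  expect_equal(solo$mean_per2000[solo$measure == "ghge" &
                                   solo$quintile == "Q1"],
               unname(ft$group_ghge[1, ] * 2000 / ft$energy[1]))

  # planted omnivorous signature: red meat contributes more in Q5 than Q1
  omn_q <- model$quintile[[match_signatures(model,
    cfg$pattern_signatures)$component[1]]]
  red <- function(q) mean((ft$group_ghge[omn_q == q, "red_meat"] *
                             2000 / ft$energy[omn_q == q]))
  expect_gt(red("Q5"), red("Q1"))

  # misaligned labels are rejected
  expect_error(group_contribution_table(ft, data.frame(p = "Q1")),
               class = "dietimpact_alignment_error")
})
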