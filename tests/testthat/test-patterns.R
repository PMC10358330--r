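# PCA behaviour is checked against closed forms and a direct-correlation
# oracle, never against another PCA implementation.

make_X <- function(n = 400, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 18), n, 18, dimnames = list(NULL, pattern_groups()))
  X
}

test_that("a perfectly correlated pair dominates the first component", {
  set.seed(2)
  n <- 1000
  base <- rnorm(n)
  X <- make_X(n, seed = 3)
  X[, 1] <- base
  X[, 2] <- 2 * base + 5   # same variable up to affine change
  m <- fit_patterns(X, K = 1)
  # closed form: a 2-variable correlated block in otherwise independent
  # noise gives lambda_1 ~= 2, loadings ~ sqrt(lambda/2) on the pair
  lambda1 <- m$eigenvalues[1]
  expect_gt(lambda1, 1.9)
  expect_equal(unname(abs(m$loadings[1, 1])), sqrt(lambda1 / 2),
               tolerance = 0.02)
  expect_equal(unname(m$loadings[1, 1]), unname(m$loadings[2, 1]),
               tolerance = 0.02)
  expect_lt(max(abs(m$loadings[3:18, 1])), 0.3)
})

test_that("independent columns give a near-identity spectrum", {
  m <- fit_patterns(make_X(2000, seed = 4), K = 3)
  expect_true(all(abs(m$eigenvalues - 1) < 0.35))
  expect_true(all(abs(m$explained_variance - 1 / 18) < 0.02))
  sr <- scree_report(m)
  expect_lt(max(sr$table$eigenvalue), sr$noise_margin)
})

test_that("loadings are variable-score correlations; spectrum is coherent", {
  cfg <- small_gen(n = 600, seed = 21)
  pop <- generate_population(cfg)
  refs <- generate_reference_tables(cfg)
  tab <- per_afe_table(pop$roster, pop$consumption, refs$fct, refs$groupmap)
  m <- fit_patterns(tab$groups, K = 3)

  # oracle: Pearson correlation between each input column and each score
  for (k in 1:3) {
    direct <- cor(tab$groups, m$scores[, k])[, 1]
    expect_equal(unname(m$loadings[, k]), unname(direct), tolerance = 1e-8)
  }
  expect_equal(sum(m$eigenvalues), 18, tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_equal(unname(colMeans(m$scores)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(m$scores, 2, sd)), rep(1, 3), tolerance = 1e-10)

  # scores invariant to per-column affine rescaling of the input
  X2 <- sweep(tab$groups, 2, seq(0.5, 9, length.out = 18), `*`)
  X2 <- sweep(X2, 2, seq(-3, 14, length.out = 18), `+`)
  m2 <- fit_patterns(X2, K = 3)
  expect_equal(m2$scores, m$scores, tolerance = 1e-8)
  expect_equal(m2$loadings, m$loadings, tolerance = 1e-8)

  # sign convention: largest-|loading| entry positive
  for (k in 1:3) {
    expect_gt(m$loadings[which.max(abs(m$loadings[, k])), k], 0)
  }
})

test_that("degenerate inputs raise informative errors", {
  X <- make_X(200)
  X[, 5] <- 3
  expect_error(fit_patterns(X), "white_meat",
               class = "dietimpact_degenerate_input_error")
  expect_error(fit_patterns(make_X(100)),
               class = "dietimpact_parameter_error")
  expect_error(fit_patterns(make_X(200), K = 19),
               class = "dietimpact_parameter_error")
})

test_that("quintile assignment balances counts and respects ties", {
  expect_identical(assign_quintiles(1:10),
                   paste0("Q", rep(1:5, each = 2)))
  # all-tied scores: stable input order fills Q1 first
  q <- assign_quintiles(rep(0, 10))
  expect_identical(q, paste0("Q", rep(1:5, each = 2)))
  # balance for n not divisible by 5
  for (n in c(7, 23, 101)) {
    set.seed(n)
    q <- assign_quintiles(rnorm(n))
    sizes <- table(q)
    expect_true(all(sizes >= floor(n / 5) & sizes <= ceiling(n / 5)))
  }
  # Q5 is highest adherence
  s <- c(5, 1, 3, 2, 4)
  expect_identical(assign_quintiles(s)[1], "Q5")
})

test_that("loading tables print the conventional x100 format", {
  m <- structure(list(loadings = matrix(c(0.47, -0.38, 0.19, rep(0, 15)),
                                        ncol = 1,
                                        dimnames = list(pattern_groups(),
                                                        "PC1"))),
                 class = "pattern_model")
  tab <- format_loading_table(m, display_threshold = 0.20)
  expect_identical(tab[1, 1], "47")
  expect_identical(tab[2, 1], "-38")
  expect_identical(tab[3, 1], "")
})

test_that("scree report flags the planted dimensionality", {
  cfg <- small_gen(n = 1500, seed = 12)
  pop <- generate_population(cfg)
  refs <- generate_reference_tables(cfg)
  tab <- per_afe_table(pop$roster, pop$consumption, refs$fct, refs$groupmap)
  sr <- scree_report(fit_patterns(tab$groups))
  expect_identical(sr$suggested_k, 3L)
  expect_equal(sr$table$cum_var[18], 1, tolerance = 1e-8)
})
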