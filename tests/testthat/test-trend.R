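test_that("quintile summaries match a brute-force groupby oracle", {
  set.seed(55)
  n <- 500
  q <- assign_quintiles(rnorm(n))
  v <- rnorm(n, mean = 10, sd = 2)

  s <- quintile_summary(v, q, "continuous", variable = "v")
  for (strat in paste0("Q", 1:5)) {
    expect_equal(s$mean[s$stratum == strat], mean(v[q == strat]))
    expect_equal(s$sd[s$stratum == strat], sd(v[q == strat]))
  }
  # total mean equals the weighted mean of stratum means
  sub <- s[s$stratum != "total", ]
  expect_equal(s$mean[s$stratum == "total"],
               sum(sub$mean * sub$n) / sum(sub$n), tolerance = 1e-10)

  # constant variable: identical means, zero SD everywhere
  s0 <- quintile_summary(rep(3.5, n), q, "continuous", variable = "c")
  expect_true(all(s0$mean == 3.5) && all(s0$sd == 0))

  # categorical: percentages sum to 100 per stratum; a uniform wealth
  # distribution shows ~20% per class in the total column
  w <- rep(1:5, each = n / 5)
  sw <- quintile_summary(w, sample(q), "categorical", variable = "wealth")
  for (strat in unique(sw$stratum)) {
    expect_equal(sum(sw$percent[sw$stratum == strat]), 100,
                 tolerance = 1e-10)
  }
  expect_equal(sw$percent[sw$stratum == "total"], rep(20, 5))

  expect_error(quintile_summary(v[-1], q, "continuous"),
               class = "dietimpact_alignment_error")
})

test_that("homogeneity test equals the hand chi-square and detects extremes", {
  # 2x5 toy table checked by hand: (n-1)/n x sum (O-E)^2/E
  q <- rep(paste0("Q", 1:5), times = c(20, 20, 20, 20, 20))
  cat_ <- c(rep(c("a", "b"), c(15, 5)), rep(c("a", "b"), c(12, 8)),
            rep(c("a", "b"), c(10, 10)), rep(c("a", "b"), c(8, 12)),
            rep(c("a", "b"), c(5, 15)))
  ht <- homogeneity_test(cat_, q)
  tab <- table(q, cat_)
  expected <- outer(rowSums(tab), colSums(tab)) / 100
  hand <- sum((tab - expected)^2 / expected) * 99 / 100
  expect_equal(ht$statistic, hand)
  expect_identical(ht$df, 4L)

  # identical distribution in every quintile: statistic 0, p 1
  ht0 <- homogeneity_test(rep(c("a", "b"), 50), rep(paste0("Q", 1:5), 20))
  expect_equal(ht0$statistic, 0, tolerance = 1e-10)
  expect_equal(ht0$p_value, 1, tolerance = 1e-10)

  # quintile perfectly determines category
  n <- 2000
  qq <- rep(paste0("Q", 1:5), each = n / 5)
  ht1 <- homogeneity_test(ifelse(qq %in% c("Q1", "Q2"), "a", "b"), qq)
  expect_lt(ht1$p_value, 1e-10)

  expect_error(homogeneity_test(rep("a", 10), rep(paste0("Q", 1:5), 2)),
               class = "dietimpact_degenerate_table_error")
})

test_that("linear trend test matches lm() and handles degeneracy", {
  q <- rep(paste0("Q", 1:5), each = 30)
  x <- as.numeric(sub("Q", "", q))
  # values exactly equal to the quintile index: slope 1, p ~ 0
  tt <- linear_trend_test(x, q)
  expect_equal(tt$slope, 1)
  set.seed(8)
  v <- 0.3 * x + rnorm(length(x))
  tt2 <- linear_trend_test(v, q)
  fit <- summary(lm(v ~ x))$coefficients  # oracle
  expect_equal(tt2$slope, fit["x", "Estimate"], tolerance = 1e-12)
  expect_equal(tt2$se, fit["x", "Std. Error"], tolerance = 1e-12)
  expect_equal(tt2$p_value, fit["x", "Pr(>|t|)"], tolerance = 1e-12)

  # constant response: flagged undefined, not a fake p-value
  tt3 <- linear_trend_test(rep(2, length(q)), q)
  expect_true(tt3$undefined)
  expect_true(is.na(tt3$p_value))

  expect_error(linear_trend_test(1:10, rep(c("Q1", "Q2"), 5)),
               class = "dietimpact_degenerate_table_error")
})

test_that("null calibration: nominal rejection rate and uniform trend p", {
  # scaled-down null simulation (the acceptance suite runs the full one)
  set.seed(99)
  n <- 400; reps <- 300
  rej_h <- 0; p_trend <- numeric(reps)
  q <- rep(paste0("Q", 1:5), each = n / 5)
  for (r in seq_len(reps)) {
    cat_ <- sample(c("a", "b"), n, replace = TRUE)
    v <- rnorm(n)
    rej_h <- rej_h + (homogeneity_test(cat_, q)$p_value < 0.05)
    p_trend[r] <- linear_trend_test(v, q)$p_value
  }
  expect_lt(abs(rej_h / reps - 0.05), 0.035)
  expect_gt(ks.test(p_trend, "punif")$p.value, 0.01)
})

test_that("quintile_report assembles summaries, p-values and flags", {
  set.seed(4)
  n <- 250
  q <- assign_quintiles(rnorm(n))
  x <- as.numeric(sub("Q", "", q))
  dat <- data.frame(strong = x + rnorm(n, sd = 0.1),
                    noise = rnorm(n),
                    cat = sample(c("u", "v"), n, replace = TRUE))
  rep_ <- quintile_report(dat, q, continuous = c("strong", "noise"),
                          categorical = "cat")
  expect_identical(unique(rep_$flag[rep_$variable == "strong"]), "ii")
  expect_true(all(rep_$p_value >= 0 & rep_$p_value <= 1))
  # BH adjustment never lowers a p-value
  rep_bh <- quintile_report(dat, q, continuous = c("strong", "noise"),
                            categorical = "cat", adjust_bh = TRUE)
  expect_true(all(rep_bh$p_value >= rep_$p_value - 1e-15))
})
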