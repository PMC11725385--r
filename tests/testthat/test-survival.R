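test_that("KM estimator matches product-limit hand values", {
  # no censoring: S steps 0.75, 0.5, 0.25, 0; median = 2
  km <- kmFit(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km@surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(kmMedian(km), 2)
  # censoring between events: S(1) = 2/3, S(3) = 0
  km2 <- kmFit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2@surv, c(2 / 3, 0))
  expect_equal(km2@time, c(1, 3))
  # all censored: S == 1 everywhere, median undefined
  km3 <- kmFit(c(5, 6, 7), c(0, 0, 0))
  expect_identical(kmMedian(km3), NA_real_)
  expect_equal(kmSurvivalAt(km3, c(0, 10)), c(1, 1))
  expect_error(kmFit(numeric(0), numeric(0)), "no survival records")
})

test_that("KM curve and median agree with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(20)
  for (i in 1:5) {
    tm <- round(rexp(40, 1 / 15), 1) + 0.1
    ev <- rbinom(40, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    km <- kmFit(tm, ev)
    sf <- summary(survival::survfit(survival::Surv(tm, ev) ~ 1))
    expect_equal(km@surv, sf$surv, tolerance = 1e-12)
    expect_equal(km@nRisk, sf$n.risk, tolerance = 1e-12)
    ref_med <- unname(stats::quantile(survival::survfit(
      survival::Surv(tm, ev) ~ 1), probs = 0.5)$quantile)
    expect_identical(is.na(kmMedian(km)), is.na(ref_med))
    if (!is.na(ref_med)) expect_equal(kmMedian(km), ref_med)
  }
})

test_that("log-rank matches hand-computed hypergeometric terms", {
  # 6 individuals, groups x/y, computable by hand
  tm <- c(2, 4, 4, 6, 8, 10)
  ev <- c(1, 1, 0, 1, 1, 0)
  g <- c("x", "y", "x", "x", "y", "y")
  lr <- logrankTest(tm, ev, g)
  # hand: event times 2, 4, 6, 8
  # t=2: n=6, n_x=3, d=1, d_x=1 -> E=0.5,  V=0.25
  # t=4: n=5, n_x=2, d=1, d_x=0 -> E=0.4,  V=0.24
  # t=6: n=3, n_x=1, d=1, d_x=1 -> E=1/3,  V=2/9
  # t=8: n=2, n_x=0, d=1, d_x=0 -> E=0,    V=0
  O <- 2; E <- 0.5 + 0.4 + 1 / 3; V <- 0.25 + 0.24 + 2 / 9
  expect_equal(lr@statistic, (O - E)^2 / V, tolerance = 1e-12)
  expect_equal(unname(lr@observed["x"]), O)
  expect_equal(unname(lr@expected["x"]), E, tolerance = 1e-12)
})

test_that("log-rank agrees with survival::survdiff and label swaps", {
  skip_if_not_installed("survival")
  set.seed(25)
  tm <- round(rexp(60, 1 / 20), 1) + 0.1
  ev <- rbinom(60, 1, 0.8)
  g <- rep(c("heat", "ambient"), each = 30)
  lr <- logrankTest(tm, ev, g)
  ref <- survival::survdiff(survival::Surv(tm, ev) ~ g)
  expect_equal(lr@statistic, ref$chisq, tolerance = 1e-10)
  # invariant to swapping group labels
  swapped <- logrankTest(tm, ev, ifelse(g == "heat", "ambient", "heat"))
  expect_equal(lr@statistic, swapped@statistic, tolerance = 1e-12)
  expect_equal(lr@pValue, swapped@pValue, tolerance = 1e-12)
})

test_that("identical groups give statistic 0 and p = 1", {
  tm <- c(1, 2, 3, 1, 2, 3)
  ev <- c(1, 1, 1, 1, 1, 1)
  lr <- logrankTest(tm, ev, rep(c("a", "b"), each = 3))
  expect_equal(lr@statistic, 0, tolerance = 1e-12)
  expect_equal(lr@pValue, 1)
  expect_error(logrankTest(tm, ev, rep("a", 6)), "exactly 2")
})

test_that("heat-vs-ambient log-rank has power at simulator defaults", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- survivalConfig(seed = 500 + s)
    rec <- simulateSurvivalRecords(cfg)
    juv <- rec[rec$stage == "juvenile", ]
    lr <- logrankTest(juv, group = "treatment")
    hits <- hits + (lr@pValue < 0.05)
  }
  expect_gte(hits, 9L)
})
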