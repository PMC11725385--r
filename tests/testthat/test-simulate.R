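test_that("community simulation is reproducible and integer-valued", {
  cfg <- communityConfig(seed = 5, nPerGroup = 5L)
  t1 <- simulateCommunityCounts(cfg)
  t2 <- simulateCommunityCounts(cfg)
  expect_identical(countMatrix(t1), countMatrix(t2))
  t3 <- simulateCommunityCounts(communityConfig(seed = 6, nPerGroup = 5L))
  expect_false(identical(countMatrix(t1), countMatrix(t3)))
  m <- countMatrix(t1)
  expect_true(all(m >= 0 & m == round(m)))
  expect_true(all(rowSums(m) > 0))
  md <- as.data.frame(SummarizedExperiment::colData(t1))
  expect_setequal(unique(md$stage), c("larva", "juvenile"))
})

test_that("heat multiplies larval background ~8-fold but leaves juveniles flat", {
  cfg <- communityConfig(seed = 31)
  design <- data.frame(stage = c("larva", "larva", "juvenile", "juvenile"),
                       treatment = c("ambient", "heat", "ambient", "heat"),
                       n = 50L)
  tab <- simulateCommunityCounts(cfg, design)
  m <- countMatrix(tab)
  md <- as.data.frame(SummarizedExperiment::colData(tab))
  bg <- cfg@background$variant
  rel_bg <- rowSums(m[, bg]) / rowSums(m)
  grp <- paste(md$stage, md$treatment)
  means <- tapply(rel_bg, grp, mean)
  ratio_larva <- means[["larva heat"]] / means[["larva ambient"]]
  expect_gt(ratio_larva, 7); expect_lt(ratio_larva, 9)
  ratio_juv <- means[["juvenile heat"]] / means[["juvenile ambient"]]
  expect_gt(ratio_juv, 0.85); expect_lt(ratio_juv, 1.15)
})

test_that("with multiplier 1 group Shannon means differ by < 2 MC SE", {
  cfg <- communityConfig(seed = 77)
  design <- data.frame(stage = "juvenile",
                       treatment = c("ambient", "heat"), n = 100L)
  tab <- simulateCommunityCounts(cfg, design)
  H <- shannonIndex(countMatrix(tab))
  md <- as.data.frame(SummarizedExperiment::colData(tab))
  h1 <- H[md$treatment == "ambient"]; h2 <- H[md$treatment == "heat"]
  se <- sqrt(var(h1) / length(h1) + var(h2) / length(h2))
  expect_lt(abs(mean(h1) - mean(h2)), 2 * se)
})

test_that("the Dirichlet concentration limit collapses onto the expectation", {
  cfg <- communityConfig(seed = 41, dirichletConcentration = 1e9,
                         librarySizeLogMean = log(1e6),
                         librarySizeLogSd = 0.01)
  tab <- simulateCommunityCounts(
    cfg, data.frame(stage = "larva", treatment = "ambient", n = 5L))
  m <- countMatrix(tab)
  rel <- m / rowSums(m)
  expected <- expectedComposition(cfg, "larva", "ambient")
  for (s in seq_len(nrow(rel)))
    expect_equal(unname(rel[s, names(expected)]), unname(expected),
                 tolerance = 5e-3)
})

test_that("dominant members above 1% are co-detected in nearly all samples", {
  detected <- c()
  for (s in 1:5) {
    cfg <- communityConfig(seed = 600 + s)
    tab <- simulateCommunityCounts(cfg)
    m <- countMatrix(tab)
    rel <- m / rowSums(m)
    mem <- names(cfg@dominantMembers)
    detected <- c(detected, apply(rel[, mem] >= 0.01, 1, all))
  }
  expect_gte(mean(detected), 0.99)
})

test_that("survival records respect the monitoring discretization", {
  cfg <- survivalConfig(seed = 3)
  rec <- simulateSurvivalRecords(cfg)
  juv <- rec[rec$stage == "juvenile", ]
  expect_true(all(juv$time_days %in% cfg@schedules$juvenile))
  # censored exactly at the last visit
  expect_true(all(juv$time_days[juv$event == 0] ==
                    max(cfg@schedules$juvenile)))
  lar <- rec[rec$stage == "larva", ]
  expect_true(all(lar$time_days %in% cfg@schedules$larva))
  # ambient median 200 d >> schedule end: mostly censored
  amb <- rec[rec$treatment == "ambient", ]
  expect_gt(mean(amb$event == 0), 0.7)
})

test_that("KM medians recover the configured exponential medians", {
  cells <- data.frame(stage = c("juvenile", "larva"),
                      treatment = "heat", median_days = c(20, 57),
                      n = 500L)
  cfg <- survivalConfig(cells = cells,
                        schedules = list(juvenile = 0:80, larva = 0:120),
                        seed = 1)
  rec <- simulateSurvivalRecords(cfg)
  mj <- kmMedian(kmFit(rec[rec$stage == "juvenile", ]))
  ml <- kmMedian(kmFit(rec[rec$stage == "larva", ]))
  expect_lte(abs(mj - 20), 3)
  expect_lte(abs(ml - 57), 6)  # ~10% closed-form check; acceptance is tighter
})

test_that("study bundles round-trip losslessly and deterministically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ccfg <- communityConfig(seed = 9, nPerGroup = 4L)
  scfg <- survivalConfig(seed = 9)
  scfg@cells$n <- 10L
  b1 <- generateStudyBundle(ccfg, scfg, d1)
  b2 <- generateStudyBundle(ccfg, scfg, d2)
  # byte-identical under the same seed
  for (f in c("counts.tsv", "metadata.tsv", "registry.json", "survival.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # round-trip through the readers
  back <- readCountTable(b1$paths$counts,
                         metadataPath = b1$paths$metadata)
  expect_identical(countMatrix(back), countMatrix(b1$table))
  reg <- readRegistry(b1$paths$registry)
  expect_identical(profileNames(reg), profileNames(b1$registry))
  surv <- readSurvivalRecords(b1$paths$survival)
  expect_equal(surv, b1$survival)
  # different seeds -> different count tables
  d3 <- withr::local_tempdir()
  b3 <- generateStudyBundle(communityConfig(seed = 10, nPerGroup = 4L),
                            scfg, d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "counts.tsv"))),
                         unname(tools::md5sum(file.path(d3, "counts.tsv")))))
})

test_that("configuration invariants are enforced", {
  expect_error(communityConfig(dominantMembers = c(C15 = 0.7, C15dq = 0.2)),
               "sum to 1")
  expect_error(communityConfig(heatMultiplierLarva = -2), "positive")
  bad_bg <- data.frame(variant = "A1", genus = "Symbiodinium",
                       baseline = 0.6)
  expect_error(communityConfig(background = bad_bg), "below dominant")
  expect_error(survivalConfig(cells = data.frame(
    stage = "larva", treatment = "heat", median_days = -1, n = 10L)),
    "medians")
  expect_error(survivalConfig(schedules = list(larva = c(5, 3, 1),
                                               juvenile = c(7, 14, 20))),
               "strictly increasing")
})
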