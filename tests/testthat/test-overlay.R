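test_that("dominant assignment follows the relative-detection rule", {
  reg <- c15Registry()
  tab <- makeTable(
    s1 = c(C15 = 50, C15dq = 30, C15dr = 20),
    s2 = c(C15 = 1000, C15dq = 2),
    extraVariants = "C_1365")
  a <- assignDominantProfile(tab, reg, detectionFraction = 0.01)
  df <- as.data.frame(a)
  # all three detected, C_1365 absent -> 3-member profile
  expect_identical(df$profile[df$sample_id == "s1"], "C15-C15dq-C15dr")
  # C15dq: 2 < 0.01 * 1002, so below detection -> dominant C15
  expect_identical(df$profile[df$sample_id == "s2"], "C15")
  expect_false(any(df$fallback))
})

test_that("samples without family members fall back to a flagged singleton", {
  reg <- c15Registry()
  tab <- makeTable(s1 = c(B1 = 5, D1 = 4),
                   s2 = c(C15 = 10),
                   extraVariants = c("C15", "C15dq"))
  a <- assignDominantProfile(tab, reg)
  df <- as.data.frame(a)
  expect_identical(df$profile[df$sample_id == "s1"], "B1")
  expect_true(df$fallback[df$sample_id == "s1"])
  expect_identical(df$profile[df$sample_id == "s2"], "C15")
})

test_that("zero-count samples are flagged unassignable", {
  reg <- c15Registry()
  tab <- makeTable(s1 = c(C15 = 10), s2 = c(C15 = 0))
  a <- assignDominantProfile(tab, reg)
  df <- as.data.frame(a)
  expect_true(is.na(df$profile[df$sample_id == "s2"]))
  expect_true(df$fallback[df$sample_id == "s2"])
})

test_that("collapse sums dominant members, retains the rest, conserves totals", {
  reg <- c15Registry()
  tab <- makeTable(
    S1 = c(C15 = 50, C15dq = 30, C15dr = 20, B1 = 5),
    S2 = c(C15 = 1000, C15dq = 2, D1 = 4),
    extraVariants = "C_1365")
  cc <- collapseToDIV(tab, reg)
  m <- countMatrix(cc)
  expect_identical(unname(m["S1", "C15-C15dq-C15dr"]), 100)
  expect_identical(unname(m["S1", "B1"]), 5)
  expect_identical(unname(m["S1", "C15"]), 0)
  expect_identical(unname(m["S2", "C15"]), 1000)
  expect_identical(unname(m["S2", "C15dq"]), 2)
  expect_identical(unname(m["S2", "D1"]), 4)
  expect_equal(rowSums(m)[c("S1", "S2")],
               rowSums(countMatrix(tab))[c("S1", "S2")])
  kinds <- columnKinds(cc)
  expect_identical(unname(kinds["C15-C15dq-C15dr"]), "background")  # 100 <= 200
  expect_identical(unname(kinds["C15"]), "DIV")
  # all-zero variant column survives, labelled background
  expect_true("C_1365" %in% colnames(m))
  expect_identical(unname(kinds["C_1365"]), "background")
})

test_that("collapse conserves per-sample totals on randomized tables", {
  reg <- defaultSimRegistry()
  for (seed in 1:30) {
    tab <- randomTable(seed)
    cc <- collapseToDIV(tab, reg)
    expect_equal(unname(rowSums(countMatrix(cc))),
                 unname(rowSums(countMatrix(tab))))
  }
})

test_that("collapsing with a singleton-only registry is the identity", {
  tab <- randomTable(99, nSamples = 6, nNoise = 3)
  vars <- variantIds(tab)
  reg <- ProfileRegistry(lapply(vars, DIVProfile))
  cc <- collapseToDIV(tab, reg)
  expect_equal(countMatrix(cc)[, vars], countMatrix(tab))
})

test_that("raising detectionFraction never lengthens a dominant profile", {
  reg <- defaultSimRegistry()
  for (seed in c(3, 17)) {
    tab <- randomTable(seed, nSamples = 8)
    lens <- sapply(c(0, 0.01, 0.05, 0.2, 0.5), function(f) {
      a <- assignDominantProfile(tab, reg, detectionFraction = f)
      vapply(a@profile, function(p)
        if (is.na(p)) 0L else length(parseProfileName(p)), integer(1))
    })
    expect_true(all(apply(lens, 1, function(x) all(diff(x) <= 0))))
  }
})

test_that("non-member columns are untouched by collapsing", {
  reg <- c15Registry()
  tab <- randomTable(7, nSamples = 10, nNoise = 5)
  cc <- collapseToDIV(tab, reg)
  noise <- grep("^X", variantIds(tab), value = TRUE)
  expect_equal(countMatrix(cc)[, noise], countMatrix(tab)[, noise])
})

test_that("collapse rejects assignments referencing unknown profiles", {
  reg <- c15Registry()
  tab <- makeTable(s1 = c(C15 = 10))
  bad <- new("DominantAssignment", sampleId = "s1", profile = "Z9-Z8",
             fallback = FALSE, lowDepth = FALSE)
  expect_error(collapseToDIV(tab, reg, bad), "unknown profile")
})

test_that("dropLowDepth removes flagged samples only when asked", {
  reg <- c15Registry()
  tab <- makeTable(deep = c(C15 = 5000), shallow = c(C15 = 50))
  cc <- collapseToDIV(tab, reg)
  expect_setequal(sampleIds(cc), c("deep", "shallow"))
  expect_true(SummarizedExperiment::colData(cc)["shallow", "lowDepth"])
  cc2 <- collapseToDIV(tab, reg, dropLowDepth = TRUE)
  expect_identical(sampleIds(cc2), "deep")
})

test_that("co-occurrence inference recovers the planted family", {
  for (seed in c(1, 2, 3)) {
    cfg <- communityConfig(seed = seed)
    tab <- simulateCommunityCounts(
      cfg, data.frame(stage = "larva", treatment = c("ambient", "heat"),
                      n = 20L))
    cand <- inferCooccurringProfiles(tab)
    target <- sort(names(cfg@dominantMembers))
    expect_true(any(vapply(cand@profiles, function(p)
      identical(sort(p@members), target), logical(1))))
  }
})

test_that("co-occurrence inference respects presence structure", {
  # never co-detected -> never merged
  m <- rbind(s1 = c(A = 900, B = 0), s2 = c(A = 900, B = 0),
             s3 = c(A = 0, B = 900), s4 = c(A = 0, B = 900),
             s5 = c(A = 900, B = 0))
  suppressWarnings(reg <- inferCooccurringProfiles(VariantCountTable(m)))
  expect_setequal(profileNames(reg), c("A", "B"))
  # identical presence vectors -> merged at any cutoff <= 1
  m2 <- rbind(s1 = c(A = 600, B = 300), s2 = c(A = 650, B = 350),
              s3 = c(A = 700, B = 290), s4 = c(A = 620, B = 310),
              s5 = c(A = 660, B = 320))
  reg2 <- inferCooccurringProfiles(VariantCountTable(m2),
                                   codetectionJaccardMin = 1)
  expect_identical(profileNames(reg2), "A-B")
})
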