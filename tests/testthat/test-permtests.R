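twoClusterDist <- function(gap = 10) {
  set.seed(1)
  pts <- rbind(matrix(rnorm(8, 0, 0.1), 4, 2),
               matrix(rnorm(8, gap, 0.1), 4, 2))
  rownames(pts) <- paste0("s", 1:8)
  dist(pts)
}

test_that("PERMANOVA pseudo-F matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(14)
  for (i in 1:5) {
    m <- matrix(rpois(120, 20) + 1, 12, 10,
                dimnames = list(paste0("s", 1:12), paste0("v", 1:10)))
    g <- factor(rep(c("a", "b", "c"), each = 4))
    d <- brayCurtis(m)
    mine <- permanovaTest(d, g, nPerm = 49, seed = i)
    ref <- vegan::adonis2(d ~ g, permutations = 49)
    expect_equal(mine@statistic, ref$F[1], tolerance = 1e-10)
  }
})

test_that("ANOSIM R matches vegan::anosim", {
  skip_if_not_installed("vegan")
  set.seed(15)
  m <- matrix(rpois(120, 20) + 1, 12, 10,
              dimnames = list(paste0("s", 1:12), paste0("v", 1:10)))
  g <- factor(rep(c("a", "b"), each = 6))
  d <- brayCurtis(m)
  mine <- anosimTest(d, g, nPerm = 49, seed = 3)
  ref <- vegan::anosim(d, g, permutations = 49)
  expect_equal(mine@statistic, unname(ref$statistic), tolerance = 1e-10)
})

test_that("exhaustive 6-sample tests match independent brute-force oracles", {
  for (seed in 1:4) {
    set.seed(seed)
    D <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
    D[lower.tri(D)] <- runif(15, 0.1, 1)
    D <- D + t(D)
    g <- factor(c("a", "a", "a", "b", "b", "b"))
    pm <- permanovaTest(as.dist(D), g, exhaustive = TRUE)
    expect_equal(pm@statistic, oraclePermanovaF(D, g), tolerance = 1e-12)
    expect_equal(pm@pValue, oracleExhaustiveP(D, g, oraclePermanovaF),
                 tolerance = 1e-12)
    an <- anosimTest(as.dist(D), g, exhaustive = TRUE)
    expect_equal(an@statistic, oracleAnosimR(D, g), tolerance = 1e-12)
    expect_equal(an@pValue, oracleExhaustiveP(D, g, oracleAnosimR),
                 tolerance = 1e-12)
  }
})

test_that("Monte-Carlo p agrees with exhaustive p within sampling error", {
  set.seed(6)
  D <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  D[lower.tri(D)] <- runif(15, 0.1, 1)
  D <- D + t(D)
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  ex <- permanovaTest(as.dist(D), g, exhaustive = TRUE)
  mc <- permanovaTest(as.dist(D), g, nPerm = 2000, seed = 8)
  expect_lt(abs(mc@pValue - ex@pValue),
            3 * sqrt(ex@pValue * (1 - ex@pValue) / 2000) + 1e-3)
})

test_that("perfectly separated clusters reach the minimal attainable p", {
  # large enough n that a random permutation essentially never recreates
  # the observed split
  set.seed(2)
  pts <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
               matrix(rnorm(20, 10, 0.1), 10, 2))
  rownames(pts) <- paste0("s", 1:20)
  d <- dist(pts)
  g <- factor(rep(c("a", "b"), each = 10))
  pm <- permanovaTest(d, g, nPerm = 999, seed = 1)
  expect_equal(pm@pValue, 1 / 1000, tolerance = 1e-12)
  an <- anosimTest(d, g, nPerm = 999, seed = 1)
  expect_equal(an@statistic, 1)  # all between > all within
})

test_that("ANOSIM R has zero expectation under random labels", {
  set.seed(44)
  D <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  g <- factor(rep(c("a", "b"), each = 6))
  labelings <- replicate(300, sample(g), simplify = FALSE)
  Rs <- vapply(labelings, function(gg)
    anosimTest(as.dist(D), gg, nPerm = 1, seed = 1)@statistic, numeric(1))
  expect_lt(abs(mean(Rs)), 3 * sd(Rs) / sqrt(300))
})

test_that("betadisper recovers direct-space centroid distances for Euclidean input", {
  set.seed(9)
  pts <- matrix(rnorm(30), 10, 3)
  rownames(pts) <- paste0("s", 1:10)
  g <- factor(rep(c("a", "b"), each = 5))
  res <- betaDispersion(dist(pts), g, nPerm = 99, seed = 2)
  # hand-computed distances to group centroids in the original space
  direct <- numeric(10)
  for (lev in levels(g)) {
    idx <- which(g == lev)
    ctr <- colMeans(pts[idx, ])
    direct[idx] <- sqrt(rowSums((pts[idx, ] - rep(ctr, each = 5))^2))
  }
  expect_equal(unname(res@extra$distances), direct, tolerance = 1e-8)
  expect_equal(res@extra$correction, 0)
})

test_that("betadisper matches vegan's centroid distances and F", {
  skip_if_not_installed("vegan")
  set.seed(10)
  pts <- matrix(rnorm(36), 12, 3)
  rownames(pts) <- paste0("s", 1:12)
  g <- factor(rep(c("a", "b", "c"), each = 4))
  d <- dist(pts)
  mine <- betaDispersion(d, g, nPerm = 99, seed = 1)
  ref <- vegan::betadisper(d, g, type = "centroid")
  expect_equal(unname(mine@extra$distances), unname(ref$distances),
               tolerance = 1e-8)
  av <- anova(ref)
  expect_equal(mine@statistic, av$`F value`[1], tolerance = 1e-8)
  expect_equal(mine@extra$parametricP, av$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("betadisper separates tight from diffuse clusters but not equal geometries", {
  set.seed(11)
  tight <- matrix(rnorm(16, sd = 0.05), 8, 2)
  diffuse <- matrix(rnorm(16, sd = 3), 8, 2)
  pts <- rbind(tight, diffuse + 20)
  rownames(pts) <- paste0("s", 1:16)
  g <- factor(rep(c("t", "d"), each = 8))
  res <- betaDispersion(dist(pts), g, nPerm = 199, seed = 5)
  expect_gt(res@statistic, 10)
  expect_lt(res@pValue, 0.05)
  # identical internal geometry: translated copy of the same cloud
  cloud <- matrix(rnorm(16), 8, 2)
  pts2 <- rbind(cloud, cloud + 50)
  rownames(pts2) <- paste0("s", 1:16)
  res2 <- betaDispersion(dist(pts2), g, nPerm = 199, seed = 5)
  expect_lt(res2@statistic, 1e-8)
  expect_gt(res2@pValue, 0.9)
})

test_that("group-size and validity checks fire", {
  d <- twoClusterDist()
  expect_error(permanovaTest(d, factor(c("a", rep("b", 7)))), "at least 2")
  expect_error(permanovaTest(d, factor(rep("a", 8))), "at least 2 groups")
})
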