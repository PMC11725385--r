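# Permutation tests on dissimilarity matrices: one-factor PERMANOVA,
# ANOSIM, and multivariate dispersion (betadisper-style).

.checkGroupsDist <- function(D, groups, min_per_group = 2L) {
  n <- nrow(D)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != n) .stopf("groups length must match the matrix")
  if (nlevels(groups) < 2L) .stopf("need at least 2 groups")
  if (any(table(groups) < min_per_group))
    .stopf("every group needs at least %d samples", min_per_group)
  groups
}

.permanovaF <- function(D2, groups) {
  n <- nrow(D2)
  k <- nlevels(groups)
  ss_total <- sum(D2[lower.tri(D2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}

#' One-factor PERMANOVA on a dissimilarity matrix
#'
#' Partitions the sum of squared dissimilarities,
#' \eqn{SS_{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2} and
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2},
#' into a pseudo-F
#' \eqn{F = \frac{SS_{between}/(k-1)}{SS_{within}/(n-k)}}, and tests it
#' by permuting the raw group labels (one-factor design only).  The
#' p-value uses the add-one convention; with `exhaustive = TRUE` all
#' distinct label arrangements are enumerated and the p-value is exact.
#'
#' @param d `dist` or symmetric dissimilarity matrix.
#' @param groups factor of group labels (each group needs >= 2
#'   samples).
#' @param nPerm number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all distinct label arrangements (small n
#'   only).
#' @return A [PermutationTestResult-class].
#' @export
permanovaTest <- function(d, groups, nPerm = 999L, seed = 1L,
                          exhaustive = FALSE) {
  D <- as.matrix(d)
  groups <- .checkGroupsDist(D, groups)
  D2 <- D^2
  obs <- .permanovaF(D2, groups)
  .permutationResult("PERMANOVA", obs, function(g) .permanovaF(D2, g),
                     groups, nPerm, seed, exhaustive)
}

.anosimR <- function(rankM, groups) {
  n <- nrow(rankM)
  within <- outer(groups, groups, "==")[lower.tri(rankM)]
  rk <- rankM[lower.tri(rankM)]
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

#' ANOSIM on a dissimilarity matrix
#'
#' Ranks all \eqn{n(n-1)/2} dissimilarities (ties averaged) and computes
#' \eqn{R = (\bar r_{between} - \bar r_{within}) / (n(n-1)/4)}; the
#' p-value is by label permutation with the add-one convention (exact
#' enumeration with `exhaustive = TRUE`).
#'
#' @inheritParams permanovaTest
#' @return A [PermutationTestResult-class].
#' @export
anosimTest <- function(d, groups, nPerm = 999L, seed = 1L,
                       exhaustive = FALSE) {
  D <- as.matrix(d)
  groups <- .checkGroupsDist(D, groups)
  rankM <- D
  rankM[lower.tri(D)] <- rank(D[lower.tri(D)])
  rankM[upper.tri(D)] <- t(rankM)[upper.tri(D)]
  obs <- .anosimR(rankM, groups)
  .permutationResult("ANOSIM", obs, function(g) .anosimR(rankM, g),
                     groups, nPerm, seed, exhaustive)
}

.permutationResult <- function(method, obs, statFun, groups, nPerm, seed,
                               exhaustive, extra = list()) {
  if (exhaustive) {
    perms <- .multisetPermutations(as.character(groups))
    stats <- apply(perms, 1L, function(g)
      statFun(factor(g, levels = levels(groups))))
    p <- mean(stats >= obs - 1e-12)
    return(new("PermutationTestResult", method = method, statistic = obs,
               pValue = p, nPerm = 0L, seed = as.integer(seed),
               exhaustive = TRUE, extra = extra))
  }
  stats <- .withStreamSeed(seed, 3L,
    vapply(seq_len(nPerm), function(i) statFun(sample(groups)),
           numeric(1)))
  new("PermutationTestResult", method = method, statistic = obs,
      pValue = .permPValue(obs, stats), nPerm = as.integer(nPerm),
      seed = as.integer(seed), exhaustive = FALSE, extra = extra)
}

# Principal-coordinates embedding with Lingoes-style additive correction
# for negative eigenvalues: if the Gower-centred matrix has a negative
# eigenvalue -c, add 2c to all off-diagonal squared dissimilarities and
# re-embed, which makes the geometry Euclidean while preserving the
# ordering of distances.
.pcoaEmbed <- function(D, tol = 1e-8) {
  n <- nrow(D)
  gower <- function(D2) {
    J <- diag(n) - matrix(1 / n, n, n)
    -0.5 * J %*% D2 %*% J
  }
  G <- gower(D^2)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  correction <- 0
  if (min(e$values) < -tol * max(abs(e$values))) {
    correction <- -min(e$values)
    D2c <- D^2 + 2 * correction
    diag(D2c) <- 0
    G <- gower(D2c)
    e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  }
  keep <- e$values > tol * max(abs(e$values), 1)
  pts <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), nrow = sum(keep))
  rownames(pts) <- rownames(D)
  list(points = pts, correction = correction)
}

#' Multivariate dispersion test (betadisper-style)
#'
#' Embeds the dissimilarity matrix by principal coordinates (with a
#' Lingoes-style additive correction when negative eigenvalues arise),
#' computes each sample's Euclidean distance to its group centroid
#' (means, not spatial medians) in the embedded space, and tests group
#' differences in those distances with a one-way ANOVA F statistic.
#' Both the parametric p (F distribution) and a permutation p obtained
#' by shuffling the group labels of the centroid distances are
#' reported; the permutation p is the primary `pValue`.
#'
#' @inheritParams permanovaTest
#' @return A [PermutationTestResult-class]; `extra` holds the
#'   per-sample centroid `distances`, the `parametricP`, and the
#'   applied eigenvalue `correction`.
#' @export
betaDispersion <- function(d, groups, nPerm = 999L, seed = 1L) {
  D <- as.matrix(d)
  groups <- .checkGroupsDist(D, groups)
  emb <- .pcoaEmbed(D)
  pts <- emb$points
  n <- nrow(pts); k <- nlevels(groups)
  distToCentroid <- numeric(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    centroid <- colMeans(pts[idx, , drop = FALSE])
    distToCentroid[idx] <- sqrt(rowSums(
      sweep(pts[idx, , drop = FALSE], 2L, centroid)^2))
  }
  names(distToCentroid) <- rownames(D)

  anovaF <- function(z, g) {
    gm <- tapply(z, g, mean)
    ssb <- sum(table(g) * (gm - mean(z))^2)
    ssw <- sum((z - gm[g])^2)
    if (ssw <= 1e-300) return(if (ssb <= 1e-300) 0 else Inf)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  obs <- anovaF(distToCentroid, groups)
  parametricP <- stats::pf(obs, k - 1, n - k, lower.tail = FALSE)
  perm <- .withStreamSeed(seed, 4L,
    vapply(seq_len(nPerm), function(i)
      anovaF(distToCentroid, sample(groups)), numeric(1)))
  new("PermutationTestResult", method = "betadisper",
      statistic = obs, pValue = .permPValue(obs, perm),
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      exhaustive = FALSE,
      extra = list(distances = distToCentroid, parametricP = parametricP,
                   correction = emb$correction))
}
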