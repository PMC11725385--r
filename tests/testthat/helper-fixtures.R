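# Shared fixtures and independent oracles, all built in code.

# The four nested C15-family profile names used throughout.
c15ProfileNames <- function() {
  c("C15", "C15-C15dq", "C15-C15dq-C15dr", "C15-C15dq-C15dr-C_1365")
}

c15Registry <- function(...) buildRegistry(c15ProfileNames(), ...)

# A count table from explicit per-sample named count vectors.
makeTable <- function(..., extraVariants = character(0)) {
  samples <- list(...)
  vars <- unique(c(unlist(lapply(samples, names)), extraVariants))
  m <- matrix(0, length(samples), length(vars),
              dimnames = list(names(samples), vars))
  for (s in names(samples)) m[s, names(samples[[s]])] <- samples[[s]]
  VariantCountTable(m)
}

# Random table with a planted nested family plus noise variants.
randomTable <- function(seed, nSamples = NULL, nNoise = NULL) {
  set.seed(seed)
  if (is.null(nSamples)) nSamples <- sample(2:12, 1)
  if (is.null(nNoise)) nNoise <- sample(1:6, 1)
  members <- c("C15", "C15dq", "C15dr", "C_1365")
  vars <- c(members, paste0("X", seq_len(nNoise)))
  m <- matrix(rpois(nSamples * length(vars), lambda = 30),
              nSamples, length(vars),
              dimnames = list(paste0("s", seq_len(nSamples)), vars))
  m[, "C15"] <- m[, "C15"] + rpois(nSamples, 500)
  VariantCountTable(m)
}

# Independent PERMANOVA oracle: explicit double loops, no shared code
# with the implementation.
oraclePermanovaF <- function(D, groups) {
  n <- nrow(D)
  groups <- as.character(groups)
  k <- length(unique(groups))
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + D[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    acc <- 0
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + D[idx[a], idx[b]]^2
    ssw <- ssw + acc / length(idx)
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

# Independent ANOSIM oracle.
oracleAnosimR <- function(D, groups) {
  n <- nrow(D)
  groups <- as.character(groups)
  dvals <- c(); within <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dvals <- c(dvals, D[i, j])
    within <- c(within, groups[i] == groups[j])
  }
  rk <- rank(dvals)
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

# Exhaustive-permutation p-value for a statistic function over all
# distinct two-group label arrangements (positions of group "a").
oracleExhaustiveP <- function(D, groups, statFun) {
  groups <- as.character(groups)
  n <- length(groups)
  aLab <- unique(groups)[1]
  nA <- sum(groups == aLab)
  obs <- statFun(D, groups)
  combos <- utils::combn(n, nA)
  stats <- apply(combos, 2, function(idx) {
    g <- rep(unique(groups)[2], n)
    g[idx] <- aLab
    statFun(D, g)
  })
  mean(stats >= obs - 1e-12)
}

# Registry covering the C15 family plus the simulator's background
# singletons.
defaultSimRegistry <- function(cfg = communityConfig()) {
  generateProfileLibrary(names(cfg@dominantMembers),
                         as.numeric(cfg@dominantMembers),
                         background = cfg@background$variant)
}
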