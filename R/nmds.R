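# Non-metric multidimensional scaling: Kruskal stress-1 minimised by
# alternating monotone regression (pool-adjacent-violators, ties averaged)
# and Guttman-transform majorization steps.

# Weighted pool-adjacent-violators: least-squares non-decreasing fit.
.pava <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx <- rep(1L, n)  # block bookkeeping
  # stack-based PAVA
  vals <- numeric(n); wts <- numeric(n); sizes <- integer(n); top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    vals[top] <- y[i]; wts[top] <- w[i]; sizes[top] <- 1L
    while (top > 1L && vals[top - 1L] > vals[top]) {
      wsum <- wts[top - 1L] + wts[top]
      vals[top - 1L] <- (vals[top - 1L] * wts[top - 1L] +
                           vals[top] * wts[top]) / wsum
      wts[top - 1L] <- wsum
      sizes[top - 1L] <- sizes[top - 1L] + sizes[top]
      top <- top - 1L
    }
  }
  rep(vals[seq_len(top)], times = sizes[seq_len(top)])
}

# Monotone disparities for configuration distances dvec given the tie
# structure of the input dissimilarities (secondary treatment: pairs with
# tied input dissimilarity share one fitted value = their mean).
.monotoneDisparities <- function(dvec, tie_block, block_sizes) {
  block_means <- as.numeric(rowsum(dvec, tie_block)) / block_sizes
  fitted <- .pava(block_means, block_sizes)
  fitted[tie_block]
}

.stress1 <- function(dvec, dhat) {
  denom <- sum(dvec^2)
  if (denom <= 0) return(0)
  sqrt(sum((dvec - dhat)^2) / denom)
}

#' Kruskal stress-1 of a configuration
#'
#' Evaluates stress-1 of arbitrary coordinates against a dissimilarity
#' matrix, fitting the optimal monotone disparities (ties averaged).
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @param points numeric samples x k coordinate matrix.
#' @return Stress-1 in `[0, 1]`.
#' @export
nmdsStress <- function(d, points) {
  D <- as.matrix(d)
  Dvec <- D[lower.tri(D)]
  o <- order(Dvec)
  tie_block_sorted <- cumsum(!duplicated(Dvec[o]))
  tie_block <- integer(length(Dvec)); tie_block[o] <- tie_block_sorted
  block_sizes <- tabulate(tie_block)
  dX <- as.matrix(stats::dist(points))
  dvec <- dX[lower.tri(dX)]
  dhat <- .monotoneDisparities(dvec, tie_block, block_sizes)
  .stress1(dvec, dhat)
}

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1 by alternating (i) monotone regression of
#' configuration distances on the rank order of the input
#' dissimilarities (pool-adjacent-violators; tied dissimilarities share
#' an averaged disparity) and (ii) a Guttman-transform majorization
#' update of the coordinates.  Stress is monitored every iteration and
#' the recorded trajectory is non-increasing: the loop stops at the
#' first non-improvement and keeps the best configuration.  The best of
#' `nRestarts` starts is returned — the first seeded from classical
#' PCoA (`cmdscale`), the rest from random Gaussian configurations —
#' so the final stress never exceeds the stress of the PCoA embedding.
#'
#' @param d a `dist` or symmetric dissimilarity matrix with zero
#'   diagonal and finite entries.
#' @param k embedding dimension (default 2; must be < number of
#'   samples).
#' @param nRestarts number of starts (default 20).
#' @param maxIter maximum majorization iterations per start (default
#'   300).
#' @param tol convergence tolerance on the stress decrease (default
#'   1e-6).
#' @param seed RNG seed for the random restarts.
#' @return An [OrdinationResult-class].
#' @export
nmdsOrdination <- function(d, k = 2L, nRestarts = 20L, maxIter = 300L,
                           tol = 1e-6, seed = 1L) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (any(!is.finite(D))) .stopf("non-finite dissimilarities")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
    .stopf("d must be symmetric with zero diagonal")
  if (k >= n) .stopf("k must be smaller than the number of samples")
  Dvec <- D[lower.tri(D)]
  if (all(Dvec == 0)) {
    pts <- matrix(0, n, k, dimnames = list(rownames(D), NULL))
    return(new("OrdinationResult", points = pts, stress = 0,
               nRestarts = as.integer(nRestarts), converged = TRUE,
               trace = 0))
  }
  o <- order(Dvec)
  tie_block_sorted <- cumsum(!duplicated(Dvec[o]))
  tie_block <- integer(length(Dvec)); tie_block[o] <- tie_block_sorted
  block_sizes <- tabulate(tie_block)
  lower <- lower.tri(D)

  runStart <- function(X) {
    X <- scale(X, center = TRUE, scale = FALSE)
    trace <- numeric(0)
    bestX <- X; bestStress <- Inf
    for (it in seq_len(maxIter)) {
      dX <- as.matrix(stats::dist(X))
      dvec <- dX[lower]
      dhat <- .monotoneDisparities(dvec, tie_block, block_sizes)
      s <- .stress1(dvec, dhat)
      if (s >= bestStress - 1e-15) {         # no further improvement
        return(list(points = bestX, stress = bestStress, trace = trace,
                    converged = TRUE))
      }
      bestX <- X; bestStress <- s
      trace <- c(trace, s)
      if (it > 1L && (trace[length(trace) - 1L] - s) < tol)
        return(list(points = bestX, stress = bestStress, trace = trace,
                    converged = TRUE))
      # Guttman transform with the current disparities
      Dhat <- matrix(0, n, n); Dhat[lower] <- dhat
      Dhat <- Dhat + t(Dhat)
      ratio <- ifelse(dX > 0, Dhat / dX, 0)
      B <- -ratio
      diag(B) <- -rowSums(B)
      X <- (B %*% X) / n
    }
    list(points = bestX, stress = bestStress, trace = trace,
         converged = FALSE)
  }

  old_rng <- if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_rng))
    assign(".Random.seed", old_rng, envir = globalenv()))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    X0 <- if (r == 1L) {
      p0 <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = k))
      if (ncol(p0) < k)  # degenerate PCoA: pad with tiny jitter
        p0 <- cbind(p0, matrix(stats::rnorm(n * (k - ncol(p0)), sd = 1e-4),
                               n))
      p0
    } else {
      set.seed(.streamSeed(seed, 100L + r))
      matrix(stats::rnorm(n * k), n, k)
    }
    res <- runStart(X0)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  pts <- best$points
  dimnames(pts) <- list(rownames(D), paste0("NMDS", seq_len(k)))
  new("OrdinationResult", points = pts,
      stress = min(max(best$stress, 0), 1),
      nRestarts = as.integer(nRestarts),
      converged = best$converged, trace = best$trace)
}
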