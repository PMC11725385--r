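# Internal helpers shared across modules.

# Derive a reproducible substream seed from a single user-facing seed.
# Streams: 1 = community counts, 2 = survival, 3+ = restarts/permutations.
# Kept strictly below 2^31 - 1 so set.seed() accepts it on all platforms.
.streamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * as.numeric(stream)) %%
               2147483629)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.checkScalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    .stopf("'%s' must be > 0", name)
  invisible(x)
}

# Coerce the various count containers to a plain samples-by-columns matrix.
.asSampleMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    m <- t(SummarizedExperiment::assay(x, "counts"))
  } else if (is.matrix(x)) {
    m <- x
  } else if (is.data.frame(x)) {
    m <- as.matrix(x)
  } else {
    .stopf("cannot interpret object of class '%s' as a count matrix",
           class(x)[1L])
  }
  storage.mode(m) <- "double"
  m
}

# All distinct orderings of a label vector (multiset permutations), as a
# matrix with one ordering per row.  Guarded for use in exhaustive
# permutation tests on small n only.
.multisetPermutations <- function(labels, max_n = 100000L) {
  labels <- as.character(labels)
  counts <- table(labels)
  total <- factorial(length(labels)) / prod(factorial(counts))
  if (total > max_n)
    .stopf("exhaustive enumeration would need %.0f arrangements (limit %d)",
           total, max_n)
  nm <- names(counts)
  recurse <- function(remaining) {
    if (sum(remaining) == 0L) return(list(character(0)))
    out <- list()
    for (k in seq_along(nm)) {
      if (remaining[k] == 0L) next
      rem <- remaining
      rem[k] <- rem[k] - 1L
      for (tail in recurse(rem)) out[[length(out) + 1L]] <- c(nm[k], tail)
    }
    out
  }
  perms <- recurse(as.integer(counts))
  do.call(rbind, perms)
}

# Evaluate expr with the RNG seeded from a substream, restoring the
# caller's RNG state afterwards so library calls never clobber user code.
.withStreamSeed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(.streamSeed(seed, stream))
  expr
}

# Permutation p-value with the add-one convention.
.permPValue <- function(observed, permuted) {
  (sum(permuted >= observed - 1e-12) + 1) / (length(permuted) + 1)
}
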