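# User-facing constructors and accessors.

#' Construct a DIV profile
#'
#' @param members ordered character vector of member variant names (no
#'   `-` characters; underscores allowed).
#' @return A [DIVProfile-class] object whose name is the members joined
#'   by `-`.
#' @examples
#' DIVProfile(c("C15", "C15dq"))
#' @export
DIVProfile <- function(members) {
  members <- as.character(members)
  new("DIVProfile", name = paste(members, collapse = "-"), members = members)
}

#' Construct a profile registry
#'
#' @param profiles list of [DIVProfile-class] objects.
#' @param backgroundReadThreshold dataset-wide column total (reads) at or
#'   below which a column is labelled background (default 200).
#' @param lowDepthThreshold per-sample read total below which the sample
#'   is flagged low-depth (default 1000).
#' @return A [ProfileRegistry-class].
#' @export
ProfileRegistry <- function(profiles = list(),
                            backgroundReadThreshold = 200,
                            lowDepthThreshold = 1000) {
  if (length(profiles) == 0L)
    warning("registry contains no profiles")
  new("ProfileRegistry", profiles = profiles,
      backgroundReadThreshold = as.numeric(backgroundReadThreshold),
      lowDepthThreshold = as.numeric(lowDepthThreshold))
}

#' Construct a variant count table
#'
#' @param counts integer matrix of read counts, samples in rows and
#'   sequence variants in columns (the on-disk orientation); row and
#'   column names are required and must be unique.
#' @param sampleData optional data.frame of per-sample metadata (stage,
#'   treatment, family, timepoint), rows matching `rownames(counts)`.
#' @return A [VariantCountTable-class] (stored variants x samples,
#'   Bioconductor orientation).
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 7L), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("C15", "A1")))
#' VariantCountTable(m)
#' @export
VariantCountTable <- function(counts, sampleData = NULL) {
  m <- as.matrix(counts)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    .stopf("counts must have sample rownames and variant colnames")
  storage.mode(m) <- "double"
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = rownames(m))
  } else {
    sd <- as.data.frame(sampleData)
    if (!is.null(rownames(sd)) && !all(rownames(sd) == as.character(seq_len(nrow(sd))))) {
      sd <- sd[rownames(m), , drop = FALSE]
    } else if ("sample_id" %in% names(sd)) {
      rownames(sd) <- sd$sample_id
      sd <- sd[rownames(m), setdiff(names(sd), "sample_id"), drop = FALSE]
    }
    DataFrame(sd, row.names = rownames(m))
  }
  new("VariantCountTable",
      SummarizedExperiment(assays = list(counts = t(m)), colData = cd))
}

#' @describeIn VariantCountTable Sample identifiers.
#' @param x a count table.
#' @export
sampleIds <- function(x) colnames(SummarizedExperiment::assay(x, "counts"))

#' @describeIn VariantCountTable Variant (or collapsed column) identifiers.
#' @export
variantIds <- function(x) rownames(SummarizedExperiment::assay(x, "counts"))

#' @describeIn VariantCountTable Count matrix with samples in rows (the
#'   analysis/file orientation).
#' @export
countMatrix <- function(x) t(SummarizedExperiment::assay(x, "counts"))

#' Column kinds of a collapsed table
#'
#' @param x a [CollapsedCountTable-class].
#' @return Named character vector, one of `"DIV"`, `"variant"`,
#'   `"background"` per column.
#' @export
columnKinds <- function(x) {
  k <- rowData(x)$kind
  names(k) <- variantIds(x)
  k
}

#' Profile names in a registry
#' @param registry a [ProfileRegistry-class].
#' @export
profileNames <- function(registry) {
  vapply(registry@profiles, function(p) p@name, character(1))
}

#' Members of a registered profile
#' @param registry a [ProfileRegistry-class].
#' @param name profile name.
#' @export
profileMembers <- function(registry, name) {
  i <- match(name, profileNames(registry))
  if (is.na(i)) .stopf("no profile named '%s' in registry", name)
  registry@profiles[[i]]@members
}

#' @describeIn kmFit KM median survival time (`NA` if S(t) never reaches
#'   0.5).
#' @param curve a [KMCurve-class].
#' @export
kmMedian <- function(curve) curve@median

#' Turn a dominant assignment into a data.frame
#' @param x a [DominantAssignment-class].
#' @param ... unused.
#' @export
as.data.frame.DominantAssignment <- function(x, ...) {
  data.frame(sample_id = x@sampleId, profile = x@profile,
             fallback = x@fallback, low_depth = x@lowDepth,
             stringsAsFactors = FALSE)
}

# ----------------------------- show methods ------------------------------

setMethod("show", "DIVProfile", function(object) {
  cat("DIVProfile:", object@name, sprintf("(%d members)\n",
      length(object@members)))
})

setMethod("show", "ProfileRegistry", function(object) {
  cat(sprintf("ProfileRegistry with %d profiles\n", length(object@profiles)))
  nm <- profileNames(object)
  if (length(nm)) cat("  ", paste(utils::head(nm, 8), collapse = ", "),
                      if (length(nm) > 8) "..." else "", "\n")
  cat(sprintf("  background read threshold: %g; low-depth threshold: %g\n",
              object@backgroundReadThreshold, object@lowDepthThreshold))
})

setMethod("show", "DominantAssignment", function(object) {
  cat(sprintf("DominantAssignment for %d samples (%d fallback, %d low-depth)\n",
              length(object@sampleId), sum(object@fallback),
              sum(object@lowDepth)))
  tab <- sort(table(object@profile), decreasing = TRUE)
  cat("  profiles:", paste(sprintf("%s (%d)", names(utils::head(tab, 5)),
                                   utils::head(tab, 5)), collapse = ", "), "\n")
})

setMethod("show", "BetaRegressionFit", function(object) {
  cat("Beta regression fit (logit mean link)\n")
  print(round(rbind(estimate = object@coefficients, se = object@se), 4))
  cat(sprintf("  phi = %.3f; logLik = %.3f; converged: %s\n",
              object@phi, object@logLik, object@converged))
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("NMDS ordination: %d samples, %d dimensions, stress-1 = %.4f\n",
              nrow(object@points), ncol(object@points), object@stress))
  cat(sprintf("  best of %d restarts; converged: %s\n",
              object@nRestarts, object@converged))
})

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%s)\n", object@method,
              object@statistic, object@pValue,
              if (object@exhaustive) "exhaustive"
              else sprintf("%d permutations", object@nPerm)))
})

setMethod("show", "KMCurve", function(object) {
  cat(sprintf("Kaplan-Meier curve: %d individuals, %d events, median = %s\n",
              object@nTotal, object@nEvents,
              if (is.na(object@median)) "not reached"
              else format(object@median)))
})

setMethod("show", "LogrankResult", function(object) {
  cat(sprintf("Log-rank test: chisq = %.4f (1 df), p = %.4g\n",
              object@statistic, object@pValue))
  if (!is.na(object@permPValue))
    cat(sprintf("  permutation p = %.4g\n", object@permPValue))
})

setMethod("show", "CommunityConfig", function(object) {
  cat("CommunityConfig\n")
  cat("  dominant members:",
      paste(sprintf("%s=%.2f", names(object@dominantMembers),
                    object@dominantMembers), collapse = ", "), "\n")
  cat(sprintf("  background total %.3f over %d variants; heat multipliers larva %g / juvenile %g\n",
              sum(object@background$baseline), nrow(object@background),
              object@heatMultiplierLarva, object@heatMultiplierJuvenile))
  cat(sprintf("  Dirichlet concentration %g; library ~ lognormal(%.2f, %.2f); seed %d\n",
              object@dirichletConcentration, object@librarySizeLogMean,
              object@librarySizeLogSd, object@seed))
})

setMethod("show", "SurvivalConfig", function(object) {
  cat("SurvivalConfig\n")
  print(object@cells, row.names = FALSE)
  for (nm in names(object@schedules))
    cat(sprintf("  %s schedule: %d visits, days %g-%g\n", nm,
                length(object@schedules[[nm]]), min(object@schedules[[nm]]),
                max(object@schedules[[nm]])))
})
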