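#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData `rowData<-` `colData<-` assayNames
NULL

# -------------------------------------------------------------------------
# DIV profiles and registries
# -------------------------------------------------------------------------

#' DIVProfile: a named, ordered set of co-occurring ITS2 sequence variants
#'
#' A DIV ("defining intragenomic variant") profile names a set of ITS2
#' sequence variants that reside together in one symbiont genome and
#' therefore co-occur across samples.  The profile name is its members
#' joined by `-` (variant names themselves never contain `-`; underscores
#' are allowed, e.g. `C_1365`).
#'
#' @slot name dash-delimited profile name.
#' @slot members ordered character vector of member variant names.
#' @exportClass DIVProfile
setClass("DIVProfile",
         slots = c(name = "character", members = "character"))

setValidity("DIVProfile", function(object) {
  msg <- character(0)
  if (length(object@members) == 0L)
    msg <- c(msg, "profile must have at least one member")
  if (any(!nzchar(object@members)))
    msg <- c(msg, "member names must be nonempty")
  if (anyDuplicated(object@members))
    msg <- c(msg, "member names must be unique")
  if (any(grepl("-", object@members, fixed = TRUE)))
    msg <- c(msg, "member names must not contain '-'")
  if (length(object@name) != 1L ||
      !identical(object@name, paste(object@members, collapse = "-")))
    msg <- c(msg, "name must equal members joined by '-'")
  if (length(msg)) msg else TRUE
})

#' ProfileRegistry: the set of collapsible DIV profiles plus thresholds
#'
#' Holds the DIV profiles recognised for a dataset together with the two
#' read-count thresholds used downstream: columns whose dataset-wide total
#' is at or below `backgroundReadThreshold` reads are labelled background
#' (default 200, the threshold at which SymPortal would have discarded
#' them; here they are labelled, never deleted), and samples with fewer
#' than `lowDepthThreshold` total reads (default 1000) are flagged
#' low-depth.
#'
#' @slot profiles list of [DIVProfile-class] objects with unique names.
#' @slot backgroundReadThreshold integer reads, dataset-wide column total.
#' @slot lowDepthThreshold integer reads per sample.
#' @exportClass ProfileRegistry
setClass("ProfileRegistry",
         slots = c(profiles = "list",
                   backgroundReadThreshold = "numeric",
                   lowDepthThreshold = "numeric"))

setValidity("ProfileRegistry", function(object) {
  msg <- character(0)
  ok <- vapply(object@profiles, function(p) is(p, "DIVProfile"), logical(1))
  if (!all(ok)) msg <- c(msg, "profiles must all be DIVProfile objects")
  nm <- vapply(object@profiles, function(p) p@name, character(1))
  if (anyDuplicated(nm)) msg <- c(msg, "profile names must be unique")
  for (thr in c("backgroundReadThreshold", "lowDepthThreshold")) {
    v <- slot(object, thr)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("%s must be a single number >= 0", thr))
  }
  if (length(msg)) msg else TRUE
})

# -------------------------------------------------------------------------
# Count tables (SummarizedExperiment-backed; variants in rows, samples in
# columns, matching Bioconductor orientation.  The on-disk TSV orientation
# is samples-as-rows; readers/writers transpose.)
# -------------------------------------------------------------------------

#' VariantCountTable: samples x sequence-variant read counts
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single
#' integer-valued `counts` assay (variants in rows, samples in columns).
#' Sample metadata (stage, treatment, family, timepoint) lives in
#' `colData`.
#'
#' @exportClass VariantCountTable
setClass("VariantCountTable", contains = "SummarizedExperiment")

.validCounts <- function(object, need_kind = FALSE) {
  msg <- character(0)
  if (!"counts" %in% assayNames(object))
    return("must contain a 'counts' assay")
  m <- assay(object, "counts")
  if (nrow(m) < 1L || ncol(m) < 1L)
    msg <- c(msg, "need at least one variant and one sample")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must carry variant and sample names")
  else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate variant ids")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate sample ids")
  }
  if (any(!is.finite(m)) || any(m < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  else if (any(abs(m - round(m)) > 1e-8))
    msg <- c(msg, "counts must be integer-valued")
  if (need_kind) {
    kind <- rowData(object)$kind
    if (is.null(kind) || !all(kind %in% c("DIV", "variant", "background")))
      msg <- c(msg, "rowData$kind must be one of DIV/variant/background")
  }
  if (length(msg)) msg else TRUE
}

setValidity("VariantCountTable", function(object) .validCounts(object))

#' CollapsedCountTable: counts after the DIV overlay
#'
#' Result of [collapseToDIV()]: columns (rows of the assay) are a mix of
#' DIV profile columns and retained individual variant columns.
#' `rowData$kind` labels each column as `"DIV"`, `"variant"`, or
#' `"background"` (dataset-wide total at or below the background read
#' threshold).  `colData$dominantProfile` records each sample's assigned
#' dominant profile.  Per-sample totals are conserved exactly relative to
#' the input [VariantCountTable-class].
#'
#' @exportClass CollapsedCountTable
setClass("CollapsedCountTable", contains = "SummarizedExperiment")

setValidity("CollapsedCountTable", function(object) {
  msg <- .validCounts(object, need_kind = TRUE)
  if (isTRUE(msg)) msg <- character(0)
  if (is.null(colData(object)$dominantProfile))
    msg <- c(msg, "colData$dominantProfile is required")
  if (length(msg)) msg else TRUE
})

#' DominantAssignment: per-sample dominant DIV profile
#'
#' @slot sampleId sample identifiers (unique; every sample exactly once).
#' @slot profile assigned profile name per sample (`NA` if unassignable).
#' @slot fallback TRUE where no registered profile qualified and the
#'   singleton of the most abundant variant was used instead.
#' @slot lowDepth TRUE where the sample total is below the registry's
#'   low-depth threshold.
#' @exportClass DominantAssignment
setClass("DominantAssignment",
         slots = c(sampleId = "character", profile = "character",
                   fallback = "logical", lowDepth = "logical"))

setValidity("DominantAssignment", function(object) {
  n <- length(object@sampleId)
  msg <- character(0)
  if (anyDuplicated(object@sampleId))
    msg <- c(msg, "every sample must be assigned exactly once")
  if (length(object@profile) != n || length(object@fallback) != n ||
      length(object@lowDepth) != n)
    msg <- c(msg, "slot lengths must agree")
  if (length(msg)) msg else TRUE
})

# -------------------------------------------------------------------------
# Statistical results
# -------------------------------------------------------------------------

#' BetaRegressionFit: maximum-likelihood beta regression
#'
#' Mean model \eqn{\mu_i = logistic(x_i^T \beta)} with common precision
#' \eqn{\phi} (shape parameters \eqn{\mu\phi, (1-\mu)\phi}), fitted by
#' BFGS on the beta log-likelihood.
#'
#' @slot coefficients named mean-model coefficients on the logit scale.
#' @slot phi precision parameter (> 0).
#' @slot se standard errors of the mean-model coefficients (observed
#'   information).
#' @slot vcov variance-covariance matrix of `(coefficients, log phi)`.
#' @slot logLik maximised log-likelihood.
#' @slot converged logical convergence flag (never silently FALSE: the
#'   fitter warns).
#' @slot groups the grouping factor used to build the design.
#' @slot y the response used for the fit.
#' @exportClass BetaRegressionFit
setClass("BetaRegressionFit",
         slots = c(coefficients = "numeric", phi = "numeric",
                   se = "numeric", vcov = "matrix", logLik = "numeric",
                   converged = "logical", groups = "factor", y = "numeric"))

#' OrdinationResult: non-metric multidimensional scaling solution
#'
#' @slot points samples x k coordinate matrix (best restart).
#' @slot stress Kruskal stress-1 of the reported configuration, in
#'   `[0, 1]`.
#' @slot nRestarts number of restarts attempted.
#' @slot converged TRUE if the best restart met the stress tolerance.
#' @slot trace stress trajectory of the best restart (non-increasing).
#' @exportClass OrdinationResult
setClass("OrdinationResult",
         slots = c(points = "matrix", stress = "numeric",
                   nRestarts = "integer", converged = "logical",
                   trace = "numeric"))

setValidity("OrdinationResult", function(object) {
  if (length(object@stress) != 1L || object@stress < 0 || object@stress > 1)
    "stress must be a single value in [0, 1]" else TRUE
})

#' PermutationTestResult: statistic plus permutation p-value
#'
#' Used by [permanovaTest()], [anosimTest()] and [betaDispersion()].  The
#' p-value follows the add-one convention
#' \eqn{p = (\#\{perm \ge obs\} + 1)/(n_{perm} + 1)} unless the test was
#' run exhaustively, in which case it is the exact proportion over all
#' distinct label arrangements.
#'
#' @slot method test name.
#' @slot statistic observed statistic (pseudo-F, ANOSIM R, dispersion F).
#' @slot pValue permutation (or exact) p-value in (0, 1].
#' @slot nPerm number of random permutations used (0 if exhaustive).
#' @slot seed RNG seed used for the permutations.
#' @slot exhaustive TRUE if all distinct arrangements were enumerated.
#' @slot extra method-specific extras (e.g. per-sample centroid distances).
#' @exportClass PermutationTestResult
setClass("PermutationTestResult",
         slots = c(method = "character", statistic = "numeric",
                   pValue = "numeric", nPerm = "integer", seed = "integer",
                   exhaustive = "logical", extra = "list"))

setValidity("PermutationTestResult", function(object) {
  p <- object@pValue
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    "pValue must lie in (0, 1]" else TRUE
})

#' KMCurve: Kaplan-Meier product-limit estimate
#'
#' @slot time distinct event times (days).
#' @slot nRisk number at risk just before each event time.
#' @slot nEvent number of events at each event time.
#' @slot surv survival probability S(t) at each event time.
#' @slot se Greenwood standard error of S(t).
#' @slot lower,upper 95% log-log confidence limits.
#' @slot median smallest time with S(t) <= 0.5; `NA_real_` if never
#'   reached (all-censored or survival stays above 0.5).
#' @slot nTotal number of individuals; @slot nEvents total events.
#' @exportClass KMCurve
setClass("KMCurve",
         slots = c(time = "numeric", nRisk = "numeric", nEvent = "numeric",
                   surv = "numeric", se = "numeric", lower = "numeric",
                   upper = "numeric", median = "numeric",
                   nTotal = "integer", nEvents = "integer"))

setValidity("KMCurve", function(object) {
  msg <- character(0)
  s <- object@surv
  if (any(s < -1e-12 | s > 1 + 1e-12)) msg <- c(msg, "S(t) must lie in [0,1]")
  if (length(s) > 1L && any(diff(s) > 1e-12))
    msg <- c(msg, "S(t) must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' LogrankResult: two-group log-rank test
#'
#' @slot statistic chi-square statistic (1 df).
#' @slot pValue asymptotic p-value.
#' @slot observed,expected per-group observed and expected event counts.
#' @slot permPValue optional permutation p-value (`NA` unless requested).
#' @exportClass LogrankResult
setClass("LogrankResult",
         slots = c(statistic = "numeric", pValue = "numeric",
                   observed = "numeric", expected = "numeric",
                   permPValue = "numeric"))

# -------------------------------------------------------------------------
# Simulator configuration
# -------------------------------------------------------------------------

#' CommunityConfig: the stated world for community simulation
#'
#' Defaults encode a community dominated by a nested C15-family DIV
#' profile (C15:C15dq:C15dr:C_1365 at 0.70/0.15/0.10/0.05 of the host
#' fraction) with 3% total baseline background split evenly over 8
#' variants spanning genera A, B, D, F plus extra C, heat expanding the
#' background 8-fold in larvae but not at all in juveniles.
#'
#' @slot dominantMembers named numeric; proportions of the dominant-profile
#'   fraction, summing to 1.
#' @slot background data.frame with columns `variant`, `genus`, `baseline`
#'   (baseline relative abundances; total strictly below the dominant
#'   total).
#' @slot heatMultiplierLarva,heatMultiplierJuvenile positive multipliers
#'   applied to background baselines under heat.
#' @slot dirichletConcentration positive; larger = less overdispersed.
#' @slot librarySizeLogMean,librarySizeLogSd log-normal library size.
#' @slot nPerGroup default samples per stage x treatment cell.
#' @slot seed integer master seed (community draws use substream 1).
#' @exportClass CommunityConfig
setClass("CommunityConfig",
         slots = c(dominantMembers = "numeric", background = "data.frame",
                   heatMultiplierLarva = "numeric",
                   heatMultiplierJuvenile = "numeric",
                   dirichletConcentration = "numeric",
                   librarySizeLogMean = "numeric",
                   librarySizeLogSd = "numeric",
                   nPerGroup = "integer", seed = "integer"))

setValidity("CommunityConfig", function(object) {
  msg <- character(0)
  dm <- object@dominantMembers
  if (is.null(names(dm)) || any(!nzchar(names(dm))))
    msg <- c(msg, "dominantMembers must be named")
  if (any(!is.finite(dm)) || any(dm <= 0) || any(dm >= 1))
    msg <- c(msg, "dominant proportions must lie in (0,1)")
  if (abs(sum(dm) - 1) > 1e-9)
    msg <- c(msg, "dominant proportions must sum to 1")
  bg <- object@background
  if (!all(c("variant", "genus", "baseline") %in% names(bg)))
    msg <- c(msg, "background needs columns variant/genus/baseline")
  else {
    if (any(!is.finite(bg$baseline)) || any(bg$baseline <= 0) ||
        any(bg$baseline >= 1))
      msg <- c(msg, "background baselines must lie in (0,1)")
    if (sum(bg$baseline) >= 1 - sum(bg$baseline))
      msg <- c(msg, "baseline background total must be below dominant total")
    if (anyDuplicated(c(names(dm), bg$variant)))
      msg <- c(msg, "variant names must be unique")
  }
  for (s in c("heatMultiplierLarva", "heatMultiplierJuvenile",
              "dirichletConcentration", "librarySizeLogSd")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (!is.finite(object@librarySizeLogMean))
    msg <- c(msg, "librarySizeLogMean must be finite")
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SurvivalConfig: the stated world for survival simulation
#'
#' Latent death times are exponential with rate `log(2)/median` per
#' stage x treatment cell; individuals are only observed at the cell's
#' monitoring schedule (21 visits over days 0-57 for larvae, 3 visits
#' over 20 days for juveniles by default).  Default medians: 20 d
#' (juvenile, heat), 57 d (larva, heat), 200 d (ambient, both stages —
#' beyond the schedules, so ambient records are mostly censored).
#'
#' @slot cells data.frame with columns `stage`, `treatment`,
#'   `median_days`, `n`.
#' @slot schedules named list (by stage) of strictly increasing
#'   monitoring days starting at or after 0.
#' @slot seed integer master seed (survival draws use substream 2).
#' @exportClass SurvivalConfig
setClass("SurvivalConfig",
         slots = c(cells = "data.frame", schedules = "list",
                   seed = "integer"))

setValidity("SurvivalConfig", function(object) {
  msg <- character(0)
  cl <- object@cells
  if (!all(c("stage", "treatment", "median_days", "n") %in% names(cl)))
    msg <- c(msg, "cells needs columns stage/treatment/median_days/n")
  else {
    if (any(!is.finite(cl$median_days)) || any(cl$median_days <= 0))
      msg <- c(msg, "medians must be > 0")
    if (any(cl$n < 1)) msg <- c(msg, "cell sizes must be >= 1")
    if (!all(cl$stage %in% names(object@schedules)))
      msg <- c(msg, "every stage needs a monitoring schedule")
  }
  for (nm in names(object@schedules)) {
    s <- object@schedules[[nm]]
    if (length(s) == 0L)
      msg <- c(msg, sprintf("schedule for '%s' is empty", nm))
    else if (any(s < 0) || any(diff(s) <= 0))
      msg <- c(msg, sprintf("schedule for '%s' must be strictly increasing, >= 0", nm))
  }
  if (length(msg)) msg else TRUE
})
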