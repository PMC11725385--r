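# The hybrid taxonomy overlay: dominant-profile assignment, DIV collapse,
# and data-driven discovery of co-occurring profiles.

#' Assign each sample its dominant DIV profile
#'
#' A member variant is "detected" in a sample when its count is positive
#' and at least `detectionFraction` of the summed count of all registry
#' member variants in that sample (detection is relative, so a sample
#' can be dominant-C15 while carrying trace C15dq).  The dominant
#' profile is the registered profile with the most members among those
#' whose every member is detected; ties are broken by larger summed
#' member count, then lexicographically smaller name.  If no registered
#' profile qualifies, the sample falls back to the singleton profile of
#' its most abundant registry member variant (or, failing that, its most
#' abundant variant overall) and is flagged.  Samples with zero total
#' count are flagged unassignable (`NA` profile).
#'
#' @param table a [VariantCountTable-class].
#' @param registry a [ProfileRegistry-class] sharing the table's variant
#'   namespace.
#' @param detectionFraction relative detection threshold in `[0, 1)`,
#'   default 0.01.
#' @return A [DominantAssignment-class].
#' @export
assignDominantProfile <- function(table, registry, detectionFraction = 0.01) {
  if (!is.numeric(detectionFraction) || detectionFraction < 0 ||
      detectionFraction >= 1)
    .stopf("detectionFraction must lie in [0, 1)")
  m <- .asSampleMatrix(table)
  prof_names <- profileNames(registry)
  members <- lapply(prof_names, function(p) profileMembers(registry, p))
  universe <- unique(unlist(members))
  uni_present <- intersect(universe, colnames(m))

  n <- nrow(m)
  profile <- character(n)
  fallback <- logical(n)
  lowDepth <- rowSums(m) < registry@lowDepthThreshold

  for (s in seq_len(n)) {
    counts <- stats::setNames(as.numeric(m[s, ]), colnames(m))
    total <- sum(counts)
    if (total == 0) {
      profile[s] <- NA_character_
      fallback[s] <- TRUE
      next
    }
    famTotal <- sum(counts[uni_present])
    detected <- names(counts)[counts > 0 &
                                counts >= detectionFraction * famTotal]
    qualifies <- vapply(members, function(mm) all(mm %in% detected),
                        logical(1))
    if (any(qualifies)) {
      size <- vapply(members, length, integer(1))
      msum <- vapply(members, function(mm)
        sum(counts[intersect(mm, colnames(m))]), numeric(1))
      cand <- which(qualifies)
      cand <- cand[size[cand] == max(size[cand])]
      cand <- cand[msum[cand] == max(msum[cand])]
      cand <- cand[order(prof_names[cand])][1L]
      profile[s] <- prof_names[cand]
    } else {
      fallback[s] <- TRUE
      pool <- counts[uni_present]
      pool <- pool[pool > 0]
      if (length(pool) == 0L) {
        pool <- counts[counts > 0]
      }
      # deterministic: largest count, then name
      best <- names(pool)[order(-pool, names(pool))][1L]
      profile[s] <- best
    }
  }
  new("DominantAssignment", sampleId = rownames(m), profile = profile,
      fallback = fallback, lowDepth = lowDepth)
}

#' Read a dominant assignment from a two-column TSV
#'
#' Mirrors supplying dominance externally (e.g. from a SymPortal run):
#' a tab-separated file with columns `sample_id` and `profile`.
#'
#' @param path file path.
#' @param table a [VariantCountTable-class]; every sample must appear
#'   exactly once in the file.
#' @param registry a [ProfileRegistry-class], used for the low-depth
#'   flag.
#' @return A [DominantAssignment-class] (fallback flags all FALSE).
#' @export
readDominantAssignment <- function(path, table, registry) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("sample_id", "profile") %in% names(df)))
    .stopf("assignment file needs columns 'sample_id' and 'profile'")
  ids <- sampleIds(table)
  i <- match(ids, df$sample_id)
  if (anyNA(i))
    .stopf("assignment file is missing samples: %s",
           paste(utils::head(ids[is.na(i)], 5), collapse = ", "))
  m <- .asSampleMatrix(table)
  new("DominantAssignment", sampleId = ids,
      profile = as.character(df$profile)[i],
      fallback = rep(FALSE, length(ids)),
      lowDepth = rowSums(m) < registry@lowDepthThreshold)
}

#' Collapse member-variant counts into DIV columns
#'
#' For each sample, the counts of the member variants of its dominant
#' profile are summed into a single column named by that profile.
#' Member variants outside a sample's dominant profile keep their counts
#' in individual variant columns (a dominant-C15 sample with trace
#' C15dq retains the C15dq count unmodified), and all non-member
#' variants are retained unchanged.  Columns whose dataset-wide total is
#' at or below the registry's background read threshold are labelled
#' `"background"` but never removed.  Per-sample totals are conserved
#' exactly.
#'
#' @param table a [VariantCountTable-class].
#' @param registry a [ProfileRegistry-class].
#' @param assignment a [DominantAssignment-class] covering all samples;
#'   computed from `table` when omitted.
#' @param detectionFraction passed to [assignDominantProfile()] when
#'   `assignment` is missing.
#' @param dropLowDepth if TRUE, samples below the low-depth threshold
#'   are removed before collapsing (default FALSE: the flags are kept,
#'   matching a resequence-rather-than-drop policy).
#' @return A [CollapsedCountTable-class].
#' @export
collapseToDIV <- function(table, registry, assignment = NULL,
                          detectionFraction = 0.01, dropLowDepth = FALSE) {
  if (is.null(assignment))
    assignment <- assignDominantProfile(table, registry, detectionFraction)
  m <- .asSampleMatrix(table)
  i <- match(rownames(m), assignment@sampleId)
  if (anyNA(i)) .stopf("assignment does not cover all samples")
  prof <- assignment@profile[i]
  fallback <- assignment@fallback[i]
  lowDepth <- assignment@lowDepth[i]

  if (dropLowDepth) {
    keep <- !lowDepth
    if (!any(keep)) .stopf("all samples are below the low-depth threshold")
    m <- m[keep, , drop = FALSE]
    prof <- prof[keep]; fallback <- fallback[keep]; lowDepth <- lowDepth[keep]
  }

  reg_names <- profileNames(registry)
  memberOf <- function(p) {
    if (p %in% reg_names) profileMembers(registry, p)
    else if (p %in% colnames(m)) p  # singleton fallback on a raw variant
    else .stopf("assignment references unknown profile '%s'", p)
  }
  used <- unique(prof[!is.na(prof)])
  for (p in used) memberOf(p)  # validate up front

  div_cols <- setdiff(used, colnames(m))  # new columns to create
  out <- cbind(matrix(0, nrow(m), length(div_cols),
                      dimnames = list(rownames(m), div_cols)), m)

  for (s in seq_len(nrow(m))) {
    p <- prof[s]
    if (is.na(p)) next
    mm <- intersect(memberOf(p), colnames(m))
    if (length(mm) == 0L) next
    tot <- sum(m[s, mm])
    out[s, mm] <- 0
    out[s, p] <- out[s, p] + tot
  }

  kind <- ifelse(colnames(out) %in% reg_names &
                   colnames(out) %in% used, "DIV", "variant")
  kind[colSums(out) <= registry@backgroundReadThreshold] <- "background"

  cd <- DataFrame(dominantProfile = prof, fallback = fallback,
                  lowDepth = lowDepth, row.names = rownames(out))
  if (is(table, "SummarizedExperiment")) {
    orig <- colData(table)[rownames(out), , drop = FALSE]
    keep <- setdiff(colnames(orig), colnames(cd))
    if (length(keep)) cd <- cbind(orig[, keep, drop = FALSE], cd)
  }
  rd <- DataFrame(kind = kind, row.names = colnames(out))
  new("CollapsedCountTable",
      SummarizedExperiment(assays = list(counts = t(out)),
                           colData = cd, rowData = rd))
}

#' Infer co-occurring DIV profiles from presence patterns
#'
#' A simplified, data-driven emulation of profile discovery: variants
#' whose dataset-wide total is at or below `backgroundReadThreshold`
#' reads are excluded from seeding; the remaining variants, visited in
#' decreasing total-abundance order, are greedily agglomerated into a
#' candidate profile whenever their presence/absence Jaccard similarity
#' across samples is at least `codetectionJaccardMin` with every current
#' member.  Presence means relative abundance at least
#' `presenceFraction` within the sample.  Each candidate profile is
#' named by its members joined by `-` in descending mean relative
#' abundance.
#'
#' @param table a [VariantCountTable-class]; a warning is issued below 5
#'   samples.
#' @param codetectionJaccardMin Jaccard cutoff in (0, 1], default 0.9.
#' @param backgroundReadThreshold seeding exclusion threshold (reads),
#'   default 200.
#' @param presenceFraction within-sample relative abundance defining
#'   presence, default 0.01.
#' @return A candidate [ProfileRegistry-class].
#' @export
inferCooccurringProfiles <- function(table, codetectionJaccardMin = 0.9,
                                     backgroundReadThreshold = 200,
                                     presenceFraction = 0.01) {
  m <- .asSampleMatrix(table)
  if (nrow(m) == 0L || ncol(m) == 0L) .stopf("empty table")
  if (nrow(m) < 5L)
    warning("fewer than 5 samples: co-occurrence inference is unreliable")
  totals <- colSums(m)
  seedable <- names(totals)[totals > backgroundReadThreshold]
  if (length(seedable) == 0L)
    return(ProfileRegistry(list(),
                           backgroundReadThreshold = backgroundReadThreshold))
  rel <- m / pmax(rowSums(m), 1)
  present <- rel >= presenceFraction & m > 0
  jaccard <- function(a, b) {
    u <- sum(present[, a] | present[, b])
    if (u == 0) return(0)
    sum(present[, a] & present[, b]) / u
  }
  order_by_abund <- seedable[order(-totals[seedable])]
  assigned <- character(0)
  groups <- list()
  for (v in order_by_abund) {
    if (v %in% assigned) next
    grp <- v
    for (w in setdiff(order_by_abund, c(assigned, v))) {
      if (all(vapply(grp, function(g) jaccard(g, w), numeric(1)) >=
              codetectionJaccardMin))
        grp <- c(grp, w)
    }
    assigned <- c(assigned, grp)
    groups[[length(groups) + 1L]] <- grp
  }
  meanRel <- colMeans(rel)
  profiles <- lapply(groups, function(g)
    DIVProfile(g[order(-meanRel[g], g)]))
  ProfileRegistry(profiles,
                  backgroundReadThreshold = backgroundReadThreshold)
}
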