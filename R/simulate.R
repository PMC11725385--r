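# Synthetic-data generator: Dirichlet-multinomial symbiont communities and
# interval-monitored exponential survival, emulating a heat-stress
# experiment on a vertically transmitting coral.

.defaultBackground <- function() {
  data.frame(
    variant = c("A1", "A2", "B1", "D1", "D1a", "F1", "C3", "C1"),
    genus = c("Symbiodinium", "Symbiodinium", "Breviolum", "Durusdinium",
              "Durusdinium", "Fugacium", "Cladocopium", "Cladocopium"),
    baseline = rep(0.03 / 8, 8),
    stringsAsFactors = FALSE)
}

#' Community simulation configuration
#'
#' See [CommunityConfig-class] for the meaning and the default stated
#' world.  Briefly: a C15-family dominated community (dominant members
#' C15/C15dq/C15dr/C_1365 at 0.70/0.15/0.10/0.05 of the host fraction),
#' 3% total baseline background over 8 variants of genera
#' *Symbiodinium* (A), *Breviolum* (B), *Durusdinium* (D), *Fugacium*
#' (F) and other *Cladocopium* (C), heat multiplying the background
#' 8-fold in larvae and not at all in juveniles.
#'
#' @param dominantMembers named numeric proportions summing to 1.
#' @param background data.frame(variant, genus, baseline).
#' @param heatMultiplierLarva,heatMultiplierJuvenile positive reals.
#' @param dirichletConcentration positive; larger = tighter around the
#'   expected composition.
#' @param librarySizeLogMean,librarySizeLogSd log-normal library size
#'   parameters (reads).
#' @param nPerGroup default samples per stage x treatment cell.
#' @param seed master seed.
#' @return A [CommunityConfig-class].
#' @export
communityConfig <- function(dominantMembers = c(C15 = 0.70, C15dq = 0.15,
                                                C15dr = 0.10, C_1365 = 0.05),
                            background = .defaultBackground(),
                            heatMultiplierLarva = 8,
                            heatMultiplierJuvenile = 1,
                            dirichletConcentration = 500,
                            librarySizeLogMean = log(2e4),
                            librarySizeLogSd = 0.4,
                            nPerGroup = 20L, seed = 1L) {
  new("CommunityConfig", dominantMembers = dominantMembers,
      background = background,
      heatMultiplierLarva = as.numeric(heatMultiplierLarva),
      heatMultiplierJuvenile = as.numeric(heatMultiplierJuvenile),
      dirichletConcentration = as.numeric(dirichletConcentration),
      librarySizeLogMean = as.numeric(librarySizeLogMean),
      librarySizeLogSd = as.numeric(librarySizeLogSd),
      nPerGroup = as.integer(nPerGroup), seed = as.integer(seed))
}

#' Default stage x treatment design for community simulation
#'
#' Larvae in all three treatment groups (pre-stress, ambient, heat) and
#' juveniles in ambient and heat, `n` samples each.
#'
#' @param n samples per cell.
#' @export
defaultCommunityDesign <- function(n = 20L) {
  data.frame(stage = c("larva", "larva", "larva", "juvenile", "juvenile"),
             treatment = c("prestress", "ambient", "heat", "ambient",
                           "heat"),
             n = as.integer(n), stringsAsFactors = FALSE)
}

#' Expected relative abundances for one stage x treatment cell
#'
#' Background baselines are scaled by the stage's heat multiplier (heat
#' treatment only), dominant member proportions are scaled by one minus
#' the scaled background total, and the whole vector is renormalised.
#'
#' @param cfg a [CommunityConfig-class].
#' @param stage `"larva"` or `"juvenile"`.
#' @param treatment `"prestress"`, `"ambient"` or `"heat"`.
#' @return Named numeric vector summing to 1 (dominant members first,
#'   then background variants).
#' @export
expectedComposition <- function(cfg, stage, treatment) {
  mult <- if (identical(treatment, "heat")) {
    if (identical(stage, "juvenile")) cfg@heatMultiplierJuvenile
    else cfg@heatMultiplierLarva
  } else 1
  bg <- cfg@background$baseline * mult
  if (sum(bg) >= 1)
    .stopf("scaled background total %.3f leaves no room for the dominant profile",
           sum(bg))
  dom <- cfg@dominantMembers * (1 - sum(bg))
  expected <- c(dom, stats::setNames(bg, cfg@background$variant))
  expected / sum(expected)
}

#' Simulate a variant count table with sample metadata
#'
#' Per sample, the realised composition is a Dirichlet draw around the
#' cell's expected composition with concentration
#' `dirichletConcentration`, and counts are multinomial at a log-normal
#' library size.  Per-sample counts sum to the drawn library size
#' exactly; identical seeds give identical tables (community draws use
#' substream 1 of the master seed).
#'
#' @param cfg a [CommunityConfig-class].
#' @param design data.frame with columns `stage`, `treatment`, `n`
#'   (optionally `family`); defaults to [defaultCommunityDesign()] with
#'   `cfg@nPerGroup` samples per cell.
#' @return A [VariantCountTable-class] whose `colData` carries `stage`,
#'   `treatment`, `family` and `timepoint`.
#' @export
simulateCommunityCounts <- function(cfg, design = NULL) {
  stopifnot(is(cfg, "CommunityConfig"))
  validObject(cfg)
  if (is.null(design)) design <- defaultCommunityDesign(cfg@nPerGroup)
  if (nrow(design) == 0L) .stopf("empty design")
  if (!all(c("stage", "treatment", "n") %in% names(design)))
    .stopf("design needs columns stage/treatment/n")
  .withStreamSeed(cfg@seed, 1L, .simulateCommunityInner(cfg, design))
}

.simulateCommunityInner <- function(cfg, design) {
  variants <- c(names(cfg@dominantMembers), cfg@background$variant)
  rows <- list(); meta <- list()
  for (r in seq_len(nrow(design))) {
    stage <- design$stage[r]; treatment <- design$treatment[r]
    nn <- design$n[r]
    fam <- if ("family" %in% names(design)) design$family[r] else "bulk"
    expected <- expectedComposition(cfg, stage, treatment)
    alpha <- cfg@dirichletConcentration * expected
    for (i in seq_len(nn)) {
      g <- stats::rgamma(length(alpha), shape = alpha)
      comp <- g / sum(g)
      lib <- max(1, round(stats::rlnorm(1, cfg@librarySizeLogMean,
                                        cfg@librarySizeLogSd)))
      counts <- as.numeric(stats::rmultinom(1, lib, comp))
      id <- sprintf("%s_%s_%s_%03d", stage, treatment, fam, i)
      rows[[id]] <- counts
      meta[[id]] <- data.frame(
        sample_id = id, stage = stage, treatment = treatment,
        family = fam,
        timepoint = if (treatment == "prestress") 0
                    else if (stage == "larva") 57 else 20,
        stringsAsFactors = FALSE)
    }
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), variants)
  md <- do.call(rbind, meta)
  VariantCountTable(m, sampleData = md)
}

#' Survival simulation configuration
#'
#' See [SurvivalConfig-class].  Default cells: heat medians 20 d
#' (juvenile) and 57 d (larva); ambient median 200 d for both stages
#' (beyond the monitoring schedules, so ambient arms are mostly
#' censored).  Default schedules: larvae monitored at 21 visits over
#' days 0-57, juveniles at 3 visits over 20 days.
#'
#' @param cells data.frame(stage, treatment, median_days, n).
#' @param schedules named list of strictly increasing monitoring days.
#' @param seed master seed (survival draws use substream 2).
#' @return A [SurvivalConfig-class].
#' @export
survivalConfig <- function(cells = NULL, schedules = NULL, seed = 1L) {
  if (is.null(cells))
    cells <- data.frame(
      stage = c("larva", "larva", "juvenile", "juvenile"),
      treatment = c("ambient", "heat", "ambient", "heat"),
      median_days = c(200, 57, 200, 20),
      n = c(192L, 192L, 96L, 96L),
      stringsAsFactors = FALSE)
  if (is.null(schedules))
    schedules <- list(larva = unique(round(seq(0, 57, length.out = 21))),
                      juvenile = c(7, 14, 20))
  new("SurvivalConfig", cells = cells, schedules = schedules,
      seed = as.integer(seed))
}

#' Simulate interval-monitored survival records
#'
#' Latent death times are exponential with rate `log(2) / median_days`
#' per cell.  An individual whose latent time falls at or before a
#' monitoring day is recorded as an event at the first monitoring day at
#' or after the latent time (the right endpoint of its interval — "deemed
#' dead when not seen" at a visit); a latent time beyond the last visit
#' yields a censored record at the last visit (event = 0).
#'
#' @param cfg a [SurvivalConfig-class].
#' @return data.frame with columns `individual_id`, `stage`,
#'   `treatment`, `family`, `time_days`, `event`.
#' @export
simulateSurvivalRecords <- function(cfg) {
  stopifnot(is(cfg, "SurvivalConfig"))
  validObject(cfg)
  .withStreamSeed(cfg@seed, 2L, .simulateSurvivalInner(cfg))
}

.simulateSurvivalInner <- function(cfg) {
  out <- list()
  for (r in seq_len(nrow(cfg@cells))) {
    stage <- cfg@cells$stage[r]; treatment <- cfg@cells$treatment[r]
    med <- cfg@cells$median_days[r]; nn <- cfg@cells$n[r]
    sched <- cfg@schedules[[stage]]
    latent <- stats::rexp(nn, rate = log(2) / med)
    pos <- findInterval(latent, sched, left.open = TRUE) + 1L
    censored <- pos > length(sched)
    time <- ifelse(censored, sched[length(sched)], sched[pmin(pos, length(sched))])
    out[[r]] <- data.frame(
      individual_id = sprintf("%s_%s_%04d", stage, treatment, seq_len(nn)),
      stage = stage, treatment = treatment, family = "bulk",
      time_days = time, event = as.integer(!censored),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a complete simulated study bundle to disk
#'
#' Generates the community table, metadata, profile registry and
#' survival records for one master seed and writes them as
#' `counts.tsv`, `metadata.tsv`, `registry.json` and `survival.tsv`
#' (formats as read by [readCountTable()], [readSampleMetadata()],
#' [readRegistry()] and [readSurvivalRecords()]).  Two runs with the
#' same configuration and seed produce byte-identical files.
#'
#' @param communityCfg a [CommunityConfig-class].
#' @param survivalCfg a [SurvivalConfig-class].
#' @param outDir output directory (created if needed).
#' @param design optional community design (see
#'   [simulateCommunityCounts()]).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
generateStudyBundle <- function(communityCfg = communityConfig(),
                                survivalCfg = survivalConfig(),
                                outDir, design = NULL) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    .stopf("cannot create output directory '%s'", outDir)
  tab <- simulateCommunityCounts(communityCfg, design)
  surv <- simulateSurvivalRecords(survivalCfg)
  reg <- generateProfileLibrary(names(communityCfg@dominantMembers),
                                as.numeric(communityCfg@dominantMembers),
                                background = communityCfg@background$variant)
  paths <- list(counts = file.path(outDir, "counts.tsv"),
                metadata = file.path(outDir, "metadata.tsv"),
                registry = file.path(outDir, "registry.json"),
                survival = file.path(outDir, "survival.tsv"))
  writeCountTable(tab, paths$counts)
  writeSampleMetadata(tab, paths$metadata)
  writeRegistry(reg, paths$registry)
  writeSurvivalRecords(surv, paths$survival)
  invisible(list(table = tab, survival = surv, registry = reg,
                 paths = paths))
}
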