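---
title: "Methods: DIV overlay, diversity statistics and survival for coral symbiont communities"
author: "SymShuffle authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DIV overlay, diversity statistics and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SymShuffle)
```

# The scientific problem

Reef-building corals host dinoflagellate symbionts (family
Symbiodiniaceae), and the composition of that community modulates the
host's thermal limits. In vertically transmitting corals the community
is inherited maternally, and a central question for early life stages
is whether larvae and juveniles can *shuffle* their resident symbionts
— shift relative abundances toward more stress-tolerant background
taxa — when heated. SymShuffle implements the analysis chain used to
answer that question from ITS2 amplicon data: a hybrid taxonomy
overlay that collapses amplicon sequence variants (ASVs) into
"defining intragenomic variant" (DIV) profiles, alpha/beta diversity
statistics with permutation tests, and Kaplan–Meier survival — plus a
simulator that generates data with the same statistical structure so
the whole chain is testable without sequencing data.

# The DIV overlay

ITS2 is a multi-copy marker: one symbiont genome carries several
distinct sequence variants, so counting raw ASVs overstates diversity.
A DIV profile names an ordered set of variants that co-occur because
they reside in one genome; nested, overlapping profiles such as
`C15`, `C15-C15dq`, `C15-C15dq-C15dr`, `C15-C15dq-C15dr-C_1365`
represent one *Cladocopium* lineage observed at increasing variant
resolution. Profile names join members with `-`; member names may
contain underscores but never dashes, so parsing is unambiguous.

Per sample the overlay proceeds in two steps:

1. **Dominant assignment** (`assignDominantProfile`). A member variant
   is *detected* when its count is positive and at least
   `detectionFraction` (default 0.01) of the summed count of all
   registry member variants in that sample. Detection is relative
   rather than absolute so that a deeply sequenced dominant-`C15`
   sample with trace `C15dq` is still assigned `C15`, with the trace
   counts retained individually. The dominant profile is the
   registered profile with the most members among those fully
   detected; ties break by summed member count, then name. When no
   registered profile qualifies, the sample falls back to the
   singleton profile of its most abundant registry member variant
   (or, if it carries none, its most abundant variant overall) and is
   flagged; zero-count samples are flagged unassignable. The
   published pipelines delegate dominance to an external profile
   caller; the relative-detection rule here is a documented stand-in,
   and an externally supplied two-column assignment file is accepted
   via `readDominantAssignment()`.
2. **Collapse** (`collapseToDIV`). Counts of the dominant profile's
   members are summed into one column named by the profile; member
   variants outside the sample's dominant profile and all non-member
   variants keep their own columns. Nothing is deleted: columns whose
   dataset-wide total is at or below the background read threshold
   (default 200 reads — the level at which conventional profile
   callers would discard them) are only *labelled* background, so
   rare variants that expand under heat remain observable. Whether
   that 200-read rule should be per-sample or dataset-wide is not
   settled; dataset-wide is used here because the labelling exists to
   protect longitudinally rare columns. Per-sample totals are
   conserved exactly — this is asserted property-style in the tests.
   Samples under 1000 total reads are flagged low-depth; dropping
   them is an explicit option (default off, mirroring a
   resequence-rather-than-drop policy).

`inferCooccurringProfiles()` offers a simplified data-driven check of
the profile structure: variants above the background threshold are
greedily agglomerated when their presence/absence Jaccard similarity
(presence = within-sample relative abundance at or above 1%) is at
least 0.9 with every current member. It recovers the simulator's
planted family essentially always; it is a diagnostic, not a
replacement for a curated registry.

# Diversity statistics

* **Shannon index** in nats, zero categories excluded (no base is
  canonical; nats make `H = log(richness)` exact for uniform
  communities).
* **Beta regression** needs a response strictly inside (0, 1), but
  Shannon is bounded by `log(S)`, not 1. The pipeline's default is
  Pielou evenness `H / log(S_total)` (with `S_total` the table-wide
  column count, so samples share one scale), followed by the standard
  boundary squeeze `(y (n - 1) + 0.5) / n`. A raw squeeze of values
  already in `[0, 1]` is exposed separately; neither option is
  asserted to be what any particular study used, because that choice
  is typically unstated.
* **Beta regression** is fitted by BFGS on the exact log-likelihood
  with a logit mean link and common precision `phi`, analytic
  gradient, OLS-on-logits initialisation and observed-information
  standard errors. Non-convergence warns and is flagged on the
  object. Pairwise group comparisons are Wald contrasts with **Holm**
  adjustment: Tukey's HSD is defined for homoscedastic normal means,
  and no studentised-range analogue exists for beta-regression
  contrasts, so Holm is the conservative, well-defined substitute.
* **Bray–Curtis**, **NMDS**, **PERMANOVA**, **ANOSIM** and the
  **dispersion test** are implemented from their defining formulas
  (the installed community-ecology package is used in the test suite
  as an independent cross-check, never as the implementation). NMDS
  minimises Kruskal stress-1 by alternating pool-adjacent-violators
  monotone regression (tied dissimilarities share an averaged
  disparity) with Guttman-transform majorization steps; 20 restarts
  (one PCoA-seeded, the rest random), tolerance 1e-6, 300 iterations.
  The loop stops at the first non-improvement and keeps the best
  configuration, so the recorded stress trajectory is non-increasing
  and the final stress never exceeds the PCoA baseline. Permutation
  p-values use the add-one convention and are reproducible under a
  seed; exhaustive enumeration over all distinct label arrangements
  is available for small n, where p is exact. The dispersion test
  embeds the distances by principal coordinates with a Lingoes-style
  additive correction when negative eigenvalues arise (group
  centroids, not spatial medians — the simpler, analytically cleaner
  option), and permutes the centroid distances' labels.

# Survival

Monitoring is interval-based: an individual present at one visit and
absent at the next is scored dead at the *right endpoint* of that
interval, because "dead" is only observable at a visit. Interval-
censored likelihoods are out of scope; with visits every 1–3 days the
right-endpoint convention biases medians upward by at most half a
visit interval. The Kaplan–Meier estimator, Greenwood variance,
log-log confidence limits and the two-group log-rank test are
standard; the median is the smallest time with `S(t) <= 0.5` and is
explicitly undefined (`NA`) when survival never reaches 0.5 — which
genuinely happens on a coarse 3-visit schedule whose last visit sits
near the true median.

# The simulator: a stated world

`communityConfig()` and `survivalConfig()` fix the world the tests
live in:

| parameter | default | why |
|---|---|---|
| dominant members | C15 0.70, C15dq 0.15, C15dr 0.10, C_1365 0.05 | a nested-family structure with members spanning two orders of magnitude |
| background total | 3% over 8 variants (genera A, B, D, F, extra C) | "below 5%" is the reported regime; 3% splits evenly |
| heat multiplier | larva 8, juvenile 1 | calibration: detectable larval shift at n = 20/group, exact juvenile null |
| Dirichlet concentration | 500 | tight regulation typical of a dominated, vertically transmitted community; keeps all dominant members co-detected in >99% of samples |
| library size | lognormal(log 2e4, 0.4) | a realistic MiSeq per-sample read depth |
| heat medians | juvenile 20 d, larva 57 d | the reported approximate medians |
| ambient median | 200 d | invented: far beyond the schedules, so ambient arms are mostly censored, matching the qualitatively high ambient survival |
| schedules | larvae 21 visits over 0–57 d; juveniles 3 visits over 20 d | the reported monitoring designs |
| n per survival cell | larva 192, juvenile 96 | larval n as reported for bulk cultures; juvenile n chosen once as realistic |

Latent death times are exponential (one parameter per cell) because
only medians are reported — a Weibull would add a shape parameter
nothing constrains. Communities are Dirichlet-multinomial: expected
background abundances are scaled by the stage's heat multiplier,
dominant members by the remaining mass, and the realised composition
is drawn around that expectation. A single master seed drives
separate substreams for community and survival draws, so either can
be regenerated independently; all package functions restore the
caller's RNG state.

What the simulator does **not** emulate: raw reads, PCR/chimera
artefacts, denoising error models, taxonomic mis-assignment,
family-level heritability structure, or any correlation between a
sample's community and its survival. A green test therefore
establishes that the *statistics* behave as designed on data with the
assumed structure — not that the biological conclusions of any one
study are correct.

# Numerical choices and degenerate inputs

* Permutation p-values: `(# permuted >= observed + 1)/(nPerm + 1)`;
  exhaustive mode divides by the number of distinct arrangements.
* Beta regression initial `phi` is clamped to `[1, 1e4]`; boundary
  responses are an error (squeeze first), not silently nudged.
* NMDS on an all-zero distance matrix returns a zero configuration
  with zero stress; duplicated points are allowed to coincide.
* KM with no events returns `S == 1` and an `NA` median rather than
  an error.
* Collapse keeps all-zero columns (labelled background) so column
  sets are stable across subsets of samples.
* Exhaustive enumeration refuses designs with more than 1e5 distinct
  arrangements.

# Known limitations

One-factor designs only (treatment within a life stage); no
multi-factor PERMANOVA, rarefaction, phylogenetic metrics, Cox or
frailty models. The dominant-assignment rule is a stand-in for an
external profile caller's internal logic, which is not public. KM
medians inherit the monitoring grid's resolution; on coarse schedules
the median can be undefined even when the underlying median is
finite.

# A worked run

```{r, eval = FALSE}
dir <- tempfile()
runPipelineCli(c("simulate", "--seed", "1", "--out", dir))
runPipelineCli(c("all", "--seed", "1", "--out", dir))
read.delim(file.path(dir, "km_medians.tsv"))
```

The same stages are available as plain functions
(`simulateCommunityCounts`, `collapseToDIV`, `shannonIndex`,
`fitBetaRegression`, `brayCurtis`, `nmdsOrdination`,
`permanovaTest`, `anosimTest`, `betaDispersion`, `kmFit`,
`logrankTest`); the CLI only orchestrates them over a bundle
directory and writes a manifest with versions, seed and thresholds
for reproducibility.
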