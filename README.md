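# SymShuffle

Analysis of Symbiodiniaceae ITS2 amplicon communities and survival in
coral early life stages under heat stress — for researchers studying
*symbiont shuffling*: the shift in relative abundance of algal
symbionts already resident in a coral host when it is warmed.

Corals host dinoflagellate symbionts whose ITS2 marker is multi-copy:
one genome carries several distinct sequence variants, so raw amplicon
sequence variants (ASVs) overstate diversity. The package's core is a
hybrid taxonomy overlay that collapses ASVs into **DIV profiles**
("defining intragenomic variants", e.g. `C15-C15dq-C15dr-C_1365` — an
ordered, nested set of co-occurring variants representing one
*Cladocopium* lineage) while *retaining* rare background variants that
conventional profile callers discard, so that background taxa
expanding under heat stay observable. Around it sit the statistics the
question needs, implemented from their defining formulas:

* **Alpha diversity** — Shannon index H = −Σ pᵢ ln pᵢ, Pielou evenness
  H/ln S, boundary squeeze (y(n−1)+0.5)/n, and maximum-likelihood beta
  regression (logit mean link, common precision φ) with Holm-adjusted
  Wald pairwise contrasts.
* **Beta diversity** — Bray–Curtis d(i,j) = Σ|xᵢ−xⱼ|/Σ(xᵢ+xⱼ), NMDS
  minimising Kruskal stress-1 (pool-adjacent-violators monotone
  regression + Guttman majorization, multi-start), one-factor
  PERMANOVA pseudo-F, ANOSIM R, and a betadisper-style multivariate
  dispersion test — all with seeded permutation p-values (add-one
  convention) and exact exhaustive enumeration for small n.
* **Survival** — Kaplan–Meier product-limit estimator S(t) = Π(1 −
  dⱼ/nⱼ) with median extraction and Greenwood/log-log intervals, and
  the two-group log-rank test.
* **Synthetic data** — a Dirichlet-multinomial community simulator and
  an interval-monitored exponential survival simulator whose defaults
  encode the studied regime (a C15-family-dominated community with <5%
  background, an 8-fold heat expansion of background taxa in larvae
  but not juveniles, heat medians ≈20 d for juveniles vs ≈57 d for
  larvae), so every stage is testable without sequence data.

## Worked example

```r
library(SymShuffle)

cfg <- communityConfig(seed = 1)                       # the stated world
tab <- simulateCommunityCounts(cfg,
         data.frame(stage = "larva",
                    treatment = c("ambient", "heat"), n = 20L))
reg <- generateProfileLibrary(names(cfg@dominantMembers),
                              as.numeric(cfg@dominantMembers),
                              background = cfg@background$variant)
cc  <- collapseToDIV(tab, reg)                          # DIV overlay
m   <- countMatrix(cc)
md  <- as.data.frame(SummarizedExperiment::colData(cc))

H <- shannonIndex(m)
round(tapply(H, md$treatment, mean), 3)
#> ambient    heat
#>   0.181   1.042

ev  <- squeezeToUnitInterval(H, mode = "evenness", sTotal = ncol(m))
fit <- fitBetaRegression(ev, md$treatment)
pairwiseGroupTests(fit)
#>         contrast  estimate        se         z p p_adj
#> 1 ambient - heat -2.055906 0.0525904 -39.09281 0     0

permanovaTest(brayCurtis(m), md$treatment, nPerm = 999, seed = 1)
#> PERMANOVA: statistic = 11.2963, p = 0.001 (999 permutations)

nmdsOrdination(brayCurtis(m), seed = 1)
#> NMDS ordination: 40 samples, 2 dimensions, stress-1 = 0.0412
#>   best of 20 restarts; converged: TRUE

rec <- simulateSurvivalRecords(survivalConfig(seed = 1))
juv <- rec[rec$stage == "juvenile", ]
logrankTest(juv, group = "treatment")
#> Log-rank test: chisq = 44.5186 (1 df), p = 2.52e-11
```

Reading: heat-treated simulated larvae roughly quintuple their mean
Shannon diversity as background genera expand (the beta-regression
contrast and the PERMANOVA both flag the community shift; NMDS embeds
it at low stress), and heat-treated juveniles die significantly faster
than ambient ones. With the juvenile heat multiplier at its default of
1, the same alpha/beta tests are null-calibrated — the test suite
checks both directions.

A subcommand CLI wraps the same functions over a file bundle
(`counts.tsv`, `metadata.tsv`, `registry.json`, `survival.tsv`):

```sh
Rscript inst/scripts/symshuffle simulate --seed 1 --out run1
Rscript inst/scripts/symshuffle all --seed 1 --out run1
```

## Acceptance script

`scripts/acceptance.R` regenerates the survival calibration targets
from scratch with the installed package: it simulates 500 heat-treated
juveniles (daily monitoring to day 80) and 500 heat-treated larvae
(daily monitoring to day 120) with the generator's default hazard
parameters, fits the Kaplan–Meier estimator to each, and writes the
two median survival times (days) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
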