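---
title: "Measuring plasmid fitness costs and plasmid-mutation epistasis"
author: "plasmidfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring plasmid fitness costs and plasmid-mutation epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidfit)
```

## The measurement model

A competition assay mixes a test strain 1:1 with a GFP-tagged reference,
dilutes the mixture 1:400 into fresh medium, and lets it grow for one cycle
(for standard rich-medium conditions this regrows to saturation, so the
reference expands by roughly the dilution factor). Flow cytometry records
10,000 events before and after the cycle, splitting them into GFP-negative
and GFP-positive classes. The relative fitness of the untagged strain is
the ratio of log fold-changes,

$$W = \frac{\log(N_{f,gfp-}/N_{i,gfp-})}{\log(N_{f,gfp+}/N_{i,gfp+})},$$

with $W = 1$ meaning the two competitors grew equally. Natural logs are
used throughout; any base gives the same $W$.

**Counts must share one scale.** The cytometer yields proportions, not
absolute numbers. $W$ is invariant to multiplying all four counts by one
positive constant, but it is *not* invariant to rescaling one timepoint
relative to the other: multiplying the final counts by $b$ and the initial
counts by $a$ shifts numerator and denominator by the same additive
$\log(b/a)$, which changes the ratio. Concretely,
`relativeFitness(1000, 1000, 1600000, 400000)` is 1.2314, but scaling the
finals by 2 gives 1.2074. So converting event proportions into "numbers of
cells" requires putting both timepoints on one cells-per-volume scale with
the population's total growth included; `fitnessTable()` assumes its inputs
satisfy this, and the simulator constructs its observed counts that way
(event proportions times the realized total expansion). If only
proportions are available, an assumed common expansion factor must be
supplied explicitly — it does affect $W$ away from neutrality.

**Normalization cascade.** The GFP insertion itself may carry a cost, so
fitness is reported relative to the plasmid-free wild type: the median of a
strain's replicates is divided by the median of the wild-type control
group. The order is fixed and each level is idempotent. Per-replicate
normalized values divide every replicate by the control *median* (the
cascade pairs medians, not replicates — replicate pairing would impose an
arbitrary matching the assay design does not define). A third,
presentational level divides combination strains by the plasmid-carrying
wild type (`normalizeToPlasmidCarrier()`). Medians of an even number of
replicates are the mean of the two central order statistics. Costs are
percentages, $(1 - W)\times 100$; negative cost is a benefit.

## Epistasis against the multiplicative null

Independent fitness determinants are expected to combine multiplicatively.
For a plasmid $p$ and a chromosomal mutation $m$,

$$\varepsilon = W_{(p;m)} - W_{(p;-)}\,W_{(-;m)},$$

where the marginals are the median fitness of the plasmid-carrying wild
type and of the plasmid-free mutant. Positive $\varepsilon$ means the
double-determinant strain is fitter than expected (the plasmid is *less*
costly in the mutant background); negative $\varepsilon$ is an aggravated,
synergistic cost.

Per-replicate $\varepsilon$ values subtract the product of the marginal
*medians* from each combination replicate — the marginals are defined as
medians, so they are shared across a group rather than paired per
replicate. The wild type's $\varepsilon$ replicates are $W - 1$.
Classification runs a one-way ANOVA across all $\varepsilon$ groups
(combinations plus wild type) followed by Tukey's HSD; each combination is
called by the sign of its median $\varepsilon$ when its Tukey-adjusted
contrast against the wild-type group has $p < \alpha$ (default 0.05). The
Tukey family is one panel of combinations per analysis; separate mutant
panels should be analysed as separate families. A combination whose median
$\varepsilon$ is exactly 0 with $p < \alpha$ is a measure-zero tie and is
called "none" with a warning rather than given an arbitrary sign.

Two deliberate numerical points:

* **The wild type's median $\varepsilon$ is zero by definition** — its
  group is normalized by its own median. Recomputing that zero through
  floating point leaves a last-ulp residual for even replicate counts
  (median of ratios is not bitwise the ratio of medians), so the reported
  value evaluates the identity ($m - m$) instead; the replicate
  $\varepsilon$ values themselves are untouched.
* **Calibration of the classification.** Because every replicate in a
  group shares the same estimated marginal product, estimation error in
  the marginals shifts whole $\varepsilon$ groups coherently — variance the
  ANOVA residual cannot see. The per-classification false-call rate at the
  default design is therefore above the naive per-contrast Tukey level
  (about 1.4% at $\alpha = 0.05$ in the package's own 200-experiment null
  simulation), and the probability that at least one combination in an
  18-combination panel is miscalled is higher still (about 20%). This is a
  property of testing replicate $\varepsilon$ groups against the wild type
  with plug-in marginals; the error-propagation mode
  (`epistasisErrorPropagation()`), which bootstraps the marginal medians
  and propagates their variance, is provided as a cross-check.

**Sign epistasis** asks a stronger question: is the combination
significantly fitter than *both* the plasmid-free mutant and the
plasmid-carrying wild type? `testSignEpistasis()` runs ANOVA + Tukey over
the three strains and requires both contrasts positive with adjusted
$p < \alpha$.

## Sequence features

The per-plasmid quantities screened against cost are replicon size, GC
content, mean per-ORF codon adaptation index, and copy number.

*CAI.* `buildWeightTable()` converts a codon-usage table (EMBOSS `.cut`
layout or 2-column TSV, auto-detected) into relative-adaptiveness weights:
within each synonymous family of the standard genetic code the most used
codon gets weight 1 and the rest their usage ratio. Zero-frequency sense
codons are floored at $w = 0.01$ — the standard convention, preventing a
single unused codon from collapsing CAI to 0 — and single-codon families
(ATG, TGG) carry weight 1. `cai()` is the geometric mean
$\exp(\overline{\ln w})$ over an ORF's codons: the terminal stop is
excluded, internal stops are excluded with a warning, codons containing
ambiguous bases are skipped and counted. `defaultCodonTable()` is a
deterministic *synthetic* reference (GC-rich third positions preferred with
geometrically decaying counts), suitable for simulation and testing; real
analyses should supply a measured reference table for the host.

*Copy number.* The mean per-position sequencing depth of the plasmid
divided by the chromosome's — scale-invariant, so it can be computed from
any uniformly processed depth table (`replicon`, `position`, `depth` TSV,
1-based).

*ORF extraction* is strand-aware (minus-strand features are
reverse-complemented) and supports origin-spanning features on circular
records, represented as `end > length` and written/read as two-segment
`join()` locations in the package's minimal GenBank reader/writer.

*The screen.* `spearmanRho()` correlates each feature with plasmid cost
using average-tie ranks. For fewer than 10 plasmids — the realistic panel
size — the two-sided p value comes from the exact permutation distribution
of $\rho$ (all $n!$ orderings), which handles ties exactly; larger panels
use the $t$ approximation with $n-2$ degrees of freedom. With six or seven
plasmids only $|\rho|$ near 1 can approach significance; the screen is a
guard against strong monotone confounders, not a powered association test.

## What the simulator emulates — and what it does not

`simulateExperiment()` generates one replicate block per genotype. Per
replicate:

1. latent initial counts are an exact 1:1 mixture;
2. the reference expands by $G$ (`expansionFactor`, default 400, the
   dilution factor regrown to saturation) and the test strain by
   $G^{w}$ — this fold-expansion law makes the estimator exact in the
   noise-free limit, which is the ratio-of-Malthusian-parameters reading
   of $W$ and gives the package a machine-precision round-trip test;
3. optional mean-one lognormal noise (sd `growthNoiseSd`, default 0)
   multiplies each competitor's fold-expansion independently —
   multiplicative noise is the minimal conventional model for growth
   variability;
4. each measurement draws `eventsPerMeasurement` (default 10,000) events
   from the latent proportions as a two-class multinomial, and the event
   counts are rescaled to the latent cell-number scale so observed counts
   honour the common-scale requirement above.

Defaults mirror the standard design: 6 replicates per genotype, 36 for the
wild type. Combination genotypes get $w_p w_m$ plus an optional additive
`epistasisShift`. Every record's seed is a stable hash of (master seed,
genotype, replicate), so datasets are reproducible independently of
generation order, and all outputs are byte-identical across reruns.

Not modelled: doublet/debris cytometry classes (gating is upstream of this
package), plasmid loss or conjugative transfer during the competition
(verified below 1% in the motivating experiments), segregational dynamics,
and induction kinetics. Passing tests on simulated data therefore show the
*analysis chain* is correct under the stated noise model — they do not
validate gating, nor detect biological artefacts like transfer during
competition.

`simulatePlasmidRecord()` builds circular records with a target GC
(intergenic composition compensates the ORF load, so realized GC lands
within about 1% of target for records of 10 kb and larger) and ORFs with
correct grammar (ATG start, stop end, length divisible by 3, random
strand); `codonBiasStrength` interpolates between uniform synonymous codon
choice (0) and always-optimal (1, giving CAI exactly 1).
`simulateDepthTable()` draws lognormal per-position depths with a chosen
coefficient of variation around means whose ratio is the true copy number.

## Statistical engines

ANOVA, Tukey's HSD and the underlying distributions are delegated to R's
`stats` (`aov`, `TukeyHSD`, `oneway.test` with `var.equal = TRUE` — the
classical, non-Welch form). The package's wrappers fix the contracts:
`oneWayAnova()` returns $F$, both degrees of freedom and $p$;
`tukeyPairwise()` returns all pairwise contrasts with family-wise adjusted
p values (at $k = 2$ this collapses to the equal-variance two-sample
comparison, which the tests verify). The Spearman implementation is the
package's own because of the exact small-$n$ permutation requirement; it is
cross-checked against `cor.test` where both are exact.

## Problem sizes and tolerances

The package's own verification uses: estimator round trips at
$w \in \{0.5, 0.7, 0.9, 1.0, 1.2\}$ checked to $10^{-12}$; 500 simulated
six-replicate experiments for the sampling-consistency check (median
estimate within $\pm 0.02$ of a true 0.8); 200 simulated experiments each
for the null-calibration and epistasis-recovery studies at a 6-plasmid
$\times$ 3-mutation design; 50 random ORFs against a brute-force CAI
oracle; 1000 simulated null ANOVAs for p-value uniformity. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bands while
keeping a full verification run to a few minutes on one core.

## Known limitations

* Real cytometry data contain gating artefacts, carryover and
  instrument drift that the two-class multinomial model does not capture.
* The ANOVA/Tukey classification inherits the plug-in-marginal calibration
  property described above; for designs with very many combinations per
  family, the error-propagation mode gives a complementary view.
* The depth-ratio copy-number proxy assumes uniformly processed,
  mapping-bias-free depths; GC-dependent coverage bias is not corrected.
* The GenBank reader is deliberately minimal (LOCUS, CDS with plain,
  `complement()` and two-segment origin-spanning `join()` locations,
  ORIGIN); records with exotic location operators should be simplified
  upstream.

## A compact session

```{r example, eval = FALSE}
cfg <- list(mode = "simulate",
            plasmids  = list(pA = 0.85, pB = 0.70),
            mutations = list(m1 = 0.75),
            epistasisShift = list("pA:m1" = 0.10),
            replicates = 6, wildtypeReplicates = 36, seed = 4)
res <- runPipeline(cfg, outputDir = "out")
res$epistasis
cat(res$report, sep = "\n")
```
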