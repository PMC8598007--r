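---
title: "Lineage-selective drug response and splicing concordance with glueSelect"
author: "glueSelect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage-selective drug response and splicing concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glueSelect)
```

# Motivation

Molecular-glue degraders such as indisulam act by recruiting a target
protein (the splicing factor RBM39) to an E3 ubiquitin ligase for
degradation. When such a compound appears unusually toxic to one cancer
lineage in a pooled viability screen, two statistical questions follow.
First, is the apparent selectivity larger than what random assignment of a
handful of cell lines would produce? Second, if the compound works by
degrading a splicing factor, does pharmacologic treatment reshape splicing
the same way genetic knockdown of that factor does? `glueSelect` implements
both analyses over standard file formats, plus the gene-dependency lineage
comparison that usually motivates the hypothesis, and synthetic-data
generators that emulate all three kinds of input.

# The lineage-selectivity permutation test

For a compound with responses pooled over n cell lines, k of which belong
to the target lineage, the selectivity statistic is the difference of group
means

$$\Delta = \bar{x}_{\text{target}} - \bar{x}_{\text{rest}},$$

computed per compound over its non-missing values only (pooled screens have
ragged coverage; a compound measured in 541 of 568 lines is compared within
its own 541). On the log2 fold-change scale a negative Δ means the target
lineage is hit harder. The null distribution holds the compound's pooled
values fixed and re-draws which k of them are called "target": a random
k-subset without replacement, which is the exact exchangeability null for
the lineage labels. When $\binom{n}{k}$ is at most `exhaustiveLimit`
(default $10^5$) every assignment is enumerated and the exact tail fraction
is reported; otherwise B Monte-Carlo draws (default $10^5$) are taken and
the add-one estimator

$$\hat{p} = \frac{1 + \#\{\Delta^* \le \Delta\}}{1 + B}$$

is used. The add-one form is the standard validity correction for sampled
permutation tests: it can never return 0, and its smallest attainable value
is $1/(B+1)$. The default alternative is one-sided ("less"), because the
analysis ranks compounds by selective *toxicity*; a two-sided variant
(doubled and capped) and the mirrored "greater" tail are available by flag.

Compounds are ranked by ascending Δ — rank 1 is the most selectively toxic
— with ties broken by smaller empirical p and then compound ID. Compounds
with fewer than 2 target or 2 non-target values (configurable) are reported
with `status = "insufficient_data"` and no rank; the screens this is
designed for do not document how singleton-coverage compounds were handled,
so the package makes the conservative choice explicit rather than silent.

Each compound's Monte-Carlo stream is seeded from a hash of
(global seed, compound ID), which makes results independent of compound
iteration order and lets any single compound be recomputed in isolation.

Screen files are cleaned before analysis by removing every cell line whose
identifier contains the failure marker (`FAILED_STR` by default, the
convention used in the PRISM Repurposing screen distributions). For
dose-response AUC files that report one row per (line, compound, screen),
`selectSecondaryScreen` keeps the screen the distributor recommends
(`MTS010` by default) with an explicit fallback list.

# The gene-dependency comparison

`lineageSummary` reports per-lineage mean ± SD of a gene's dependency
scores (DEMETER2 convention: more negative = more dependent), and
`targetVsRestTest` tests one lineage against all others pooled. The
comparison the motivating figure draws does not name its test; Welch's
unequal-variance t is the package default because the 25-lineage setting
has very unequal group sizes and variances, with Wilcoxon rank-sum as an
option. Because the original test is unidentified, reproducing its exact
p-value is not promised; panels of genes get a Benjamini–Hochberg adjusted
column. "Rest" pools all non-target lineages; per-lineage pairwise
comparison is the caller's composition of `targetVsRestTest` over labels.

# The junction-concordance chain

Starting from STAR `SJ.out.tab` files (9 tab-separated columns, 1-based
inclusive intron coordinates), the chain is:

1. **Unify**: rows are the union of junction keys (chromosome, intron
   start, intron end, strand code) over all samples; a junction absent from
   a sample is 0 — SJ tables enumerate observed junctions, so absence is an
   observed zero, not missingness. Only uniquely-mapped read counts are
   used; multi-mapped counts are ignored.
2. **Normalize**: each sample's vector is scaled by its own total unique
   junction reads within the unified matrix, times $10^6$. The total is
   necessarily the within-matrix total: SJ tables do not carry the
   library's total mapped reads, and the chain operates on junction vectors
   only.
3. **Average** replicate samples within each genotype (arithmetic mean of
   the normalized vectors).
4. **Filter**: drop junctions whose summed normalized count across all
   genotype columns is *smaller than* 10 — the boundary value 10 is
   retained. The sum runs over all genotypes in the analysis set, not just
   the pair being correlated, so every pairwise correlation is computed on
   one common junction set.
5. **Correlate**: Pearson r for each genotype pair, with two-sided
   significance from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of
   freedom, n the number of retained junctions.

The chain is a state machine (`raw → normalized → averaged → filtered`);
each step verifies its input state, so steps cannot be reordered silently.

Two correlation modes are provided because the underlying question is
genuinely ambiguous: `direct` correlates the genotype vectors as stated,
while `delta` correlates treatment-minus-control difference vectors, which
isolates the *altered* component of splicing and is the better match for
"do two perturbations change the same junctions". Neither is asserted to be
the original authors' choice; `direct` is the default as the literal
reading. Direct-mode r between RNA-seq libraries of the same cell line is
dominated by the shared abundance profile and sits near 1 regardless of
perturbation; delta-mode r is the discriminating quantity, and the
acceptance checks show it rises strictly with the fraction of junctions two
perturbations share. No log transform is applied by default.

# rMATS post-processing

Events are read per category (SE, A5SS, A3SS, MXE, RI) from standard rMATS
result tables. Significance filtering keeps events with FDR < 0.05 **and**
|ΔPSI| > 0.1, both bounds strictly exclusive as the thresholds are
conventionally quoted; inclusive variants exist but are not default. Events
with missing ΔPSI cannot be assessed and are dropped with a recorded count.
Event identity for cross-run overlap is the full coordinate tuple plus
category, chromosome and strand — never the run-local numeric ID, which is
not stable across rMATS runs. Concordance between two comparisons is the
Spearman correlation of ΔPSI over shared events (average ranks for ties,
two-sided p).

# What the simulators emulate — and what they do not

`simulateScreen` draws responses i.i.d. Normal(0, σ₀) with σ₀ = 0.5 by
default and adds a planted shift δ (default −1.3, the magnitude of a
strongly lineage-selective compound on the log2FC scale) to selective
compounds in the target lineage; the default design plants 5 target lines
among 541, mirroring the indisulam case (5 neuroblastoma vs 536 other lines
with coverage). Normal noise is a deliberate modeling choice — collapsed
log2 fold changes are approximately symmetric — not a claim about the real
screen, which has heavier tails, correlated compounds and structured
missingness. Passing the calibration and recovery tests therefore shows the
statistic and its null are implemented correctly, not that real screens are
this clean.

`simulateJunctions` gives junctions log-normal(μ = 3, τ = 1.5) abundance
weights and negative-binomial counts (dispersion 0.05) around
depth × relative weight, with a fixed per-junction fold direction (×4 or
÷4) applied to each genotype's perturbed set — so genotypes sharing a
perturbed junction move it concordantly, which is what makes the
shared-fraction sweep meaningful. Real junction tables additionally exhibit
positionally correlated junctions (shared splice sites), annotation
structure, and library-size variation far beyond the simulated range.

`simulateRmatsTables` plants exact significant-event counts and overlaps,
and draws shared ΔPSI pairs from a Gaussian copula with the Pearson
parameter set to $2\sin(\pi\rho_s/6)$ so the *Spearman* correlation equals
the requested ρ after the monotone map onto ±(0.1, 0.95]. Background events
get |ΔPSI| < 0.1 and p ≥ 0.1, so the planted set is exactly what the
standard filter recovers — by design, to make count recovery testable
exactly.

All generators restore the caller's RNG state and are byte-identical given
the same seed.

# Numerical and design choices

* Empirical p-values in sampled mode are never 0 (add-one); exhaustive mode
  returns the exact tail fraction, which is positive whenever the observed
  assignment is itself one of the enumerated subsets.
* Lineage labels are matched after case-folding and whitespace trimming;
  unannotated cell lines are dropped with a logged count.
* The low-total junction filter uses `>= threshold` retention so that the
  quoted "smaller than 10" exclusion has an exact, testable boundary.
* Zero-variance columns in correlation yield `NA` with a warning rather
  than propagating `NaN`.
* Welch t rather than Student t wherever group variances are not assumed
  equal; BH for multiplicity across gene panels.
* Problem sizes in the shipped checks (e.g. permutation sweeps at
  n ≤ 12, k ≤ 4 against exhaustive enumeration at B = 10⁵; 1000-compound
  null calibration at B ≈ 2000; 100-replicate concordance sweeps at 400
  junctions) were chosen as the smallest designs at which each property is
  statistically identifiable; the full-scale defaults (B = 10⁵ draws)
  remain the package defaults.

# Pipeline orchestration

`validateConfig` resolves a YAML configuration against explicit defaults,
rejecting unknown keys and out-of-range values by name. `runPipeline`
executes the selected stages into a run directory with TSV/JSON outputs and
a manifest recording the seed, effective parameters and md5 digests of
every stage's inputs and outputs; a stage whose digests all match is reused,
and a corrupted intermediate is detected and recomputed. One global seed
feeds per-stage (and per-compound) derived substreams, so stages are
independently reproducible. A thin wrapper in `inst/scripts/run-pipeline.R`
maps configuration, data and runtime errors to distinct exit codes.

# Known limitations

* The package post-processes rMATS output; it does not re-derive PSI
  inference, nor fit dose-response curves, nor collapse screen replicates.
* Junction normalization cannot use total mapped reads (not present in
  SJ tables); comparisons against analyses normalized that way will differ
  by a per-sample scale factor.
* The dependency comparison treats cell lines as the unit of analysis;
  if the original comparison used lineage-level means, its p-values will
  differ.
* Exhaustive-vs-sampled equivalence is only checked where enumeration is
  feasible; for large $\binom{n}{k}$ correctness rests on the sampled
  estimator's construction.

# Session

```{r}
sessionInfo()
```
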