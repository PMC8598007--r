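# glueSelect

Tools for asking, and answering reproducibly, two questions that come up when
a molecular-glue degrader (such as the RBM39 degrader indisulam) looks
promising in one cancer lineage:

1. **Is the compound's toxicity selective for that lineage?** Given a pooled
   viability screen (compounds × cell lines, log2 fold change vs vehicle or
   dose-response AUC), `glueSelect` computes for every compound the
   target-vs-rest mean difference
   Δ = mean(target-lineage responses) − mean(all other responses)
   and an empirical p-value from a permutation null: random k-subsets of the
   compound's own pooled values take the role of the target group
   (exhaustively enumerated when `choose(n, k)` is small, otherwise
   Monte-Carlo with the add-one estimator
   p̂ = (1 + #{Δ\* ≤ Δ}) / (1 + B)). Compounds are ranked by ascending Δ.
   The same comparison is provided for gene-dependency scores (DEMETER2
   convention) via Welch's t or rank-sum tests.

2. **Do genetic and pharmacologic loss of the target perturb splicing the
   same way?** From STAR `SJ.out.tab` junction tables, `glueSelect` builds a
   unified junction × sample read matrix (union of junction keys, unique
   reads only), normalizes each sample to reads-per-million (×10⁶), averages
   replicates within genotypes, drops junctions whose total normalized count
   is below 10, and computes pairwise Pearson correlations between genotypes
   (directly or on treatment-minus-control difference vectors), with
   significance from the t transform t = r·√(n−2)/√(1−r²). rMATS
   differential-splicing tables are post-processed with the standard
   FDR < 0.05 and |ΔPSI| > 0.1 filters, counted per event category
   (SE/A5SS/A3SS/MXE/RI), overlapped across comparisons on coordinate-based
   event identity, and compared by Spearman correlation of ΔPSI.

Deterministic synthetic-data generators (`simulateScreen`,
`simulateJunctions`, `simulateRmatsTables`, `simulateDependency`) emit every
input format with ground-truth ledgers, so the entire pipeline runs and is
testable with no external downloads.

## Worked example

```r
library(glueSelect)

# a screen with 5 target-lineage lines among 200, one compound planted
# with a -2 log2FC lineage-selective shift
sim <- simulateScreen(nCompounds = 50,
                      lineageSizes = c(neuroblastoma = 5, other = 195),
                      nSelective = 1, effectSize = -2, noiseSd = 0.5,
                      seed = 1)
res <- selectivityScreen(sim$screen, "neuroblastoma",
                         PermutationConfig(nDraws = 1999, seed = 1))
head(as.data.frame(res)[order(res$rank), c("compoundId", "meanDiff",
                                           "pEmpirical", "rank")], 3)
#>    compoundId   meanDiff pEmpirical rank
#> 1     CPD0001 -1.9878657     0.0005    1
#> 34    CPD0034 -0.4249666     0.0255    2
#> 46    CPD0046 -0.3982016     0.0350    3
```

The planted compound is recovered at rank 1: its mean difference (−1.99) is
the average log2 fold-change gap between the target lineage and the rest,
and the empirical p-value 5×10⁻⁴ is the smallest value the add-one
estimator can return at B = 1999 draws — none of the permuted assignments
produced so extreme a difference.

```r
# junction concordance between two perturbations hitting the same junctions
sets <- sharedPerturbedSets(400, 80, f = 1, seed = 1)
js <- simulateJunctions(nJunctions = 400,
                        genotypes = c(control = 2, g1 = 2, g2 = 2),
                        perturbed = list(g1 = sets$a, g2 = sets$b),
                        seed = 2)
junctionConcordance(js$samples, js$groups, mode = "delta",
                    control = "control")
#> DataFrame with 1 row and 7 columns
#>         a   b       r nJunctions       t  df            p
#> 1      g1  g2 0.97495        398 87.2272 396 1.24812e-260
```

Two genotypes that perturb the same 80 junctions correlate at r ≈ 0.97 in
delta mode (398 junctions survive the low-count filter; the t transform
gives the two-sided p).

An end-to-end run over all stages, driven by a YAML configuration with a
manifest of parameters and file digests:

```r
runPipeline(validateConfig("run.yaml"))   # or scripts in inst/scripts/
```

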