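# mixturetox

Comparative whole-mixture toxicogenomics for developing zebrafish.

Passive-sampler extracts from contaminated waterways are complex chemical
mixtures. A practical way to rank their hazard without exhaustive chemical
characterization is to expose developing zebrafish (*Danio rerio*) to
extract dilutions, score morphological endpoints, profile the larval
transcriptome by RNA-seq, and summarize the extract chemistry (PAH totals
and source-diagnostic ratios). `mixturetox` implements that comparative
analysis as a tested, reusable R pipeline for toxicologists comparing two
or more environmental mixtures:

- **Differential expression.** Per-gene negative-binomial GLM
  (log link, median-of-ratios size factors as offsets) with a *single
  dispersion shared across all treatment groups*, estimated by maximizing
  a Cox–Reid-adjusted profile likelihood for α in
  `var = μ + αμ²`; Wald test per treatment-vs-control contrast;
  Benjamini–Hochberg adjustment; DEGs at `|log2FC| ≥ 1` (heatmaps/PCA) or
  `≥ 0.5` (gene-set analysis) with `p_adj ≤ 0.05`. A classical-MDS screen
  flags outlying samples (distance to group centroid > median + 3·MAD).
- **Cross-mixture comparison.** Direction concordance over the DEG union;
  the effect-size ratio between mixtures by regression through the origin
  (`b = Σxy/Σx²`, no-intercept `r² = 1 − RSS/Σy²`); heatmap structure via
  k-means (k = 8, 500 random-partition starts) and average-linkage
  treatment ordering; treatment-level PCA on the DEG log2FC matrix.
- **Gene-set overrepresentation and topology.** Three-way DEG partition
  (A-only / shared / B-only); upper-tail hypergeometric test against
  15–400-gene terms with BH control per (query, namespace); enrichment-map
  network with overlap-coefficient edges
  (`C = |A∩B| / min(|A|,|B|) ≥ 0.4`) and connected-component clusters;
  term-redundancy reduction by complete-linkage clustering on Jaccard
  distance (`< 0.45` merges, merged term named after its smallest member).
- **Developmental screen statistics.** Plate QC (fail when control
  mortality exceeds 2/8), exact Clopper–Pearson incidence intervals,
  two-sided Fisher's exact comparisons, per-endpoint profiles at a chosen
  dilution.
- **Chemistry summaries.** ΣPAH with propagated t-intervals (replicate
  variance, optionally borrowed from a reference sample), FLA/PYR,
  RET/CHR and PHE/ANT diagnostic ratios, composition profiles.
- **Synthetic data with planted truth.** NB counts where mixture B's
  per-gene log2 effects are `β·θ + ε` of mixture A's (default β = 0.59),
  gene sets with planted coherent regulation, binomial dose-response
  screens (n = 40/dose), and paired chemistry profiles differing by a
  scale factor — all reproducible from one master seed, with every latent
  quantity recorded for parameter-recovery tests.

## Worked example

```r
library(mixturetox)

truth <- synthTruth(4000, beta = 0.59, alpha = 0.05, seed = 42)
sim   <- simulateCounts(truth, samplesPerGroup = 3)

alphaHat <- estimateCommonDispersion(sim$counts)
alphaHat
#> [1] 0.0512269

cA <- nbWaldContrast(sim$counts, "mixtureA", "control", alphaHat)
cB <- nbWaldContrast(sim$counts, "mixtureB", "control", alphaHat)
length(classifyDegs(cA)); length(classifyDegs(cB))
#> [1] 319
#> [1] 276

directionConcordance(cA, cB)[1:3]
#> $n_union          387
#> $n_discordant     16
#> $n_discordant_both_significant  0

lfc <- buildLfcMatrix(list(mixtureA = cA, mixtureB = cB))
reg <- originRegression(lfc[, "mixtureA"], lfc[, "mixtureB"])
sprintf("slope %.3f (95%% CI %.3f-%.3f), r2 %.2f", reg$slope,
        reg$ci[1], reg$ci[2], reg$r2)
#> "slope 0.589 (95% CI 0.558-0.619), r2 0.79"
```

The estimated dispersion recovers the planted 0.05; the origin-regression
slope recovers the planted effect ratio 0.59: mixture B perturbs the same
genes as mixture A, in the same directions, at about 59% of the
amplitude — the signature of two extracts sharing a contamination source
at different intensities. `runDemo()` (or `runPipeline()` with a YAML
config) runs the whole chain — MDS screen, contrasts, concordance,
heatmap structure, PCA, three-way enrichment, enrichment map, term
reduction, screen and chemistry summaries — and writes every table plus a
manifest that makes the run byte-for-byte reproducible.

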