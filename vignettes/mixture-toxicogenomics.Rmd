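---
title: "Methods: comparative whole-mixture toxicogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative whole-mixture toxicogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixturetox)
```

# The analysis problem

Two passive-sampler extracts from nearby river sites are complex,
partially overlapping chemical mixtures. The comparative question is not
"which genes respond to extract X" in isolation but *how similarly* the
two mixtures perturb a developing vertebrate, and whether the differences
are a matter of intensity (the same toxic program, scaled) or of kind
(distinct programs). `mixturetox` answers this with four coupled analyses
on a shared experimental design — a vehicle control plus one group per
exposure, with two to four replicate pools of embryos each:

1. per-treatment differential expression against the shared control,
2. cross-mixture comparison of the per-gene log2 fold changes,
3. gene-set overrepresentation and network topology of the enriched
   terms, and
4. organism-level anchors: developmental-screen statistics and extract
   chemistry.

# Differential expression model

Counts for gene $g$ in sample $j$ are modeled negative-binomial with mean
$\mu_{gj}$ and a **single dispersion $\alpha$ shared by all genes and
groups**, in the standard RNA-seq parameterization
$\mathrm{Var} = \mu + \alpha\mu^2$. With only two or three replicates per
group a per-gene dispersion is hopeless; a common dispersion pooled
across all treatment groups borrows strength from every gene and is the
classical small-$n$ choice. The price is that genuinely
high-variability genes are tested liberally and low-variability genes
conservatively; the package accepts that trade deliberately and states
it here rather than layering on trended/shrunken dispersion estimators.

The per-contrast model is a GLM with log link,

$$\log \mu_{gj} = \beta_{g0} + \beta_{g1}\,x_j + \log s_j,$$

where $x_j$ indicates the treatment group and $s_j$ is a median-of-ratios
size factor (geometric-mean pseudo-reference over genes with all-positive
counts; library-size ratios when fewer than 50 such genes exist, as in
tiny fixtures). The Wald statistic $\hat\beta_{g1}/\mathrm{SE}$ is
referred to N(0,1); `log2FC` is $\hat\beta_{g1}/\log 2$. BH adjustment
runs over all genes with a defined p in the contrast. Genes with zero
counts in both groups are untestable: they carry `NA` and are excluded
from the BH family (including them would only dilute the adjustment with
tests that cannot reject). Genes zero in exactly one group get a reported
`log2FC` from a 0.5 pseudo-count on normalized group means, because the
GLM coefficient diverges; the test statistic still comes from the GLM.

## Dispersion estimation

$\hat\alpha$ maximizes the profile likelihood with per-group plug-in
means $\hat q_{g\cdot} = \sum_j y_{gj} / \sum_j s_j$, **Cox–Reid
adjusted** by $\tfrac12 \log\det(X^\top W X)$ per gene (with one mean per
group this is half the log of each group's summed working weights
$w = \mu/(1+\alpha\mu)$). The adjustment matters: the raw plug-in profile
likelihood is biased low by roughly a factor $(n-1)/n$ per group at
$n = 3$, which would misstate $\alpha$ by a third. Optimization is a
25-point grid on $\log_{10}\alpha \in [-4, 1]$ followed by Brent
refinement in the bracketing interval; a maximum at the lower boundary is
reported as $\alpha = 0$ (no detectable extra-Poisson variation). On
10,000-gene simulations with three replicates per group the estimator
recovers a planted $\alpha = 0.05$ to the third decimal, and it agrees
with edgeR's common-dispersion estimate (an independent implementation of
the same idea) in the test suite.

## Sample outlier screen

Before any testing, classical MDS (the eigendecomposition of the
double-centered squared-distance matrix, via `cmdscale`) embeds samples
from Euclidean distances in log2(CPM+1) space. "Raw reads" for this
purpose are taken as log-CPM rather than raw counts: distances on raw
counts would be dominated by sequencing depth, which the screen is not
meant to detect. A sample is flagged when its distance to its group
centroid exceeds median + 3×MAD (MAD with the usual 1.4826 consistency
constant) of within-group centroid distances pooled across groups.
Flagging is a report, not a removal: with $n = 3$ an outlier drags its
group centroid and inflates its mates' distances, so the analyst should
inspect the flagged set rather than trust automatic exclusion.

# Cross-mixture comparison

**Concordance.** Over the union of DEGs (threshold recorded), a gene is
discordant when its log2FC signs differ between contrasts; "discordant
and significant in both" is the stricter count. Genes missing from one
contrast are counted non-discordant and reported — absence of evidence is
not directional disagreement.

**Effect ratio.** The scalar relating the two mixtures' per-gene effects
is estimated by least squares through the origin,
$b = \sum x y / \sum x^2$, with
$\mathrm{SE} = \sqrt{(\mathrm{RSS}/(n-1))/\sum x^2}$, a $t_{n-1}$
interval, and the no-intercept coefficient of determination
$r^2 = 1 - \mathrm{RSS}/\sum y^2$. Two conventions needed fixing and are
stated here because they change the number: (i) $r^2$ uses the
no-intercept total sum of squares $\sum y^2$, not the centered one —
squared Pearson correlation would give a different value; (ii) $x$ is
the stronger mixture (larger DEG response) and $y$ the weaker, so a
slope below 1 reads "the weaker mixture produces the same program at a
fraction of the amplitude". The through-the-origin form encodes the
scientific null that a gene unmoved by one mixture is unmoved by the
other. Note the regression treats $x$ as fixed; with $x$ itself
estimated, attenuation biases the slope slightly toward zero, which is
visible (≈0.6 vs the planted 0.59 plus noise-order wobble) when the
regression is run on estimated rather than latent effects.

**Heatmap structure.** Genes (rows) are clustered by k-means, k = 8,
keeping the best of 500 starts by total within-cluster SS. Each start
draws a random partition of rows into k groups and begins Lloyd
iterations from the partition means — with per-start seeds derived from
the master seed, so results are reproducible and adding starts can only
improve the best WSS. Treatment columns are ordered by average-linkage
hierarchical clustering on Euclidean distances. A DEG absent from a
contrast has no measured change; its cell is rendered 0 and the number of
imputed cells is reported.

**Treatment PCA.** PCA of the treatment × gene DEG-log2FC matrix,
centered but not scaled (the features share units — log2 fold change —
so unit-variance scaling would only amplify noise genes). Variance
fractions are eigenvalue shares and sum to one. The choice of the DEG
log2FC matrix as the PCA representation is a design decision; published
variance fractions from other representations are not comparable targets.

# Gene-set overrepresentation and term topology

The three-way design splits DEGs (at the looser `|log2FC| ≥ 0.5` cutoff,
which exists precisely to give the set analysis enough genes) into
A-only, shared, and B-only sets. Each query is tested against a
collection filtered to terms with 15–400 in-universe genes — below 15 a
term cannot be meaningfully enriched; above 400 it is too broad to
interpret. The alternate upper bound of 450 used in some figure-style
analyses is available by argument. The **background universe is the set
of genes with a defined DE test result in all contrasts being compared**:
overrepresentation should be judged against what was measurable, not the
whole genome.

The p-value is the exact upper tail $P(X \ge k)$ of the hypergeometric;
the enrichment ratio $(k/n)/(K/N)$ ranks terms. Multiple testing is BH
within each (query, namespace) family. This replaces the proprietary
multi-threshold correction used by some web services, which has no
published closed form suitable for exact reimplementation; BH is the
transparent standard, but published *counts* of significant terms
obtained under other corrections (and other GO releases) are therefore
not reproduction targets for this package.

**Enrichment map.** One node per (term, query) — mirroring displays where
node color encodes the query set — and an edge when the overlap
coefficient $|A\cap B|/\min(|A|,|B|)$ of the terms' in-universe gene sets
reaches 0.4. The overlap coefficient (rather than Jaccard) makes a small
term nested in a large one maximally connected, which is what a
GO-hierarchy-shaped collection needs. Clusters are connected components;
components with more than three terms are flagged and given free-text
annotation slots — themes are a human judgment, and the package
deliberately does not auto-label them.

**Term reduction.** Per treatment and namespace, significant terms are
ranked by enrichment ratio (ties broken by term id for determinism) and
the top 60 kept; the pool is clustered by complete linkage on pairwise
Jaccard distances and cut strictly below 0.45. Complete linkage is the
package's choice where the method description names none: it is the only
standard linkage that *guarantees* every pair inside a merged group sits
within the merge radius, which makes the within-group property checkable
(and checked) in the test suite. The merged term takes the name of the
smallest constituent (fewest in-universe genes, ties lexicographic) — the
smallest term is the most specific description of the shared gene core.
Merging defaults to within-namespace, with pooling available by flag.

# Screen statistics and chemistry

Incidence intervals are exact Clopper–Pearson from beta quantiles
("binomial distribution with n = 40" read as the exact construction);
Wilson is available by flag. Exact intervals are conservative — coverage
≥ 95% by construction, ~96% at p = 0.3, n = 40 — which is the right
failure mode for small-n screens. Fisher's exact two-sided p follows the
probability-mass convention (sum of tables no more probable than
observed), the same rule as `fisher.test`; conventions differ enough
across software that this is stated explicitly. Plate QC fails a plate
when mortality exceeds two fish in either control arm (two exactly
passes). The per-endpoint profile at a chosen dilution sorts by incidence
difference versus control; BH across endpoints is available but off by
default, matching screening practice of reporting single unadjusted
comparisons. "Any effect except mortality" aggregates fish alive at the
end of the window with at least one morphological endpoint.

ΣPAH sums per-analyte replicate means; its variance sums per-analyte
variances of the mean under an independence assumption, with
$t_{r-1}$ intervals ($r$ = replicates). When a sample is unreplicated the
variance may be borrowed from a designated reference sample — the design
in which one extract's triplicates supply the uncertainty for both
reported totals. Because the summed variance estimate pools several
per-analyte variances while the df stays $r-1$, the interval is mildly
conservative; the suite verifies coverage ≥ nominal by simulation.
Values below a configurable LOQ enter totals as zero (flagged) and are
excluded from diagnostic ratios. The bundled 33-analyte panel and default
concentration profile are **synthetic** constructions (so labeled in the
file name): a representative parent+alkyl PAH panel with a
pyrogenic-leaning composition whose totals (190 and 310 µM at the 1%
exposure scale, ratio ≈ 1.63) and diagnostic ratios sit at realistic
values, standing in for measured appendix tables that are not bundled.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the rest of the package is exercised under:

- NB counts, $\mathrm{Var} = \mu + \alpha\mu^2$, default $\alpha = 0.05$
  (a typical common dispersion for pooled-larvae bulk RNA-seq), baseline
  means log-normal(log 100, 1), size factors log-normal(0, 0.1).
- 10% of genes DE in mixture A with $|\theta| \sim U(0.5, 3)$ log2 units;
  mixture B's latent effect is $0.59\,\theta + \varepsilon$,
  $\varepsilon \sim N(0, 0.3^2)$. The 0.59 is the package's planted
  cross-mixture effect ratio; 0.3 gives $r^2$ in the 0.7–0.8 range on
  the DEG union, i.e. strongly but not perfectly correlated mixtures.
  No generative model for these quantities is prescribed anywhere; the
  defaults only need to exercise the pipeline at realistic
  signal-to-noise.
- Gene sets of 15–400 genes; planted "active" terms draw 90% of members
  from same-sign DE genes (100% available), so coherent regulation is
  recoverable but not trivial.
- Screens draw Binomial(40, p) per endpoint/dilution with planted curves:
  saturation at the 1% exposure, a discriminating mid dose (0.675 vs
  0.265 any-effect at 0.2%, the wavy-notochord endpoint driving the more
  toxic mixture's excess), background at the two lowest doses, and
  control/plate-QC rates (negative-control mortality 1.25%/well,
  positive-control 10%) chosen once as realistic screen background.
- Chemistry tables scale one profile by 310/190 with log-normal replicate
  noise of exact mean and CV.

One master seed fans out to fixed per-generator streams
(`deriveSeed`), so modules are independently reproducible and a single
integer pins an entire run.

**What passing tests do and do not show.** The generator matches the
analysis model (NB counts, independent genes, shared size factors). Real
data violate it in known ways: gene–gene correlation, dispersion trending
with mean, batch structure, GO terms with heavily overlapping hierarchies
rather than near-independent draws. Calibration and recovery results here
therefore certify the *implementation* — the estimators recover what was
planted under their own assumptions — not robustness to those
violations. In particular, observed FDR control on independent-gene
simulations is known to degrade under strong positive correlation.

# Numerical choices and degenerate inputs

- GLM fits use `glm.fit` with the negative-binomial family at fixed
  $\theta = 1/\alpha$ (Poisson at $\alpha = 0$), max 100 IRLS iterations;
  SEs come from the expected information $X^\top W X$ at dispersion 1.
  Fit failures yield `NA` p-values rather than aborting a contrast.
- Identical treatment and control give log2FC = 0 and p = 1 to numerical
  tolerance; swapping contrast direction negates log2FC and preserves p
  exactly.
- `cmdscale` on degenerate geometries (all-identical samples) returns
  fewer axes than requested; missing axes are padded with zeros and no
  sample is flagged.
- k-means starts that degenerate (duplicate or empty partition centers)
  are discarded and count against the start budget; `k = 1` reduces to
  the column-mean WSS identity.
- The Jaccard-merge cut uses $h = 0.45(1 - 10^{-9})$ so "distance < 0.45
  merges" is strict; cutree's ≤-cut would otherwise merge at exactly
  0.45.
- Hypergeometric tails use `phyper(k-1, …, lower.tail = FALSE)`; the test
  suite checks all $N \le 30$ configurations against explicit
  combinatorial sums at $10^{-12}$.

# Problem sizes

The shipped tests and the acceptance script run at sizes chosen to make
Monte-Carlo bands tight while keeping a full check fast on one CPU:
5,000-gene null and planted-signal simulations with three replicates per
group for test calibration; 10,000 genes for dispersion recovery; 100
seeds × 1,000 gene pairs for slope-recovery coverage; 50 seeds × 60 terms
for planted-term recovery; 10,000 draws for interval coverage; a
4,000-gene end-to-end run for the pipeline demo. The whole suite
completes in under two minutes; the acceptance script in well under one.

# Known limitations

- The DE module is a deliberate simplification of full
  shrinkage-based RNA-seq pipelines: no dispersion trend, no LFC
  shrinkage, no independent filtering, no count-outlier replacement.
  DEG counts from such pipelines are approximated, not reproduced
  bit-for-bit.
- The common dispersion misstates per-gene variability in both
  directions; interpret borderline genes accordingly.
- The enrichment module assumes pre-propagated annotations in the GMT
  (no GO-DAG reasoning) and tests overrepresentation only — no ranked
  (GSEA-style) statistics.
- The screen module fits no dose–response curve (no EC50/EC80
  estimation); it summarizes observed incidences.
- Graph outputs are data files (GraphML/TSV); layout and visual styling
  are left to dedicated tools.
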