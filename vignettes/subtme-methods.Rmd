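---
title: "Methods: tumor-microenvironment subtyping, scoring, and interaction inference"
author: "subtme package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-microenvironment subtyping, scoring, and interaction inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtme)
```

# Overview

`subtme` implements a pipeline for characterizing tumor-microenvironment
subtypes (subTMEs) from annotated single-cell RNA-seq cohorts and projecting
them onto bulk and spatial transcriptomes. The stages are:

1. **QC and normalization** of gene-by-cell UMI counts.
2. **Module discovery**: cell subtypes whose per-sample relative abundances
   co-vary across tumor samples are clustered into subTME modules.
3. **Scoring**: each subtype gets a signature built from expressing-cell
   fractions; module scores combine signature scores with per-sample
   abundances; bulk samples are scored by single-sample gene set enrichment
   (ssGSEA) over top marker genes.
4. **Cell–cell interaction (CCI) inference** within a module by
   ligand–receptor (L-R) co-expression with permutation significance and a
   cross-pair specificity ranking.
5. **Prognostic modelling**: univariate Cox screening of module marker
   genes, a linear risk score, median-split Kaplan–Meier comparison and
   time-dependent ROC.
6. **Spatial co-localization** of two signatures across spots.

Every stage is exercised against data from the package's own synthetic
cohort generator, which plants the structures the analysis is meant to
find. This vignette documents the model assumptions, the tunable parameters
and their defaults, the numerical choices, and what the synthetic tests do
and do not demonstrate.

# Relative abundance and module discovery

The relative abundance of subtype $s$ in sample $k$ is
$P_{s,k} = n_{s,k} / n_{M(s),k}$, the subtype's cell count divided by the
cell count of its parent major type $M(s)$ in the same sample. Normalizing
within the major type removes gross compositional differences (e.g. biopsy
cellularity) and matches how subtype shifts are described in the field.
When a sample has no cell of $M(s)$ the abundance is *missing*, never zero:
a zero would assert absence that the data cannot support.

Pairwise association across tumor samples uses Spearman correlation
(tie-corrected, pairwise-complete, with a `min_samples = 10` guard) and
Benjamini–Hochberg FDR across all pairs. Samples are restricted to tumors
by default because the co-infiltration structure of interest is a property
of the tumor ecosystem; `tissue` is exposed.

Modules are obtained by average-linkage agglomerative clustering on the
distance $1 - r$ over the full correlation matrix. The literature the
pipeline follows reports hierarchical clustering without stating linkage,
distance, or a cut rule, so those are this package's choices:

* **Average linkage on $1-r$**: parameter-free and robust to single noisy
  edges, the common choice for correlation-pattern clustering.
* **Module count by mean silhouette** over $k \in [2, \min(10, n-1)]$,
  overridable by `k`. Exact silhouette ties (which arise only for
  structureless inputs) resolve to the largest $k$, so a correlation matrix
  with no structure fragments instead of merging unrelated subtypes.
* The conventional edge thresholds $r > 0.3$ and FDR $< 0.05$ are applied
  as a *post-hoc quality flag* (`weakly_assigned`), not a hard pre-filter:
  thresholding before clustering would silently drop subtypes, while the
  flag keeps the partition total and lets the analyst discount weak members.
* All tie-breaking is lexicographic in subtype name, so results are
  invariant to input order.

Tumor-vs-normal enrichment of a module score is a two-sided Wilcoxon
rank-sum test with the direction called at $\alpha = 0.05$
(`compare_module_presence`).

# Signature scores

For gene $g$ and subtype $j$, let $t$ be the lower quartile
(linear-interpolation quantile) of the gene's *nonzero* normalized values
inside the subtype. A cell "highly expresses" $g$ if its value exceeds $t$.
Then

$$S_{g} = 1 - \frac{Q_{g}}{P_{g}},$$

where $P_g$ is the fraction of subtype cells above $t$ and $Q_g$ the
fraction of all other cells above the *same* $t$. Sharing the threshold is
essential: a per-population threshold would make the two fractions (and
hence $S_g$) incomparable. Genes with no nonzero value in the subtype are
ineligible (excluded, not scored $-\infty$); negative scores are retained in
diagnostic tables but never selected. Genes with $S_g > 0.7$ form the
subtype signature and their mean is the subtype score $S_{sub_j}$. The
per-sample module score is

$$S_{subTME} = \frac{1}{n}\sum_{j=1}^{n} S_{sub_j} \times P_{sub_j},$$

with $P_{sub_j}$ the subtype's relative abundance in that sample; subtypes
with missing abundance are skipped and $n$ reduced (flagged `incomplete`).
The lower-quartile direction of the threshold and the per-sample (rather
than cohort-pooled) $P_{sub_j}$ are deliberate readings of an
under-specified recipe; both are stated here because they change the scale,
not the ordering, of scores.

Quantile estimation uses R's default type-7 linear interpolation; the
brute-force oracle in the test suite reproduces it independently.

# ssGSEA

`ssgsea_score` ranks a profile descending, breaking ties by gene name so
the score is deterministic and exactly invariant under strictly monotone
transforms. Walking down the ranking, in-set positions advance a running
statistic by their rank weight $r^\alpha$ (normalized over the set,
$\alpha = 0.25$ by default) and out-set positions retreat it uniformly; the
score is the sum of the running statistic, positive for top-of-ranking
enrichment.

Two normalizations exist. For a single profile, `"range"` divides by the
range of that profile's running statistic. For matrices
(`ssgsea_matrix`, and through it `bulk_subtme_score` and
`spot_signature_scores`), scores are divided by their range *across
samples* — the convention of the standard single-sample GSEA
implementation. The distinction matters: dividing each profile by its own
running-statistic range rescales every sample differently and, in
measurement on synthetic data during design, destroyed roughly half of the
rank information in cross-sample comparisons; the cohort-level form is an
affine transform that leaves rankings and correlations untouched.

Bulk samples are scored per subtype with the subtype's top-10
fold-change markers and averaged over the module's subtypes
(`bulk_subtme_score`); a mean z-score alternative (`method = "mean_z"`) is
provided for sensitivity analyses.

# Marker detection

`find_markers` tests each gene's normalized expression in a subtype against
all other cells with a two-sided Wilcoxon rank-sum test, using mid-ranks
and tie-corrected variance under the normal approximation (no continuity
correction; at single-cell group sizes the correction is negligible and
exact enumeration is infeasible). Ranks are computed once per gene and
reused across subtypes, which is what makes testing every subtype of a
cohort cheap; a unit test pins the p-values to `stats::wilcox.test`.
The reported fold change is the usual
$\log(\text{mean expm1 in} + 1) - \log(\text{mean expm1 out} + 1)$.
Because "fold change > 1" is ambiguous between natural and log scale, the
retention threshold is a knob (`min_lfc`, default 0 = any positive
enrichment, the looser reading). Both Benjamini–Hochberg and Bonferroni
adjustments are reported; filtering uses BH by default.

# Cell–cell interactions

The interaction score of an L-R pair for an ordered (sender, receiver)
subtype pair is the arithmetic mean of the ligand summary (mean normalized
expression in sender cells; minimum over components for complexes) and the
receptor summary, gated to zero when any component is expressed in fewer
than 10% of the cells on its side. These three conventions — mean of means,
minimum over complex components, 10% gate — follow the widely used
permutation-based CCI frameworks and are all configurable.

Significance comes from shuffling subtype labels among the participating
cells (`n_perm = 1000` by default) and recomputing the mean-based score;
the add-one estimator $p = (1 + \#\{null \ge obs\})/(1 + n_\text{perm})$
avoids $p = 0$, and a gated observed score is assigned $p = 1$. The gate is
not applied inside the null: it is a reporting filter, not part of the test
statistic. Counts of significant interactions per subtype pair and a
symmetrized total mirror the usual interaction-count heatmaps.

Specificity ranks pairs by the coefficient of variation (population-SD
convention, so a pair scoring $s$ in one of $m$ subtype pairs and 0
elsewhere has $cv = \sqrt{m-1}$) of their scores across all subtype pairs,
after keeping each subtype's `top_n = 100` highest-scoring interactions.
Cells are optionally subsampled per subtype (default 300) before scoring;
the default is a desk-scale choice, exposed in the API.

# Risk modelling

`univariate_cox` fits one proportional-hazards model per gene via
`survival::coxph` with Efron tie handling (better than Breslow when event
times look discrete) and flags Wald $p <$ 0.05. The linear risk score is
$\sum_x \text{Exp}(mRNA_x)\,\beta_x$ applied to the expression values as
supplied — no internal re-standardization, since published coefficient sets
are meant to multiply reported expression directly; a `standardize` flag
exists for recovery studies on z-scored covariates. The packaged
colorectal-cancer subTME1 model (`crc_subtme1_model()`) carries 11 gene
coefficients and is the worked example used throughout.

Median stratification sends scores strictly above the median to "high" and
ties to "low" (a documented convention; the recipe is silent). Kaplan–Meier
curves and the two-group log-rank test delegate to `survival`. The
time-dependent ROC is the cumulative-case / dynamic-control AUC with
inverse-probability-of-censoring weights from the Kaplan–Meier estimate of
the censoring distribution (Uno-type estimator, left-continuous
$G(t^-)$); with no censoring it reduces exactly to the case/control
Mann–Whitney statistic, which the tests verify.

# Spatial co-localization

Spots are treated as a plain observation matrix; platform-specific binning
or registration is upstream of this package. Two signatures are scored per
spot with ssGSEA and compared by Spearman correlation
(`colocalization`); gene-pair co-expression uses Spearman correlation plus
a per-spot flag "both normalized values > 0" — no threshold is imposed
because none is established.

# The synthetic cohort generator

`simulation_config()` defines the study conditions; its defaults are fixed
and are what the acceptance-level tests run under.

* **Cohort**: 40 samples, 60% tumor (typical of the tumor/normal balance of
  public single-cell cohorts), ~300 cells per sample, 3 major types
  (lymphoid, myeloid, stromal) with 4 subtypes each.
* **Planted modules**: two modules, each recruiting *one subtype from every
  major type*. Cross-major membership is forced by compositional algebra:
  within a major type the Dirichlet proportions of $k$ equal subtypes carry
  a built-in correlation of $-1/(k-1)$, so only cross-major members can be
  independent when the planted coupling is switched off — the null
  condition the generator must also support.
* **Coupling**: per sample, each module draws a latent factor
  $f \sim N(0,1)$; the Dirichlet log-concentration of every member subtype
  is shifted by `module_strength` $\times f$ (default 2, large enough that
  realized within-module Spearman correlations comfortably exceed the 0.3
  edge threshold used downstream).
* **Tumor shift**: module 1's log-concentration is additionally raised by 4
  in tumor samples, emulating a strongly tumor-specific module — the
  populations that define such modules (exhausted T cells, APOE+ TAMs,
  myCAFs) are near-absent in normal tissue, i.e. enriched on a
  presence/absence scale. Relative to the latent-factor SD of 2 this is a
  2-SD effect.
* **Markers**: 10 genes per subtype; a marker is expressed
  (Bernoulli gate) with probability `p_in = 0.8` inside its subtype and
  `p_out = 0.05` outside, with negative-binomial counts (mean 4, size 2)
  when expressed. The gate construction makes the expected expressing-cell
  fractions — and hence the signature scores — analytic:
  $S_g \approx 1 - p_{out}/p_{in} \approx 0.94$.
* **Planted L-R pairs**: ligand/receptor genes expressed broadly at NB mean
  2, up-scaled 3-fold in their sender/receiver subtype.
* **Survival**: exponential event times with hazard
  $h_0 \exp(\sum_g \beta_g z_g)$ on z-scored normalized bulk expression
  ($h_0 = 0.01$); uniform censoring with the horizon solved numerically for
  the target censoring fraction (default 0.3). Exponential times give
  closed-form sanity checks (a Kolmogorov–Smirnov test under the null) and
  clean Cox coefficient recovery.
* **Spatial**: smooth mixing-weight fields built from 12 random sinusoids
  (frequencies up to 4 cycles per slide; enough spatial degrees of freedom
  that two independent fields decorrelate over a few hundred spots),
  logit-scale noise 0.3, signature-gene mean $1 + 8w$, and 800
  heterogeneous background genes so signatures shift ranks gradually
  rather than saturating the top of the ranking. Co-localized signatures
  share one field.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: transcriptome-wide gene–gene
correlation structure, batch and donor effects, doublets, ambient RNA,
annotation errors in the subtype labels, and any dependence between cell
abundance and cell state. The generator validates that the estimators find
the structures they are defined on; performance on real cohorts depends on
upstream clustering and annotation quality, which are inputs here.

# Problem sizes and numerical choices

The test suite runs the full pipeline at the default cohort size (40
samples, ~12,000 cells, 184 genes) over 20 seeds for module recovery,
tumor enrichment, specificity ranking and bulk concordance; permutation
calibration uses 500 null pairs × 1000 permutations; Cox recovery uses
n = 500 samples × 20 seeds. These sizes were chosen so each property is
measured with a few percent Monte-Carlo error while the whole suite runs
in minutes on a laptop.

Degenerate inputs are handled by refusal rather than coercion: mismatched
dimensions, duplicate identifiers, all-censored survival, constant score
vectors, empty signatures and empty QC results all raise informative
errors; skippable degeneracies (tiny clusters, low-overlap signatures,
pairs with too few complete samples) warn and are excluded.

# Known limitations

* Module labels (`module1`, `module2`, ...) are positional; the biological
  naming of modules (immune-suppressive, matrix-remodelling, ...) is the
  analyst's task, supported by the scoring functions but not automated.
* The silhouette cut rule is a reproducible default, not an inference; for
  cohorts with nested or overlapping modules, force `k` and compare.
* The permutation test shuffles labels within one pooled cell population
  and therefore ignores sample-level pseudo-replication; a
  sample-stratified null would be stricter.
* ssGSEA scores are comparable within one matrix (one normalization range),
  not across independently scored matrices.
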