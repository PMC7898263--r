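---
title: "Methods: consensus age-DE, cell typing and the synthetic mammary atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus age-DE, cell typing and the synthetic mammary atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical methods: the
models, the tunable parameters and their defaults, the numerical choices,
what the synthetic generator does and does not emulate, and the design
decisions that were genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The analysis problem

A young-versus-aged mammary scRNA-seq comparison asks two questions per
cell type: *did its relative abundance change?* and *which genes changed
expression?* Both are statistically treacherous in droplet data. Counts
are overdispersed and zero-rich; some zeros are biological silence, others
are dropout. Cells from one mouse are pseudo-replicates — a gene shifted
in a single animal can look "significant" across thousands of its cells.
And proportions are compositional: one type's expansion mechanically
shrinks every other type's share.

The package's answer is a stringent, multi-criteria design: two
independent test engines must agree, the effect must hold in every
young × aged pair of animals, and only adequately detected genes are
considered at all.

## Cell-level quality control

Cells are kept when total UMIs lie in [1,000, 60,000], detected genes in
[500, 2,500], and the mitochondrial UMI fraction is at most 10%
(`qc_thresholds()`). Two conventions are pinned by tests:

* **Boundary inclusivity.** Elimination is defined by strict inequalities
  ("< 1,000", "> 10%"), so a cell exactly at a threshold is *kept*.
* **Degenerate cells.** A zero-UMI cell has mitochondrial fraction
  defined as 0 and can never pass.

Detected means raw count > 0 — the droplet convention; normalization
plays no role in detection. Mitochondrial genes are recognized by a
configurable prefix, `"mt-"` by default (the mouse convention; the data
do not themselves declare the rule). Depth medians use linear
interpolation for even counts, with a `"lower"` option, since either
convention is defensible and the choice matters at desk scale.

The 10% detection floor for differential expression
(`filter_detected_genes`) is applied per comparison — within the cells of
the focal type, a gene must be detected in at least 10% of young or of
aged cells (inclusive "at least"). We deliberately do not apply a global
gene filter: a gene silent in fibroblasts may be informative in luminal
cells.

## Normalization and fold changes

Expression is library-size normalized to `scale_factor` (default 10,000)
counts per cell and log1p-transformed for rank-based testing, scoring and
clustering. *Fold changes are never computed on the log scale*: the shared
estimator is the ratio of de-logged normalized group means with a
pseudocount,

$$\mathrm{fold}(A, B) = \frac{\bar e_A + c}{\bar e_B + c}, \qquad c = 0.01,$$

in normalized-expression units. The pseudocount guards empty denominators;
at 0.01 (one part in 10^6 of a library) it is negligible for any
quantifiable gene but caps the fold change of near-silent genes instead of
letting it diverge. The same estimator serves signature derivation, the
grouped DE criterion and the per-sample DE criterion, so a single
threshold means one thing everywhere.

## The consensus differential-expression procedure

For one cell type, young vs aged, `consensus_de()` computes per gene:

1. **Grouped criterion.** Fold change (aged over young, cells pooled
   within each age group) at least 1.5 in either direction — inclusive,
   "at least" — *and* BH-adjusted p < 0.05 — strict. The fold is evaluated
   once (it is an estimate of effect size, not an engine property); the
   adjusted p must pass *separately under each engine*.
2. **Per-sample criterion.** The fold change recomputed for every young ×
   aged sample pair (12 pairs in the 3 + 4 design) must be at least 1.25
   *in every pair and in the same direction*. A sample contributing fewer
   than `min_cells_per_sample = 3` cells of the type yields NA folds and
   the gene fails, with a logged reason — a deliberate bias toward
   stringency. This criterion is fold-only (no p-value): it is a
   replication requirement across animals, the package's guard against
   pseudo-replication.
3. **Cross-method criterion.** Consensus = grouped(Wilcoxon) ∧
   grouped(ZINB) ∧ per-sample, with direction agreement.

BH adjustment is performed across the genes passing the detection filter
in that comparison, one family per engine. BH was chosen because the
procedure that generated the printed "adjusted p-values" of the source
analyses is the de-facto default of both Seurat and edgeR; it wraps
`stats::p.adjust`.

### The Wilcoxon engine

`wilcoxon_test()` uses midranks for ties. For combined n ≤ 12 the null is
enumerated exhaustively over all group assignments of the observed values
— exact even under ties — with the two-sided p defined by
|U − E(U)| ≥ |u − E(U)|. Above 12 it switches to the normal approximation
with tie-corrected variance and continuity correction (the regime between
13 and 25, where neither rule was prescribed, uses the approximation; at
those sizes it is already accurate to a few permille). A pooled sample
with all values identical gives p = 1. Inside `consensus_de` a vectorized
normal-approximation path handles hundreds of cells per group.

### The ZINB engine

Per gene, counts follow the mixture
$$y_{c} \sim \pi\,\delta_0 + (1-\pi)\,\mathrm{NB}(s_c \beta_{g(c)},\ \phi),$$
with $s_c$ the cell's relative library size, $\beta$ a mean per age group,
and variance $\mu + \phi\mu^2$. `fit_zinb_weights()` runs EM:

* **E-step**: posterior weight $w = P(\text{NB} \mid y)$; $w = 1$ wherever
  $y > 0$ (a positive count cannot be a structural zero).
* **M-step**: $\pi$ = mean posterior structural-zero mass; group means =
  weight-discounted totals; $\phi$ = weighted method of moments, floored
  at 1e-8.
* Convergence when the largest parameter change is below 1e-6, cap 100
  iterations.

**Boundary collapse.** $\pi$ sits on the edge of its space, so under
pure-NB truth its MLE is spuriously positive for about half of all genes.
After EM, each gene's observed-data log-likelihood is compared with the
plain NB fit through a boundary likelihood-ratio screen (null
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$), Bonferroni-controlled at 0.01
familywise across genes. Genes without evidence of zero inflation collapse
to $\pi = 0$ with unit weights — where the weighted test below *is* the
plain NB test, exactly. This is what makes the engine's degenerate limit
an identity rather than an approximation.

**Testing.** `zinb_nb_lrt()` compares the two-group-mean model against the
common-mean model by a weight-discounted NB likelihood ratio. The group
log-means are re-fit by weighted IRLS (scalar Newton with score
$\sum w(y-\mu)/(1+\phi\mu)$ and information $\sum w\mu/(1+\phi\mu)$,
50-iteration cap, non-converged genes get p = NaN); evaluating the LRT at
the EM's moment estimates instead is *not* sound — they are not the NB
MLEs, and the clamped statistic piles mass at p = 1. Dispersion is shared
between null and alternative, profiled under the alternative. The
statistic is referred to $\chi^2_1$; the posterior weights already enter
the log-likelihood, so the effective sample size is the weight total and
no second scaling by $\sum w / n$ is applied — a second scaling would
double-count the discount and break the degenerate-limit identity.

Relative to the zingeR-edgeR framework this engine is a documented
simplification: $\pi$ is mean-independent, dispersion is per-gene moments
without empirical-Bayes trend shrinkage, and exact replication of zingeR's
weight scheme is a non-goal. Calibration is verified empirically: under
exchangeable null simulations both engines' p-values pass
Kolmogorov–Smirnov uniformity and the consensus list is empty (the
acceptance suite computes this over 20 seeds).

## Cell typing

`cluster_cells()`: dispersion-based highly variable genes (variance/mean,
z-scored within 20 mean bins; default 2,000), PCA on the scaled submatrix
(default 30 components), a kNN graph (k = 20) with shared-nearest-neighbor
Jaccard weights, Louvain communities at resolution 1. None of these values
is prescribed by the emulated study; all are exposed and logged, and the
defaults are in the range every toolkit in this field uses. Identical
seeds give identical labels; resolution → 0 provably yields one community.

`score_signature()` is the binned-control module score: the mean
expression of the signature genes minus the mean of control genes sampled,
per signature gene, from the same average-expression bin (25 bins, 100
controls per gene). Signature genes are excluded from their own control
pools; with near-degenerate toy inputs (a single occupied bin) the pool
falls back to the whole bin. Cell-cycle phase calls
(`assign_cell_cycle`) are G1 when both S and G2M scores are ≤ 0, else the
larger score's phase, ties to S — the tie rule is arbitrary and therefore
documented and tested. Mouse-cased S and G2M gene lists ship in
`inst/extdata/`.

`annotate_clusters()` labels each cluster by its best module score.
**Hybrid detection is done on relative marker expression, not on raw
scores** — a deliberate design deviation. Raw module scores inherit each
gene set's expression scale: on a simulated hybrid cluster expressing both
parent programs at 0.6× amplitude, the two parent scores differed by
2.5-fold purely through baseline luck, so any "runner-up within X% of the
maximum" rule on raw scores is unstable. Instead, for every marker gene
the cluster-mean de-logged expression is divided by the best cluster's
mean for that gene and the ratios are averaged per panel entry: 1 means
"full parent-level program", 0 means none, and numerator and denominator
share genes so gene-level scale cancels. A cluster is labeled hybrid
(`"HS-AV"`, panel order fixing the name) when its top two types both reach
`hybrid_rel = 1/3` — half the amplitude at which the simulator's hybrids
express their parents, and far above the ~0.1 cross-expression that pure
clusters show.

## Signatures

`derive_type_signatures()` implements the one-vs-each rule: gene ∈
signature(T) iff against *every* other type the fold is strictly > 1.25
and the within-comparison BH-adjusted Wilcoxon p < 0.05. Setting
`alpha = 1` disables the p filter entirely (so the conjunction degenerates
to a strict argmax of group means — a tested identity), rather than
leaving a `p < 1` edge case. Signatures are disjoint across types by
construction and this is asserted at run time. Types with fewer than 3
cells are excluded with a warning.

`derive_hybrid_signature()` compares the hybrid against each parent
separately; a marker must clear 1.25-fold with adjusted p < 0.05 against
*both*, in the *same* direction. Direction agreement is an interpretation
we make explicit: a gene above one parent but below the other describes a
gradient, not a hybrid marker. The analysis can be restricted to young
cells to separate type identity from aging. `derive_pairwise_markers()`
is the symmetric two-type contrast at 2-fold.

## Composition

`composition_table()` pools cells across samples within an age group and
tests each type as (type vs all other compartment types) × (young vs
aged). Per-sample replicate-aware models (Dirichlet-multinomial and kin)
are deliberately *not* implemented, mirroring the emulated analysis'
stated choice; the caveat of compositional closure — one type's rise
forces apparent falls elsewhere — applies and is documented. Fisher's
exact test uses the probability-mass two-sided rule (sum over tables, at
fixed margins, with point probability ≤ observed; the common convention,
stated because conventions differ), with the sample odds ratio ad/bc (0 or
∞ when one cross product vanishes, NaN when both do; degenerate margins
give p = 1). The chi-square companion is Pearson's with 1 df, no
continuity correction by default (a flag enables Yates), NaN when an
expected count is 0. Proportion fold changes are reported in the direction
of change with a direction tag.

## Over-representation analysis

`ora_hypergeom()` tests each gene set by the upper-tail hypergeometric
P(X ≥ overlap), BH across the collection, reporting sets with FDR < 0.05
ranked by p and truncated at 30 by default. The universe is the genes that
passed the detection filter of the originating DE comparison — the
statistically defensible background, configurable to all annotated genes.
Set membership is intersected with the universe first; sets reduced below
3 genes are skipped. Up- and downregulated genes are tested jointly by
default (a direction split is available); mouse symbols are mapped to
human via a user-supplied two-column table (`map_homologs`), unmapped
genes reported rather than silently dropped.

## The synthetic atlas generator

`simulate_atlas()` emulates the *statistical structure* the analysis
assumes: 3 young and 4 aged samples of 1,200–2,800 cells; twelve cell
types mirroring the mammary roster (myoepithelial, luminal HS/AV, the rare
HS-AV hybrid, fibroblasts, vascular/lymphatic endothelium, pericytes and
four immune types) with planted proportion shifts encoding the emulated
age effects (epithelium 45% → 82% of cells; within it AV 26% → 69%, HS
53% → 9%); per-type marker programs at 8-fold, hybrids expressing both
parents at 0.6×; planted age-DE genes at |log2FC| = 1 in the four most
abundant types; ZINB counts (φ = 0.4, π = 0.1 — conventional values, the
study reports no per-type dispersions) with lognormal library sizes
(median ≈ 5,500, matching the reported depth) and lognormal(0, 0.1)
per-sample-per-gene random effects. A *scalar* per-sample shift would
cancel under library-size normalization; the per-gene form is what makes
the per-sample criterion genuinely restrictive. Mitochondrial genes carry
a per-cell lognormal budget (mean 5%, sdlog 0.45) so a realistic tail of
cells violates the 10% rule and QC is exercised. Optional doublets are
sums of two cells' draws with truth flags (injection only; detection is
out of scope). Baselines are gamma(0.6); marker and planted-DE baselines
are floored at the gamma median because a planted program on a gene with
~10⁻⁴ relative expression is unexpressed and unrecoverable by any method —
the floor is what makes planted truth mean something.

What it does *not* emulate: ambient RNA, batch chemistry, UMI collision,
cell-cycle structure, mean-dependent dropout (π is mean-independent, the
same assumption the DE engine makes) and spatial or lineage structure. A
green pipeline on these simulations therefore demonstrates correctness of
the *procedures* under the stated model, not robustness to every artifact
of real droplet data.

Determinism: all randomness flows from one integer seed
(`withr::with_seed`); identical config + seed gives bit-identical counts.

## Problem sizes and study designs used by the tests

The acceptance suite runs three designs, chosen as desk-scale versions of
the study conditions: the *study-conditions atlas* (12 types, 1,200–2,800
cells/sample, 2,000 genes) for QC and composition; the *power design*
(`sim_config_recovery`: five types at equal proportions, 1,500
cells/sample ≈ 300 per type per sample, 1,000 genes, 30 planted DE genes
per type at |log2FC| = 1) for sensitivity and FDR of the consensus
procedure; and an *exchangeable null* (one type, 100 cells/sample, 300
genes, no sample effects) for calibration. Calibration nulls set the
per-sample effect to zero on purpose: those effects exist precisely to
violate cell-level exchangeability, and a calibration check of the engines
requires an exchangeable null.

## Known limitations

* The ZINB engine's mean-independent π and unshrunk dispersions are
  simplifications; strongly mean-dependent dropout would be absorbed
  partly into φ.
* Pooled composition tests inherit pseudo-replication; the per-sample DE
  criterion mitigates this for expression but nothing equivalent exists
  for composition (by design, see above).
* The per-sample criterion requires every sample to contribute ≥ 3 cells
  of the type; very rare types (e.g. lymphatic endothelium at desk scale)
  may be untestable, and the failure is logged, not silent.
* Exact reproduction of any specific clustering of real data is out of
  scope: cluster boundaries depend on resolution and neighborhood choices
  that the emulated study does not pin down.
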