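---
title: "Retrograde lineage-competency mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrograde lineage-competency mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(constellatr)
```

## The question the package answers

In a developmental time course of single-nucleus ATAC-seq data, each terminal
cell type (a "tissue") carries a signature set of accessible chromatin peaks.
The question is *when* that signature first appears: is lineage-specific
accessibility inherited from the earliest multipotent progenitors, or
established progressively? `constellatr` answers this retrogradely: peak sets
enriched in terminal-stage clusters are scored on every earlier timepoint,
and the shape of the per-cell score distribution dates the establishment of
each lineage's chromatin competency.

## Module scores: background-matched deviation z-scores

For a peak set (a tissue module or a motif annotation), a cell's observed
count sum $X_i$ is compared with the depth expectation
$E_i = T_i \cdot t_{set}/T$, where $T_i$ is the cell's total fragment count,
$t_{set}$ the set's grand total and $T$ the overall total. The raw deviation
is $Y_i = (X_i - E_i)/E_i$, and the reported score standardizes it against
$B$ background peak sets matched on GC content and mean accessibility:

$$z_i = \frac{Y_i - \overline{Y^b_i}}{\mathrm{sd}_b(Y^b_i)}.$$

Background sets are sampled with replacement, one candidate per set member,
from each member's `k_candidates = 100` nearest peaks in the standardized
(GC, mean accessibility) plane. The default `n_background = 50` follows the
convention of deviation-based motif scoring. Expectations conserve each
annotation's total count exactly ($\sum_i E_i = t_{set}$), and cells whose
background deviations are degenerate are flagged `NA`, never silently
zeroed. Scores are computed per timepoint: each developmental stage is a
separate library with its own depth structure, so pooling timepoints into
one deviation model would let stage-specific depth masquerade as biology.

Cluster-enriched peak sets (used to define tissue modules at the terminal
stage) come from a likelihood-ratio test per peak: logistic regression of
binarized accessibility on an in-cluster indicator plus log fragments in
peaks, against the depth-only null, with $\chi^2(1)$ p-values adjusted by
Benjamini–Hochberg within cluster and selected at adjusted $p < 0.001$ with
a positive in-cluster effect. Counts are binarized for this test (single
nuclei are mostly 0/1/2 at a peak) while raw counts feed the deviations.

## Competency calls: skewness of the score distribution

If a tissue's signature is established at a timepoint, only the lineage
fraction of cells scores highly and the score distribution is strongly
right-skewed; before establishment the distribution is symmetric noise. The
estimator is the adjusted Fisher–Pearson standardized third moment,
$G_1 = \frac{m_3}{m_2^{3/2}} \cdot \frac{\sqrt{n(n-1)}}{n-2}$. A
(tissue, timepoint) is called **skewed** when $G_1 > 1$ (strict). At the
earliest timepoint only, the cutoff is lowered to $0.4$ — overall skewness
is lower when signatures are just emerging — with a guard requiring the
maximum module score to exceed 15, so that low-magnitude noise cannot pass
the relaxed bar. A tissue's establishment timepoint is the *earliest*
skewed call; a later diffuse call does not veto it, since the first
appearance is the quantity of interest. Skewness is computed over all cells
at a timepoint (no subsetting): the competency signal is precisely that a
*minority* subpopulation separates, and restricting to a subset would
presuppose the answer. Constant score vectors yield an undefined skewness;
these are flagged and called diffuse rather than erroring.

## The constellation distance

Relatedness of (tissue, timepoint) nodes combines two terms:

$$D = D_{tissue} + a \cdot D_{timepoint}, \qquad
D_{tissue} = \tfrac{1}{2}\left[d_{(A,B),t_1} + d_{(A,B),t_2}\right],$$

where $d_{(A,B),t}$ is the Euclidean distance between the two tissues'
per-cell score vectors at timepoint $t$, and $D_{timepoint}$ is the
Robinson–Foulds distance between the tissue score dendrograms of the two
timepoints (average-linkage trees over the score vectors; the linkage is
configurable and recorded, as no single convention dominates). The weight
$a = 12$ rescales the integer-valued RF term onto the scale of the score
distances. $D$ is symmetric with a zero diagonal and $D_{timepoint}$
depends only on the timepoint pair; $D$ is not guaranteed to satisfy the
triangle inequality, which is a known property of the construction and the
reason grouping operates on $D$ directly rather than assuming a metric.
Per-cell score vectors (rather than cluster means) are used for
$d_{(A,B),t}$; since cell counts can differ across timepoints, an opt-in
`normalize = TRUE` divides each timepoint's distances by $\sqrt{n_{cells}}$
to put them on a root-mean-square scale, with the literal (raw) form as the
default.

The Robinson–Foulds term is computed from the non-trivial bipartitions each
internal edge induces, canonicalized to the side excluding a reference
leaf; the distance is the size of the symmetric difference of the two
bipartition sets (topology only, heights ignored). For binary trees on $n$
leaves it is bounded by $2(n-3)$.

Nodes are embedded in 2D by classical multidimensional scaling of the
precomputed $D$ — a deterministic embedding, so reruns are bit-identical —
and grouped by an average-linkage hierarchical cut of $D$. Diffuse nodes
are retained in the matrix and flagged in the map (they are part of the
picture), but lineage-family evaluation on synthetic data is performed on
competency-established nodes: pre-establishment nodes carry no lineage
signal by construction, so their grouping is arbitrary.

## Priming regression

To surface candidate lineage-priming factors, each tissue's module score is
regressed on every motif deviation and every TF gene activity
*univariately* (ordinary least squares, two-sided slope test,
Benjamini–Hochberg across features within tissue). A joint fit over
hundreds of collinear features would be rank-deficient at realistic cell
counts; the univariate reading is the faithful one and the package records
it in its output. Coefficients that are negative or fail adjusted
$p \le 0.05$ are clipped to zero — only positive association with the
module is evidence of priming — and a curated (motif, TF) pair is flagged
for a tissue when both members survive clipping. Regression cells default
to the timepoint where the tissue's competency was first called (the
establishment stage is where priming factors should act); the cell set is
configurable.

## The LSI-projected temporal graph

Each timepoint's matrix is TF-IDF weighted
($\log(1 + \mathrm{TF}\cdot\mathrm{IDF}\cdot 10^4)$, IDF computed within
the timepoint) and factorized by truncated SVD, $M = U S V^T$, keeping 30
components and dropping the first (depth-dominated) component downstream.
To link timepoint $t$ to $t-1$, the earlier matrix is projected into the
later basis by solving $M_{t-1} = U^p S_t V_t^T$ in least squares:
$U^p = M_{t-1} V_t S_t^{-1}$. The rows of $U_t$ and $U^p$ (components
2..30) are concatenated, scaled to unit length, and each cell of $t$ is
linked to its `k_link` nearest $t-1$ cells; intra-timepoint kNN edges
(k = 20) in each timepoint's own LSI space complete the graph. Edge weights
are $1/(1+d)$ (the published construction does not fix a weighting; this
choice is recorded and configurable). The graph is exported as an edge
list and GraphML for external force-directed layout; no layout is computed
in-package. Peak spaces are aligned on the merged union peak list before
weighting, as the shared $V_t$ basis requires; peaks empty in any
timepoint are dropped from the shared space.

## The synthetic atlas

The generator plants everything downstream stages are asked to recover.
Cells carry a terminal fate drawn balanced over tissues; counts are
$\mathrm{Poisson}(\mathrm{depth}_i \cdot p_j \cdot f_{jk})$ with lognormal
per-cell depth, Gamma-distributed per-peak base weights normalized to
probabilities, and $f_{jk} = $ `effect_size` on a tissue's specific peaks
for in-lineage cells at or after that tissue's establishment timepoint,
`family_effect` for cells of sibling tissues in the same lineage family
(shared-progenitor accessibility, which is what makes families
recoverable), and 1 otherwise. GC covariates are Beta(5,5), independent of
lineage by default, with an optional confounded mode that shifts
tissue-peak GC to stress-test background matching. Planted priming motifs
are unit-variance Gaussian deviations shifted additively in post-
establishment lineage cells; paired TF activities are an affine transfer of
the motif plus independent noise; decoys are pure noise.

Default study conditions: 5 timepoints, 10 tissues in 5 families of 2,
2000 cells per timepoint, 50 specific peaks per tissue plus 1000 background
peaks, `effect_size = 3` with `family_effect = (1+effect)/2`, depth
lognormal with meanlog $\log 5000$ and sdlog 0.5 (inside the shipped QC
fragment window), establishment timepoints cycling over the first three
stages (mirroring a time course where signatures arise well before the
terminal stage), one planted priming pair per tissue among 200 decoy pairs
(motif shift 2, TF transfer 0.8), and FRIP drawn Beta(13,7). These sizes
keep a full study run (simulation through priming) under half a minute on
one CPU while leaving each stage's statistics comfortably powered.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: read-level fragment structure and Tn5 bias,
doublets, batch effects between libraries, gradual (rather than step)
establishment of accessibility, correlated peak–peak covariance within
modules beyond the planted mean shift, and imputation noise in TF gene
activities. Establishment recovery at `effect_size = 3` says the pipeline's
statistics are wired correctly, not that a 3-fold accessibility shift is
typical of real lineages.

## Numerical choices and degenerate inputs

* QC: FRIP is compared strictly (`>`), the fragment window inclusively; the
  published thresholds ship as the `"zebrafish_cncc"` preset. Inclusivity
  of the fragment bounds is a documented choice where the source
  convention is unstated.
* Interval merging is half-open (BED): bookended peaks merge.
* Deviation scoring refuses annotations with zero total counts and errors
  when every cell's background is degenerate.
* `effect_size = 1` is accepted as the null generator; values below 1 are
  rejected.
* SVD rank exceeding the matrix rank is reduced with a warning; zero
  singular values make the projection error out, naming the component.
* Skewness requires at least 3 observations and flags constant vectors.
* Ties in background-candidate distances are resolved by peak order within
  the 100-candidate neighbourhood, which is immaterial once the
  neighbourhood covers the tied peaks.

## Worked run

```{r, eval = FALSE}
spec <- lineage_spec(seed = 1)
sim <- simulate_atlas(spec)
scores <- score_all(sim$atlases, sim$module_sets, n_background = 50, seed = 1)
report <- competency_report(scores)
establishment_table(report)
cd <- build_distance(scores, a = 12)
map <- embed_constellation(cd, statuses = report)
```

The acceptance script (`scripts/acceptance.R`) runs exactly this study plus
the null calibrations and writes the recovered quantities as JSON; the
README shows a complete worked example with its printed output.

## Known limitations

* The pipeline consumes peaks, motif annotations and TF activities; it
  calls no peaks and scans no motifs.
* Grouping quality on real data depends on the linkage and on `a`; both are
  parameters, not estimates.
* The temporal graph implements the LSI projection and plain kNN linking;
  published trajectory tools layer additional edge-filtering heuristics on
  top, which are intentionally out of scope here.
* With very small tissue panels (4 or fewer), module-score mixtures are too
  balanced for the skewness criterion to be meaningful; the method is
  designed for atlases with many terminal types, where each lineage is a
  minority of cells.
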