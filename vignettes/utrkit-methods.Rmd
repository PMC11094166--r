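---
title: "Models and methods behind utrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind utrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrkit)
library(tibble)
```

utrkit quantifies alternative polyadenylation (APA) from 3' end
single-cell RNA-seq: where a transcript's cleavage-and-polyadenylation
site (CS) falls determines its 3'UTR length, and 3'-tagged scRNA-seq
protocols concentrate their reads near those sites, so CS usage can be
measured per cell without full-length coverage. This vignette explains
the models the package implements, the parameters that matter, and the
choices made where the design was genuinely open. It states no result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Cleavage-site calling and classification

Read 5'-end coverage (strand-specific, single-nucleotide) is merged to
local modes within a **30 nt radius**: the highest-count position
absorbs all positions within the radius, then the next highest among
the remainder, iteratively. Peaks are retained when their support
exceeds **5 reads per million** — strictly, so a site at exactly 5 RPM
is dropped. Per-cell-type peaks are then summed and re-merged once at
the same radius to harmonize small positional shifts between cell
types. The RPM denominator is the per-cell-type read total; a
per-sample denominator would only rescale the filter.

Candidates are classified against two references using **40 nt windows
(±20 nt, center to center, same strand)**: sites near an annotated
transcript 3' end (transcripts with the unvalidated-end tag excluded)
are *validated*; remaining sites near an external polyA-atlas cluster
with **≥ 3 TPM** are *supported*; remaining sites passing an
internal-priming filter are *likely*; the rest are discarded. The
retained atlas is the union of supported and likely sites — validated
sites already exist in the annotation.

**Internal priming.** Oligo(dT) priming at genomic A-stretches creates
spurious 3' ends. utrkit uses a transparent sequence heuristic: a site
fails when the 20 nt immediately downstream (strand-aware) have an
A-fraction ≥ 0.65 or contain a run of ≥ 8 consecutive A. Published
pipelines often use a trained Bayes classifier here; we chose a
deterministic rule with exposed thresholds because it is auditable and
exactly testable. It will differ from a trained classifier near the
decision boundary, which is a real limitation for borderline A-rich
contexts.

Region labels are assigned with a fixed precedence —
`three_prime_UTR` > `five_prime_UTR` > `exon` > `intron` >
`extended_five_prime_UTR` (1 kb upstream) >
`extended_three_prime_UTR` (5 kb downstream) > `intergenic` — taking
the best label across all same-strand overlapping transcripts.

**Usage score.** A site's usage score is the number of cell types that
use it divided by the number of cell types expressing its gene. "Use"
means the site survived peak calling in that cell type; "express" means
at least one UMI in the cell type's pseudobulk — neither is fully
pinned down by convention, so both definitions are stated here and
implemented as such. A site used in **< 10** expressing cell types is
*minor*. A fraction-based variant (< 10% of expressing cell types) is
available via `rule = "fraction"`; the count rule is the default.

## The truncated UTRome

Quantifying 3'-end tags against full transcripts is wasteful and
ambiguous, so the annotation is rebuilt around cleavage sites:

1. **Augment**: interior 3'UTR sites generate "upstream" isoform
   copies truncated at the site; sites up to 5 kb downstream of an
   annotated end generate "downstream" copies extending the last exon.
2. **Truncate** every isoform to its 3'-most **500 nt** of spliced
   sequence (the empirical span of 10x read 5' ends from the CS; the
   95th-percentile diagnostic is `peak_width_percentiles()`).
3. **Deduplicate** isoforms whose 3' ends are **< 50 nt** apart
   (transitively chained, genomic end distance) down to the most 3'
   member, preferring "downstream"-sourced models on positional ties
   and keeping the lexicographically smallest transcript id.
4. **Merge table**: isoform ends **< 200 nt** apart cannot be reliably
   discriminated by 3'-end reads, so each isoform is mapped to the most
   3' isoform within that distance, and pointer chains are resolved to
   a fixed point. Counting then assigns merged isoforms to the distal
   representative, which conserves total counts exactly.

Dedup distance is measured on genomic 3'-end coordinates: truncated
bodies are suffixes of the same gene sequence, so end distance
determines sequence difference, and nearby ends share a last exon in
practice. Chain resolution to a fixed point is deliberate — counting
needs a single representative per merge group even when the immediate
most-downstream neighbor itself merges further.

An isoform is flagged **IPA** (intronic polyadenylation) when its 3'
end falls inside an annotated intron of its gene; IPA isoforms are
excluded from 3'UTR-length statistics but drive the IPA-gene
classification.

## Quantification and the EM step

A read is compatible with an isoform when its 3'-end position lies in
the isoform's truncated body. Reads unique to one isoform (or to one
merge group) are counted directly; the rest form equivalence classes
resolved by expectation maximization on a categorical mixture. The
class likelihood is the *unweighted* sum of member abundances: 3'-end
tags violate the uniform-coverage assumption that effective-length
weighting encodes, so no length term is used. EM iterates to a 1e-8
abundance tolerance (cap 1000 iterations); the log-likelihood is
non-decreasing by construction and the suite checks agreement with a
grid-search maximizer on small instances. Instances where no class pins
any isoform down are flagged non-identifiable and returned uniform.

**Resolution calibration.** `simulate_two_isoform()` rebuilds the
two-isoform experiment that motivates the 200 nt merge distance: read
5'-end distances from each CS follow a discretized gamma with mean
300 nt and sd 100 nt (shape `(300/100)^2 = 9`, scale `100/3`), rounded
to integers and floored at the 100 nt read length (a read cannot end
downstream of its site — the paper-level description omits the
discretization, which we state as our choice). Reads are assigned and
EM-resolved, and `(estimated − true)/true` is reported per isoform.
`resolution_sweep()` runs the full grid (distances 50–700 by 50,
truncations 350–600 by 50, 50/100 reads per isoform, 10 replicates) and
`resolved_distance()` flags the smallest distance whose *worst-case*
mean absolute relative error stays below an explicit tolerance
(default 0.05) from there on — the underlying selection is a judgment
call ("errors approaching zero"), so the tolerance is a parameter, not
a constant, and the worst-case-over-conditions reading is deliberately
conservative.

## Isoform-usage statistics and the bootstrap test

Isoforms of a gene are ordered 5'→3' by CS position and weighted by
scaled positional rank: `{0, 1}`, `{0, 1/2, 1}`, `{0, 1/3, 2/3, 1}`, …
The **WUI** (weighted UTR index) is the weighted mean of isoform
expression fractions — 0 when all counts sit on the shortest isoform, 1
on the longest, and for two-isoform genes simply the long-isoform
fraction. **UI** is the fraction difference of one flagged isoform
(short, long, or IPA), and **WD** is half the L1 distance between
fraction vectors (the earth-mover distance on the discrete isoform
set). For two-isoform genes |UI| = WD = |ΔWUI| exactly, which the suite
asserts on random profiles.

`two_sample_bootstrap_test()` tests, per gene, whether usage differs
between two groups of cells. Statistics are computed on **pseudobulk**
(counts summed within each group — consistent with the CI machinery;
per-cell averaging is noisier at these counts and is not used). Under
the null, cells are resampled with replacement from the union of both
groups at the original group sizes; one set of resampled cell indices
serves every gene, which both vectorizes the computation and matches
the principle that cells, not gene values, are the sampling unit. The
two-sided p-value takes "as extreme" on absolute values of the
difference statistic and adds a pseudocount of 1:

    p = (1 + #{ b : |T_b| >= |T_obs| }) / (1 + B_valid)

so p is never 0. Genes need **≥ 50** expressing cells in each observed
group to be tested; bootstrap samples failing the same minimum are
discarded per gene, and a gene whose every sample fails is reported
`NA` with zero retained bootstraps (rather than dropped, so the caller
sees why). BH adjustment runs across tested genes. Percentile
confidence intervals (`bootstrap_percentile_ci()`) use **2000**
resamples of one group's cells, with mean per-cell TPM or pseudobulk
WUI per gene. TPM throughout the package means UMIs per million total
UMIs — no length normalization is meaningful for 3'-end tags.

## Gene classification and DGE vs DUL

A 3'UTR isoform *qualifies* when it carries ≥ 10% (inclusive) of its
gene's non-IPA counts in at least one cell type; genes with ≥ 2
qualifying isoforms are **multi-UTR**. The 10% rule uses count
fractions, which are identical to TPM fractions under per-million
scaling. IPA genes are called analogously but on total-gene fractions
with IPA isoforms included. Isoform switching considers cell types with
≥ 200 cells and gene expression > 5 TPM (excluding IPA); a gene
switches when its dominant isoform differs between qualifying cell
types, with within-cell-type ties resolved deterministically toward the
more 3' isoform.

Differential gene expression uses a per-gene Welch t-test on
`log2(count / size_factor + 1)` per cell, with library-size factors
scaled to mean 1 by default and a hook for externally computed
(e.g. pooling-based) factors. Fold changes come from de-logged group
means; significance requires |FC| > 1.5 and q < 0.05. Differential
3'UTR length (DUL) requires |ΔWUI| > 0.10 and q < 0.05 from the
bootstrap test. Coexpressed multi-UTR genes then land in exactly one of
none / DGE-only / DUL-only / both, and a chi-square test on the 2×2
significance table asks whether expression and UTR-length regulation
are independent. The Yates-corrected statistic is reported as primary
(the R default for 2×2 tables); the uncorrected statistic is returned
alongside because the correction is intentionally conservative and the
suite's null-uniformity check targets the uncorrected p.

`minor_isoform_dominance()` asks, for significant two-UTR genes,
whether the isoform with the largest |log2 FC| (in the lower-expression
cell type) is the lower-abundance isoform there; exact abundance ties
are excluded.

## Perturbation screens

Per perturbation and gene, a pseudobulk WUI is compared with a
cell-count-weighted baseline over the non-targeting controls; the
resulting **dWUI** matrix keeps perturbations with ≥ 30 cells.
Per-perturbation average dWUI (and dIPA, computed identically on IPA
fractions) summarizes genes with control expression > 5 TPM and
baseline value inside [0.1, 0.9] — genes pinned near 0 or 1 cannot
move and would dilute the average, which as a plain mean is sensitive
to unidirectional shifts only.

For clustering, genes are restricted to well-measured responses
(control detection ≥ 80% of cells, control TPM ≥ 20), missing effects
are imputed as dWUI = 0 (identical to baseline), and each perturbation
row is scaled to unit variance **without centering** — the zero point
is already fixed by the controls, and uncentered scaling preserves
signs. Clustering proceeds in rounds of PCA (30 PCs) → kNN graph →
walktrap community detection (4-step random walks, modularity-optimal
cut), alternating axes with k = 5, 4, 3. Early rounds drop
"patternless" clusters; the published analysis made that call by eye,
so utrkit substitutes an explicit dispersion score (cluster mean |z|
below the bottom quartile by default, configurable) and does not claim
to reproduce any particular retained set.

The kNN graph is symmetrized by **union** (an edge when either point
names the other as a neighbor). We initially considered mutual-neighbor
symmetrization, but at k = 5 it fragments coherent 20-member modules
into walktrap sub-communities and fails planted-module recovery, while
the union graph recovers planted modules exactly (the suite's ARI
check); union is also the common choice in single-cell graph pipelines.
Mutual symmetrization remains available via `symmetrize = "mutual"`.

Per-cluster differential tests compare per-perturbation WUI (or TPM)
values of cluster members against non-targeting perturbations with a
two-sided Mann–Whitney test, BH-adjusted within cluster; gene overlap
between cluster gene sets uses the one-sided hypergeometric tail;
replicate validation correlates cluster-average z-profiles with
replicate profiles from a second dataset against a non-targeting
control distribution (one-sided Mann–Whitney, greater).

**Compensation.** For two-isoform genes with significant DUL in a
cluster, expression is split as
`TPM_SU = mean(TPM)·(1 − mean(WUI))` and `TPM_LU = mean(TPM)·mean(WUI)`
and the changes versus control compared: regulation is *coordinated*
when `−0.5 ≥ dTPM_LU/dTPM_SU ≥ −2` (bounds inclusive — at least half
the expression gained by one isoform is lost by the other), otherwise
it is SU- or LU-specific by the larger |dTPM|. When `dTPM_SU = 0`
alone, the gene is LU-specific; when both changes are zero no category
is assigned.

## Decay kinetics

Metabolic-labeling conversion rates approach a plateau as
`c(t) = c_max (1 − e^{−kt})` under first-order turnover
(half-life `ln 2 / k`). Rates are averaged per timepoint (0, 120, 240,
360 min) weighted by read counts, then fit by weighted nonlinear least
squares with `c_max` free, initialized from a log-linear regression
with the plateau guessed at 1.05× the maximum observed rate (also the
fallback if the optimizer fails). The published description names only
"first-order kinetics" via a GLM; the saturating-asymptote formulation
is our interpretation, stated as such. Fits are flagged when conversion
never increases, never happens (infinite half-life), or saturates
before the first nonzero timepoint (half-life below the sampling grid
is reported but low-confidence).

## What the synthetic data does and does not show

All tests run on data from the package's own generators:

* `generate_fixture()` draws per-cell isoform counts from a
  Dirichlet-multinomial around planted per-group isoform fractions
  (gene totals Poisson around a planted per-cell mean; concentration
  `Inf` gives a pure multinomial). Planted WUI shifts and fold changes
  are therefore exactly known.
* `generate_toy_annotation()` / `generate_reads()` lay out multi-isoform
  genes on both strands with gamma-distributed read distances.
* `generate_effect_matrix()` plants sign-coherent perturbation × gene
  modules plus Gaussian noise.

These emulate planted effect sizes, sampling noise, overdispersion, and
strand/coordinate bookkeeping. They do **not** emulate ambient RNA,
doublets, UMI collisions or sequencing errors, gene-length- and
GC-dependent capture biases, correlated gene programs, batch structure,
or realistic mRNA abundance distributions. Passing tests therefore
demonstrate correctness of the algorithms and calibration under the
stated sampling models — not performance on any real dataset.

Problem sizes in the suite (e.g. 1000 null genes × 400 cells × 1000
bootstraps for calibration; 60 × 300 effect matrices; 200 random gene
layouts; 10,000 peak-calling cases) were chosen so each property is
measured with comfortable margin while the whole suite stays quick to
run locally.

## Numerical and degenerate-input choices

* Local-mode ties break to the leftmost (5'-most on `+`) position, for
  determinism.
* Bootstrap "as extreme" is `|T_b| ≥ |T_obs|`; with `T_obs = 0` every
  sample is extreme and p = 1.
* EM convergence: max abundance change < 1e-8 or 1000 iterations;
  zero-count classes are removed up front (they carry no information
  and would create 0/0 responsibilities at the boundary).
* Genes with zero pseudobulk totals on either side are flagged, not
  tested; usage scores are `NA` when a gene is expressed in no cell
  type.
* Windows that would extend past a contig end are truncated (priming
  filter, motif scans).
* Barcodes are namespaced by sample when data from several samples are
  combined, since barcode collisions across samples are otherwise
  ambiguous.
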