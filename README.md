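# utrkit

Quantifying 3'UTR length and alternative polyadenylation (APA) from 3'
end single-cell RNA-seq.

Most mammalian genes can end their mRNAs at more than one cleavage-and-
polyadenylation site (CS), producing isoforms that differ only in 3'UTR
length. 3'-tagged scRNA-seq (10x-style) concentrates reads near those
sites, so CS usage is measurable per cell — but standard pipelines
quantify genes, not 3' ends. utrkit provides the full stack for doing
this properly, for computational biologists working on APA:

1. **CS atlas** — call single-nucleotide cleavage sites from
   strand-specific read 5'-end coverage (local-mode merging within
   30 nt, > 5 reads-per-million), harmonize across cell types, classify
   against an annotation and an external polyA-site atlas
   (validated / supported / likely within ±20 nt windows), filter
   internal-priming artifacts (A-rich downstream context), label
   genomic regions, and score CS usage across cell types.
2. **Truncated UTRome** — augment a GTF with atlas sites, truncate
   every isoform to its 3'-most 500 nt, deduplicate ends closer than
   50 nt, and emit a merge table collapsing ends closer than 200 nt
   onto the distal site (such ends are not discriminable from 3'-end
   reads; the threshold is calibrated by the package's own two-isoform
   simulation with gamma-distributed read distances, mean 300 / sd 100).
3. **Quantification** — assign reads by 3'-end position, resolve
   ambiguous reads with an expectation-maximization step over
   equivalence classes (uniform within-class read model; no length
   weighting, which 3'-end tags violate).
4. **scUTRboot-style statistics** — per-gene two-sample bootstrap tests
   on cell resamples for three statistics: the **WUI** (weighted UTR
   index; isoform fractions weighted by 5'→3' positional rank scaled to
   [0, 1], i.e. weights {0, 1}, {0, 1/2, 1}, {0, 1/3, 2/3, 1}, …), the
   single-feature **UI**, and the Wasserstein distance **WD** = half
   the L1 distance between isoform-fraction vectors. P-values are
   `p = (1 + #{|T_b| ≥ |T_obs|}) / (1 + B_valid)` with a pseudocount of
   1, genes gated on ≥ 50 coexpressing cells, BH-adjusted; percentile
   bootstrap CIs use 2000 resamples.
5. **Gene-level analysis** — single-/multi-UTR and IPA gene
   classification (10% isoform rule), dominant-isoform switching, Welch
   differential expression (|FC| > 1.5, q < 0.05) versus differential
   UTR length (|ΔWUI| > 0.10, q < 0.05), and their chi-square
   independence.
6. **Perturbation screens** — dWUI/dIPA effect matrices against
   cell-weighted non-targeting baselines, uncentered z-scaling with
   zero imputation, iterative PCA/kNN/walktrap clustering, per-cluster
   Mann–Whitney tests, Fisher-overlap between cluster gene sets,
   replicate validation, gene-feature correlations, and compensation
   classification (`TPM_SU = TPM·(1−WUI)`, `TPM_LU = TPM·WUI`;
   coordinated when `−0.5 ≥ dTPM_LU/dTPM_SU ≥ −2`).
7. **Decay kinetics** — first-order fits
   `c(t) = c_max(1 − e^{−kt})` to metabolic-labeling conversion rates,
   half-life `ln 2 / k`.

Everything takes and returns tibbles (plus a light sparse
`cell_counts` container), chains with the pipe, and ships seeded
synthetic-data generators for every input, so the whole stack is
exercised end to end without any external data.

## Worked example

Plant a 3'UTR shortening (WUI 0.65 → 0.40) across 50 two-isoform genes
in two groups of 300 cells, then test for differential UTR length:

```r
library(utrkit)

fx <- generate_fixture(
  cells_per_group = c(HSC = 300, Ery = 300),
  n_genes = 50, wui = list(HSC = 0.65, Ery = 0.40),
  mean_count = 6, seed = 7)

res <- two_sample_bootstrap_test(fx$counts, "HSC", "Ery",
                                 mode = "wui", n_boot = 1000,
                                 min_cells_per_gene = 50, seed = 8)
head(res, 3)
#> # A tibble: 3 × 6
#>   gene_id statistic observed        p        q n_bootstraps_retained
#>   <chr>   <chr>        <dbl>    <dbl>    <dbl>                 <int>
#> 1 gene001 WUI          0.249 0.000999 0.000999                  1000
#> 2 gene002 WUI          0.267 0.000999 0.000999                  1000
#> 3 gene003 WUI          0.248 0.000999 0.000999                  1000
glance(res)
#> # A tibble: 1 × 6
#>   n_genes n_significant n_boot min_cells_per_gene group_a group_b
#>     <int>         <int>  <dbl>              <dbl> <chr>   <chr>
#> 1      50            50   1000                 50 HSC     Ery
```

`observed` is the pseudobulk WUI difference (HSC − Ery): every gene
recovers the planted ≈ 0.25 shift, and with the pseudocount no p-value
can fall below `1/(B+1) = 0.000999`. All 50 genes clear the
`|ΔWUI| > 0.10, q < 0.05` significance rule.

The EM step on the worked equivalence-class instance — 50 reads unique
to the proximal isoform, 30 unique to the distal, 20 ambiguous —
converges to the analytic fixed point `α_p = (50 + 20·α_p)/100`:

```r
em_abundance(c(p = 50, d = 30, `d,p` = 20))
#> # A tibble: 2 × 3
#>   isoform_id abundance est_count
#>   <chr>          <dbl>     <dbl>
#> 1 d              0.375      37.5
#> 2 p              0.625      62.5
```

A thin command-line dispatcher over the same functions is installed at
`inst/cli/utrkit.R` (subcommands `atlas`, `utrome`, `simulate`,
`fixture`, `defaults`).

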