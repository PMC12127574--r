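# gdgse — gene set enrichment from discretized expression

Single-sample gene set enrichment scoring for bulk and single-cell
transcriptomes, built on per-gene discretization against a reference
condition rather than on continuous values or within-sample gene ranks.
It is aimed at analysts who have a two-condition design (tumor vs normal,
treated vs control, one cell type vs the rest) and want pathway or
signature activity scores per sample that are robust to dropout zeros and
to baseline expression differences between genes.

## The method

Given a genes × samples matrix with a query condition C1 and a reference
condition C2, each gene g is summarized over the reference samples by its
mean μ_g and population standard deviation σ_g (divisor |C2|). A query
sample s is binarized per gene:

    M'(g, s) = 1  if  v(g, s) > μ_g + σ_g,   else 0

and the enrichment score of a gene set GS with G genes is the fraction of
its genes above threshold:

    ES(s, GS) = (1/G) · Σ_{g ∈ GS} M'(g, s)  ∈ [0, 1]

Because the threshold moves with the data, scores are invariant to
per-gene affine rescaling applied to all samples. The package also
provides: a one-vs-rest mode that scores each cell type's signature
against the complement of that type; a label-permutation significance
test (p = #{ES_perm ≥ ES_obs}/n, with a small-sample-corrected variant
reported alongside); a null-calibration harness (p-value matrix under
shuffled labels, 100 quantile bins, QQ slope, KS uniformity); synthetic
two-condition and single-cell generators with planted gene-set activation,
dropout and additive Gaussian noise; evaluation metrics (adjusted Rand
index, silhouette, sensitivity/specificity/balanced accuracy, coefficient
of variation, min-max scaling); and readers/writers for dense TSV/CSV,
MatrixMarket triplets and GMT gene sets. See the methods vignette
(`vignettes/gdgse-methods.Rmd`) for the model, conventions and design
rationale.

## Worked example

Simulate a 1000-gene cohort with 12 tumor and 12 normal samples in which
two planted 25-gene sets are shifted up by 2 per-gene standard deviations
in the tumor samples, then score and test:

```r
library(gdgse)
sim <- simulate_two_condition(n_genes = 1000, n_c1 = 12, n_c2 = 12,
                              n_planted = 2, n_decoy = 2, set_size = 25,
                              delta = 2, seed = 42)
fit <- gdgse(sim$expr, sim$sets)
summary(fit)
#>     gene_set genes_measured set_size mean_es min_es max_es
#> 1 PLANTED_01             25       25   0.837   0.72   1.00
#> 2 PLANTED_02             25       25   0.837   0.72   0.96
#> 3   DECOY_01             25       25   0.153   0.08   0.28
#> 4   DECOY_02             25       25   0.200   0.08   0.28

pt <- permutation_test(sim$expr, sim$sets, n = 1000, seed = 43)
pt$table
#>          set es_obs     p p_corrected
#> 1 PLANTED_01  0.837 0.000    0.000999
#> 2 PLANTED_02  0.837 0.000    0.000999
#> 3   DECOY_01  0.153 0.828    0.828172
#> 4   DECOY_02  0.200 0.462    0.462537
```

The planted sets average a score of 0.84 in tumor samples — about 84 % of
their genes exceed the normal-tissue threshold per sample — while decoys
sit near the null baseline of ~0.16 (the tail mass above μ+σ). No
permutation reaches the planted sets' observed statistic (uncorrected
p = 0; corrected p ≈ 0.001), while the decoys are unremarkable.

A command-line interface over the same functions is installed at
`inst/cli/gdgse.R` (subcommands `score`, `onevsrest`, `permute`,
`calibrate`, `simulate`, `noise`, `evaluate`; see `--help`).

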