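---
title: "Scoring gene sets from discretized expression: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene sets from discretized expression: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdgse)
```

## The model

Most single-sample enrichment methods (ssGSEA, AUCell, singscore, ...) work
on continuous expression values or within-sample gene ranks. Ranks are
fragile in single-cell data, where dropout zeros disrupt them, and they
compare genes against each other inside a sample without correcting for
baseline expression differences between genes. The approach implemented
here instead discretizes expression gene by gene against a reference
condition before any set-level aggregation.

Samples carry one of two conditions: a query condition C1 (e.g. tumor) and
a reference condition C2 (e.g. matched normal tissue). For each gene $g$
the reference samples define

$$\mu_g = \frac{1}{|C2|}\sum_{s' \in C2} v(g, s'), \qquad
  \sigma_g = \sqrt{\frac{1}{|C2|}\sum_{s' \in C2} (v(g, s') - \mu_g)^2},$$

and a query sample $s$ is binarized per gene:

$$M'(g, s) = \begin{cases} 1 & v(g, s) > \mu_g + \sigma_g \\
                           0 & \text{otherwise.} \end{cases}$$

The enrichment score of a gene set $GS$ with $G$ genes in sample $s$ is
the fraction of its genes above threshold:

$$ES(s, GS) = \frac{1}{G} \sum_{g \in GS} M'(g, s) \in [0, 1].$$

Two consequences are worth spelling out. First, every score is an exact
rational $k/G$; the scores of a set live on a fixed grid. Second, the
threshold moves with the data: adding a constant to a gene in all samples,
or rescaling it by a positive factor, changes $\mu_g + \sigma_g$ by
exactly the same transformation, so the binarization — and hence every
score — is invariant to per-gene affine changes applied consistently
across samples. This is the sense in which the method corrects for
baseline expression differences between genes. Raising a single query
entry can flip its gene from 0 to 1 but never the reverse, so scores are
monotone in individual expression values.

Three details are deliberate and tested:

* **Population divisor.** $\sigma_g$ divides by $|C2|$, not $|C2| - 1$.
  This differs from `sd()` and most library defaults; a single reference
  sample yields $\sigma_g = 0$ rather than `NA`.
* **Strict inequality.** A value exactly equal to $\mu_g + \sigma_g$ maps
  to 0. With $\sigma_g = 0$ (constant reference) the threshold degenerates
  to $\mu_g$ and only strictly larger values count.
* **No internal transformation.** Values are consumed as provided
  (normalized scales such as RSEM or CPM are appropriate); the package
  never log-transforms or renormalizes.

### Genes missing from the matrix

The set-size denominator $G$ is ambiguous when member genes are absent
from the expression matrix. The default (`denominator_mode = "measured"`)
divides by the number of member genes actually measured, because
unmeasured genes would deterministically deflate scores regardless of
biology; `"full"` divides by the literal set size for users who want the
textbook formula. Sets with no measured members are dropped with a warning
and listed in the fit object and the JSON sidecar.

### One-vs-rest cell-type scoring

For cell-type signatures, `one_vs_rest()` conditions each type against all
other cells in turn: C2 is the complement of type $t$, reference
statistics come from that complement, and **all** cells — including the
complement — are binarized against those statistics so that in-type and
out-of-type cells are scored on the same footing. (The alternative, only
scoring in-type cells, would make in/out comparisons incoherent; the
all-cells reading is adopted and used by `summary()`, which reports the
per-type fold change of mean scores.) The fold change convention:
out-group mean 0 with positive in-group mean yields `Inf`; both means 0
yields 1.

## Permutation significance

`permutation_test()` assesses a set's enrichment by shuffling the sample
label vector (preserving $|C1|$ and $|C2|$), recomputing reference
statistics, binarization and scores each time, and comparing the
recomputed statistic to the observed one:

$$p = \frac{\#\{ES_{perm} \ge ES_{obs}\}}{n}, \qquad n = 1000 \text{ by default}.$$

The per-dataset statistic is not uniquely determined by the formula above,
since a dataset yields one ES per C1 sample; the default aggregates by the
mean over C1 samples (`statistic = "mean_C1"`), with a per-sample variant
available that pools permuted-C1 scores into the null. The one-sided
$\ge$ comparison is kept as the primary definition, which means $p$ can be
exactly 0; the corrected variant $(\text{count}+1)/(n+1)$ is always
reported alongside, never silently substituted. Because the statistic is
discrete, ties between permuted and observed statistics are counted in the
numerator, which makes small-sample p-values mildly conservative — visible
in the calibration harness below when sets or sample sizes are very small.
No multiple-testing correction is applied by default; a
Benjamini–Hochberg column is opt-in (`bh = TRUE`).

Seeding: one master seed initializes the RNG; permutations are drawn
sequentially from that stream, so results are bit-reproducible given the
seed.

## Null calibration harness

`null_calibration()` measures false-positive behaviour under a true null.
The labels are shuffled `n_perm` times; each shuffled dataset receives a
full permutation test per gene set (`n_inner` fresh inner shuffles),
producing a p-value matrix (sets × permutations). Pooled p-values are
sorted, cut into 100 equal-width quantile bins (0–0.01, 0.01–0.02, ...),
and the mean observed versus expected $-\log_{10}(p)$ per bin is reported
with a QQ slope and a Kolmogorov–Smirnov uniformity statistic.

Numerical conventions: observed $p = 0$ (possible under the count-based
formula) is floored at $1/(2 \cdot n_{inner})$ on the log scale only, and
the number of floored values is reported; the QQ slope is the
least-squares slope through the origin of the binned observed-vs-expected
means; fewer pooled p-values than bins triggers a warning and coarser
binning, recorded in the report; a constant expression matrix produces all
$p = 1$ and a `degenerate` flag rather than an error. Empty bins are
flagged, never silently dropped.

## The synthetic data generators

The generators stand in for the tumor/normal cohorts and annotated
single-cell datasets that the method is normally applied to. They emulate:
per-gene baseline heterogeneity (lognormal means, `meanlog = 1.5`,
`sdlog = 0.7`, giving a median baseline around 4.5 on a normalized-count
scale); per-gene dispersion proportional to the mean (`cv = 0.4`, floored
at `min_sd = 0.5`); a planted, set-coherent upward shift of `delta`
per-gene standard deviations in C1 only; uniform Bernoulli dropout for
single-cell data; and additive Gaussian noise with mean 0.01 and standard
deviations on the 0.01–0.06 grid used by the robustness protocol
(`noise_sd_grid()`). Default sizes are 2000 genes and 20 + 20 samples for
bulk, three types × 50 cells with dropout 0.6 for single-cell mode.

They do **not** emulate: gene–gene correlation beyond the planted sets,
library-size variation, expression-dependent dropout (dropout is uniform
by design; expression-dependent masking would couple dropout to the
threshold and is out of scope), count noise (values are truncated
Gaussians, not negative-binomial counts), or batch effects. Passing tests
on these generators therefore demonstrates correctness of the algorithmic
pipeline and its statistical calibration, not performance on any real
cohort.

Values are truncated at zero after the Gaussian draw because the input
contract requires non-negative normalized expression; noise injection, by
contrast, performs literal addition with no clamping (an explicit
`clamp = TRUE` exists for count-like downstream use), and noise is added
to **all** entries — reference samples included — so that threshold and
query values are perturbed consistently.

## Problem sizes used by the test suite

The checks are sized to run on a single CPU in minutes, as the package's
own test-design choice: oracle equivalence uses 50 random instances up to
30 genes × 15 samples × 5 sets against a scalar triple-loop
implementation; permutation correctness enumerates all
$\binom{6}{3} = 20$ label assignments of a 6-sample toy; calibration uses
4000 genes, 30 + 30 samples and 50 disjoint sets of 80 genes with
200 × 200 permutations — disjoint, hallmark-sized sets keep the pooled
p-values close to independent and the discrete statistic fine-grained
enough for a meaningful uniformity test; effect-size recovery uses 20
replicates per effect size on 400-gene simulations. The acceptance script
(`scripts/acceptance.R`) re-runs the same workflows at moderately larger
sizes and writes its quantities as JSON.

## Known limitations

* A reference condition is required; there is no reference-free mode.
* With very few reference samples, $\mu_g + \sigma_g$ is noisy and scores
  are unstable; $n_{ref} = 1$ is allowed but degenerates to
  $\sigma_g = 0$.
* The permutation p-value inherits the discreteness of the score grid;
  for tiny sets/sample counts it is conservative (documented above), and
  the corrected variant should be preferred downstream.
* The adjusted Rand index is often described as ranging from 0 to 1, but
  its chance correction can produce small negative values; the
  implementation returns the true value rather than truncating at 0.
* Silhouette values for singleton clusters are set to 0 by convention;
  min–max scaling of a constant vector returns all zeros with a warning.
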