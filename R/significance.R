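## Fast internal scoring path shared by the permutation machinery: per-set
## enrichment scores of the c1 columns given reference columns c2.
.es_matrix <- function(values, memb, denom, c1, c2) {
  ref <- values[, c2, drop = FALSE]
  mu <- rowMeans(ref)
  sig <- if (length(c2) == 1L) 0 else sqrt(rowMeans((ref - mu)^2))
  bin <- (values[, c1, drop = FALSE] > mu + sig) + 0
  (memb %*% bin) / denom
}

## mean ES over c1 per set without materialising the per-sample ES matrix:
## mean_s ES(set, s) = memb %*% rowSums(bin) / (denom * |c1|)
.mean_es_stat <- function(values, memb, denom, c1, c2) {
  ref <- values[, c2, drop = FALSE]
  mu <- rowMeans(ref)
  sig <- if (length(c2) == 1L) 0 else sqrt(rowMeans((ref - mu)^2))
  cnt <- rowSums(values[, c1, drop = FALSE] > mu + sig)
  as.numeric(memb %*% cnt) / (denom * length(c1))
}

#' Permutation significance of enrichment scores
#'
#' Assesses the significance of observed enrichment by permuting the sample
#' condition labels. Each permutation shuffles the label vector uniformly at
#' random (preserving the sizes of C1 and C2), recomputes the reference
#' statistics, the binarization and the enrichment scores, and records the
#' test statistic. The reported p-value is the fraction of permutations
#' whose statistic is greater than or equal to the observed one (one-sided):
#' `p = count(ES_perm >= ES_obs) / n`. This can be exactly 0; a
#' small-sample-corrected variant `(count + 1) / (n + 1)` is always reported
#' alongside and never silently substituted.
#'
#' The per-dataset statistic defaults to the mean enrichment score across
#' the C1 samples (`statistic = "mean_C1"`). With `statistic =
#' "per_sample"`, the per-sample ES values of all permuted-C1 samples are
#' pooled into the null and each original C1 sample receives its own
#' p-value.
#'
#' @param x a [gdgse_expr()] object with labels and a reference level.
#' @param sets a [gene_sets()] collection.
#' @param n number of permutations (default 1000).
#' @param statistic `"mean_C1"` (default) or `"per_sample"`.
#' @param seed optional integer seed for reproducibility.
#' @param denominator_mode see [score_gene_sets()].
#' @param bh if `TRUE`, a Benjamini-Hochberg adjusted column is added
#'   (opt-in; no multiple-testing correction is applied by default).
#' @return An object of class `gdgse_perm`: list with `table` (data.frame of
#'   set, es_obs, p, p_corrected), `es_perm` (n-by-sets matrix of permuted
#'   statistics for `"mean_C1"`), `n`, `statistic`, `seed`.
#' @examples
#' sim <- simulate_two_condition(n_genes = 200, n_c1 = 5, n_c2 = 5,
#'                               n_planted = 1, n_decoy = 1, delta = 5, seed = 1)
#' pt <- permutation_test(sim$expr, sim$sets, n = 200, seed = 2)
#' pt
#' @export
permutation_test <- function(x, sets, n = 1000,
                             statistic = c("mean_C1", "per_sample"),
                             seed = NULL,
                             denominator_mode = c("measured", "full"),
                             bh = FALSE) {
  statistic <- match.arg(statistic)
  .assert(is.numeric(n) && length(n) == 1L && n >= 1, "input",
          "'n' must be a positive permutation count")
  n <- as.integer(n)
  is_ref <- x$labels %in% x$reference
  .assert(!is.null(x$labels) && !is.null(x$reference), "config",
          "labels and a reference level are required")
  .assert(any(is_ref) && any(!is_ref), "config",
          "both conditions must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  prep <- .set_prep(rownames(x$values), sets, denominator_mode)
  v <- x$values
  es_obs <- .es_matrix(v, prep$memb, prep$denom, which(!is_ref), which(is_ref))

  if (statistic == "mean_C1") {
    obs <- rowMeans(es_obs)
    es_perm <- matrix(NA_real_, nrow = n, ncol = length(obs),
                      dimnames = list(NULL, names(obs)))
    for (i in seq_len(n)) {
      perm <- sample(is_ref)
      es_perm[i, ] <- .mean_es_stat(v, prep$memb, prep$denom,
                                    which(!perm), which(perm))
    }
    count <- colSums(es_perm >= rep(obs, each = n))
    tab <- data.frame(set = names(obs), es_obs = unname(obs),
                      p = unname(count / n),
                      p_corrected = unname((count + 1) / (n + 1)),
                      row.names = NULL)
  } else {
    null_pool <- vector("list", n)
    for (i in seq_len(n)) {
      perm <- sample(is_ref)
      null_pool[[i]] <- .es_matrix(v, prep$memb, prep$denom,
                                   which(!perm), which(perm))
    }
    pool <- do.call(cbind, null_pool)      # sets x (n * |C1|)
    tot <- ncol(pool)
    tab <- do.call(rbind, lapply(rownames(es_obs), function(nm) {
      cnt <- vapply(seq_len(ncol(es_obs)),
                    function(j) sum(pool[nm, ] >= es_obs[nm, j]), numeric(1))
      data.frame(set = nm, sample = colnames(es_obs),
                 es_obs = es_obs[nm, ], p = cnt / tot,
                 p_corrected = (cnt + 1) / (tot + 1), row.names = NULL)
    }))
    es_perm <- pool
  }
  if (bh) tab$p_bh <- p.adjust(tab$p, method = "BH")
  structure(list(table = tab, es_perm = es_perm, n = n,
                 statistic = if (statistic == "mean_C1") "mean_ES_over_C1"
                             else "per_sample_ES",
                 seed = seed),
            class = "gdgse_perm")
}

#' @export
print.gdgse_perm <- function(x, ...) {
  cat(sprintf("Permutation test (%s), n = %d permutations%s\n", x$statistic,
              x$n, if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  print(head(x$table, 10L))
  if (nrow(x$table) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x$table) - 10L))
  invisible(x)
}

#' Label-permutation null calibration
#'
#' Measures false-positive behaviour under a true null: the sample labels
#' are shuffled `n_perm` times to destroy any label-expression association,
#' and for each shuffled dataset a permutation p-value is computed for every
#' gene set (with `n_inner` fresh inner permutations), yielding a null
#' p-value matrix (sets by permutations). All null p-values are pooled and
#' sorted, binned into `n_bins` equal-width quantile bins, and the mean
#' observed versus expected -log10(p) per bin is reported together with a
#' least-squares QQ slope (through the origin) and a Kolmogorov-Smirnov
#' uniformity test. A well-calibrated procedure has slope near 1 and an
#' approximately uniform pooled distribution.
#'
#' Observed p-values of exactly 0 are floored at `1 / (2 * n_inner)` on the
#' log scale only; the number of floored values is reported.
#'
#' @param x a [gdgse_expr()] object with labels and a reference level;
#'   expression should carry no true label association.
#' @param sets a [gene_sets()] collection.
#' @param n_perm number of outer label shuffles (columns of the p-matrix).
#' @param n_inner permutations per inner significance test.
#' @param n_bins number of quantile bins (default 100); coarsened with a
#'   warning when fewer pooled p-values than bins are available.
#' @param seed optional integer seed.
#' @param denominator_mode see [score_gene_sets()].
#' @return An object of class `gdgse_calibration`: list with `p_matrix`,
#'   `bins` (data.frame with per-bin counts and mean expected/observed
#'   -log10 p), `qq_slope`, `ks_statistic`, `ks_pvalue`, `n_zero_floored`,
#'   `degenerate` flag, and the calibration parameters.
#' @export
null_calibration <- function(x, sets, n_perm = 200, n_inner = n_perm,
                             n_bins = 100, seed = NULL,
                             denominator_mode = c("measured", "full")) {
  .assert(n_perm >= 1 && n_inner >= 1, "input",
          "'n_perm' and 'n_inner' must be positive")
  is_ref <- x$labels %in% x$reference
  .assert(any(is_ref) && any(!is_ref), "config",
          "both conditions must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  prep <- .set_prep(rownames(x$values), sets, denominator_mode)
  v <- x$values
  n_sets <- nrow(prep$memb)
  p_matrix <- matrix(NA_real_, nrow = n_sets, ncol = n_perm,
                     dimnames = list(rownames(prep$memb), NULL))
  for (o in seq_len(n_perm)) {
    lab_o <- sample(is_ref)                     # shuffled "observed" dataset
    obs <- .mean_es_stat(v, prep$memb, prep$denom,
                         which(!lab_o), which(lab_o))
    count <- numeric(n_sets)
    for (j in seq_len(n_inner)) {
      perm <- sample(lab_o)
      stat <- .mean_es_stat(v, prep$memb, prep$denom,
                            which(!perm), which(perm))
      count <- count + (stat >= obs)
    }
    p_matrix[, o] <- count / n_inner
  }

  pooled <- sort(as.vector(p_matrix))
  N <- length(pooled)
  if (N < n_bins) {
    n_bins <- max(1L, N)
    warning(sprintf("too few pooled p-values for requested bins; using %d bins",
                    n_bins))
  }
  expected_q <- (seq_len(N) - 0.5) / N
  bin <- pmin(n_bins, ceiling(expected_q * n_bins))
  floor_p <- 1 / (2 * n_inner)
  n_zero <- sum(pooled == 0)
  obs_nl <- -log10(pmax(pooled, floor_p))
  exp_nl <- -log10(expected_q)
  bins <- data.frame(
    bin = seq_len(n_bins),
    lo = (seq_len(n_bins) - 1L) / n_bins,
    hi = seq_len(n_bins) / n_bins,
    n = as.integer(tabulate(bin, nbins = n_bins)),
    expected_neglog10 = as.numeric(tapply(exp_nl, factor(bin, levels = seq_len(n_bins)), mean)),
    observed_neglog10 = as.numeric(tapply(obs_nl, factor(bin, levels = seq_len(n_bins)), mean)))
  if (any(bins$n == 0L))
    warning(sprintf("%d empty quantile bin(s) flagged", sum(bins$n == 0L)))
  ok <- bins$n > 0L
  qq_slope <- sum(bins$observed_neglog10[ok] * bins$expected_neglog10[ok]) /
    sum(bins$expected_neglog10[ok]^2)
  degenerate <- all(p_matrix == 1)
  ks <- suppressWarnings(ks.test(pooled, "punif"))
  structure(list(p_matrix = p_matrix, bins = bins, qq_slope = qq_slope,
                 ks_statistic = unname(ks$statistic),
                 ks_pvalue = unname(ks$p.value),
                 n_zero_floored = n_zero, degenerate = degenerate,
                 n_perm = n_perm, n_inner = n_inner, n_bins = n_bins,
                 seed = seed),
            class = "gdgse_calibration")
}

#' @export
print.gdgse_calibration <- function(x, ...) {
  cat(sprintf("Null calibration: %d sets x %d label shuffles (inner n = %d)\n",
              nrow(x$p_matrix), x$n_perm, x$n_inner))
  cat(sprintf("  QQ slope: %.3f  KS statistic: %.4f (p = %.3g)\n",
              x$qq_slope, x$ks_statistic, x$ks_pvalue))
  if (x$n_zero_floored > 0L)
    cat(sprintf("  %d zero p-value(s) floored at %.4g on the log scale\n",
                x$n_zero_floored, 1 / (2 * x$n_inner)))
  if (x$degenerate)
    cat("  WARNING: degenerate null distribution (all p = 1)\n")
  invisible(x)
}

#' @export
plot.gdgse_calibration <- function(x, ...) {
  ok <- x$bins$n > 0L
  plot(x$bins$expected_neglog10[ok], x$bins$observed_neglog10[ok],
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)),
       main = "Null p-value calibration", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
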