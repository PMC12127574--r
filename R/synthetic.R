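#' Simulate a two-condition expression matrix with planted gene sets
#'
#' Generates a genes-by-samples matrix on a normalized-expression-like
#' scale. Per-gene baselines are drawn once and shared across conditions:
#' baseline means are lognormal, per-gene standard deviations scale with the
#' mean (floored away from zero), and values are Gaussian around the
#' baseline, truncated at zero to honour the non-negativity of normalized
#' expression. Member genes of each planted set are shifted upward by
#' `delta` reference standard deviations in the query (C1) samples only;
#' decoy sets are drawn from unshifted genes. All sets use disjoint genes so
#' the ground truth is unambiguous.
#'
#' @param n_genes,n_c1,n_c2 problem dimensions (genes, query samples,
#'   reference samples).
#' @param n_planted,n_decoy number of planted (shifted) and decoy sets.
#' @param set_size genes per set.
#' @param delta effect size in units of the per-gene standard deviation;
#'   recycled across planted sets.
#' @param baseline_meanlog,baseline_sdlog lognormal hyperparameters of the
#'   per-gene baseline means.
#' @param cv per-gene standard deviation as a fraction of the baseline mean.
#' @param min_sd floor on the per-gene standard deviation.
#' @param dropout_rate probability of Bernoulli zero-masking per entry
#'   (single-cell mode; 0 disables).
#' @param seed optional integer seed; fixed seeds give bit-identical output.
#' @return A list with `expr` (a [gdgse_expr()] with labels `"tumor"` /
#'   `"normal"`, reference `"normal"`), `sets` (a [gene_sets()] collection)
#'   and `truth` (data.frame: set, planted flag, delta).
#' @examples
#' sim <- simulate_two_condition(n_genes = 500, n_c1 = 10, n_c2 = 10,
#'                               delta = 2, seed = 7)
#' sim$truth
#' @export
simulate_two_condition <- function(n_genes = 2000, n_c1 = 20, n_c2 = 20,
                                   n_planted = 5, n_decoy = 5, set_size = 25,
                                   delta = 2,
                                   baseline_meanlog = 1.5, baseline_sdlog = 0.7,
                                   cv = 0.4, min_sd = 0.5,
                                   dropout_rate = 0, seed = NULL) {
  .assert(n_genes >= 1 && n_c1 >= 1 && n_c2 >= 1, "input",
          "matrix dimensions must be positive")
  .assert(dropout_rate >= 0 && dropout_rate <= 1, "input",
          "'dropout_rate' must be in [0, 1]")
  .assert(all(delta >= 0), "input", "'delta' must be non-negative")
  n_sets <- n_planted + n_decoy
  .assert(n_sets >= 1, "input", "at least one set must be generated")
  .assert(n_sets * set_size <= n_genes, "input",
          sprintf("sets need %d disjoint genes but only %d are available",
                  n_sets * set_size, n_genes))
  if (!is.null(seed)) set.seed(seed)

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- c(sprintf("T%03d", seq_len(n_c1)), sprintf("N%03d", seq_len(n_c2)))
  labels <- c(rep("tumor", n_c1), rep("normal", n_c2))

  m_g <- rlnorm(n_genes, meanlog = baseline_meanlog, sdlog = baseline_sdlog)
  s_g <- pmax(min_sd, cv * m_g)
  values <- matrix(rnorm(n_genes * (n_c1 + n_c2), mean = m_g, sd = s_g),
                   nrow = n_genes,
                   dimnames = list(gene_ids, sample_ids))
  values <- pmax(values, 0)

  pool <- sample(gene_ids, n_sets * set_size)
  members <- split(pool, rep(seq_len(n_sets), each = set_size))
  set_names <- c(if (n_planted > 0) sprintf("PLANTED_%02d", seq_len(n_planted)),
                 if (n_decoy > 0) sprintf("DECOY_%02d", seq_len(n_decoy)))
  names(members) <- set_names
  delta_vec <- c(if (n_planted > 0) rep_len(delta, n_planted),
                 if (n_decoy > 0) rep(0, n_decoy))
  names(delta_vec) <- set_names

  if (n_planted > 0 && n_c1 > 0) {
    for (k in seq_len(n_planted)) {
      g <- members[[k]]
      values[g, seq_len(n_c1)] <-
        values[g, seq_len(n_c1)] + delta_vec[k] * s_g[match(g, gene_ids)]
    }
  }
  if (dropout_rate > 0)
    values[matrix(runif(length(values)) < dropout_rate,
                  nrow = nrow(values))] <- 0

  list(expr = gdgse_expr(values, labels = labels, reference = "normal"),
       sets = gene_sets(members),
       truth = data.frame(set = set_names,
                          planted = grepl("^PLANTED", set_names),
                          delta = unname(delta_vec)))
}

#' Simulate a single-cell expression matrix
#'
#' Two modes. `mode = "two_condition"` produces the bulk simulation of
#' [simulate_two_condition()] followed by independent Bernoulli zero-masking
#' of entries at `dropout_rate`, emulating dropout: the frequent undetected
#' expression of genes in single-cell data. `mode = "cell_types"` generates
#' `n_types` cell types, each with its own signature set upshifted by
#' `delta` per-gene standard deviations in that type's cells, and labels the
#' cells by type for one-vs-rest scoring.
#'
#' @inheritParams simulate_two_condition
#' @param mode `"two_condition"` or `"cell_types"`.
#' @param n_types number of cell types (cell-type mode).
#' @param cells_per_type cells per type (cell-type mode).
#' @return For `"two_condition"`, the list of [simulate_two_condition()];
#'   for `"cell_types"`, a list with `expr` (labels = cell types, no
#'   reference), `sets` (one signature per type, named by type) and `truth`.
#' @export
simulate_single_cell <- function(mode = c("two_condition", "cell_types"),
                                 n_genes = 2000, set_size = 25, delta = 2,
                                 dropout_rate = 0.6,
                                 n_c1 = 100, n_c2 = 100,
                                 n_planted = 5, n_decoy = 5,
                                 n_types = 3, cells_per_type = 50,
                                 baseline_meanlog = 1.5, baseline_sdlog = 0.7,
                                 cv = 0.4, min_sd = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "two_condition")
    return(simulate_two_condition(n_genes = n_genes, n_c1 = n_c1, n_c2 = n_c2,
                                  n_planted = n_planted, n_decoy = n_decoy,
                                  set_size = set_size, delta = delta,
                                  baseline_meanlog = baseline_meanlog,
                                  baseline_sdlog = baseline_sdlog,
                                  cv = cv, min_sd = min_sd,
                                  dropout_rate = dropout_rate, seed = seed))
  .assert(n_types >= 2, "input", "cell-type mode needs at least two types")
  .assert(n_types * set_size <= n_genes, "input",
          "not enough genes for disjoint type signatures")
  .assert(dropout_rate >= 0 && dropout_rate <= 1, "input",
          "'dropout_rate' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_cells <- n_types * cells_per_type
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  cell_ids <- sprintf("c%04d", seq_len(n_cells))
  types <- sprintf("type%d", seq_len(n_types))
  labels <- rep(types, each = cells_per_type)

  m_g <- rlnorm(n_genes, meanlog = baseline_meanlog, sdlog = baseline_sdlog)
  s_g <- pmax(min_sd, cv * m_g)
  values <- matrix(rnorm(n_genes * n_cells, mean = m_g, sd = s_g),
                   nrow = n_genes, dimnames = list(gene_ids, cell_ids))
  values <- pmax(values, 0)

  pool <- sample(gene_ids, n_types * set_size)
  members <- split(pool, rep(seq_len(n_types), each = set_size))
  names(members) <- types
  for (t in seq_len(n_types)) {
    g <- members[[t]]
    in_t <- labels == types[t]
    values[g, in_t] <- values[g, in_t] + delta * s_g[match(g, gene_ids)]
  }
  if (dropout_rate > 0)
    values[matrix(runif(length(values)) < dropout_rate,
                  nrow = nrow(values))] <- 0
  list(expr = gdgse_expr(values, labels = labels),
       sets = gene_sets(members),
       truth = data.frame(set = types, planted = TRUE, delta = delta))
}

#' Aggregate single cells into pseudobulk samples
#'
#' Sums raw expression per gene across the cells assigned to each
#' pseudobulk sample, emulating bulk-level resolution. Total counts per
#' gene are conserved. Labels are inherited from the cells: each pseudobulk
#' sample takes the (unique) label of its cells; mixed-label groups are an
#' error unless `labels` overrides them.
#'
#' @param x a [gdgse_expr()] object (cells in columns).
#' @param assignment character/factor of pseudobulk sample ids, one per
#'   cell (positional, or named by cell id). Every cell must be assigned.
#' @param labels optional named vector: label per pseudobulk sample,
#'   overriding inheritance.
#' @param reference optional reference level for the result.
#' @return A [gdgse_expr()] object, genes by pseudobulk samples.
#' @export
aggregate_pseudobulk <- function(x, assignment, labels = NULL,
                                 reference = NULL) {
  .assert(inherits(x, "gdgse_expr"), "input", "'x' must be a gdgse_expr")
  cells <- colnames(x$values)
  if (!is.null(names(assignment))) {
    missing <- setdiff(cells, names(assignment))
    .assert(length(missing) == 0L, "input",
            paste0("unassigned cells: ", paste(head(missing, 5L), collapse = ", ")))
    assignment <- assignment[cells]
  } else {
    .assert(length(assignment) == length(cells), "input",
            "'assignment' must cover every cell")
  }
  .assert(!anyNA(assignment), "input", "unassigned (NA) cells")
  assignment <- as.character(assignment)
  groups <- unique(assignment)
  agg <- vapply(groups,
                function(g) rowSums(x$values[, assignment == g, drop = FALSE]),
                numeric(nrow(x$values)))
  dimnames(agg) <- list(rownames(x$values), groups)
  if (is.null(labels) && !is.null(x$labels)) {
    labels <- vapply(groups, function(g) {
      lv <- unique(x$labels[assignment == g])
      .assert(length(lv) == 1L, "input",
              sprintf("pseudobulk sample '%s' mixes labels (%s); pass 'labels' explicitly",
                      g, paste(lv, collapse = ", ")))
      lv
    }, character(1))
  }
  gdgse_expr(agg, labels = labels,
             reference = if (is.null(reference)) {
               if (!is.null(labels) && !is.null(x$reference) &&
                   any(labels %in% x$reference)) x$reference else NULL
             } else reference)
}

#' Inject additive Gaussian noise
#'
#' Adds an iid Gaussian noise matrix of identical shape to the whole
#' expression matrix (all samples, both conditions): entrywise
#' `v + N(noise_mean, noise_sd)`. No clamping at zero is applied by default
#' (literal addition); `clamp = TRUE` truncates negative results at 0 for
#' count-like downstream use. The defaults follow the robustness protocol
#' of noise mean 0.01 with standard deviations on a 0.01-0.06 grid
#' (`noise_sd_grid()`).
#'
#' @param x a [gdgse_expr()] object.
#' @param noise_mean mean of the noise distribution (default 0.01).
#' @param noise_sd standard deviation of the noise (must be >= 0).
#' @param seed optional integer seed.
#' @param clamp truncate negative post-noise values at zero.
#' @return A [gdgse_expr()] object with the same labels and reference.
#' @export
inject_gaussian_noise <- function(x, noise_mean = 0.01, noise_sd,
                                  seed = NULL, clamp = FALSE) {
  .assert(inherits(x, "gdgse_expr"), "input", "'x' must be a gdgse_expr")
  .assert(is.numeric(noise_sd) && length(noise_sd) == 1L && noise_sd >= 0,
          "input", "'noise_sd' must be a single non-negative number")
  if (!is.null(seed)) set.seed(seed)
  noisy <- x$values + rnorm(length(x$values), mean = noise_mean, sd = noise_sd)
  if (clamp) noisy <- pmax(noisy, 0)
  out <- x
  out$values <- matrix(noisy, nrow = nrow(x$values),
                       dimnames = dimnames(x$values))
  out
}

#' Standard-deviation grid of the noise-robustness protocol
#'
#' @return The numeric vector `c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)`.
#' @export
noise_sd_grid <- function() c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)
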