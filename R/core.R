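#' Per-gene reference statistics
#'
#' Computes, for every gene, the mean and standard deviation of its
#' expression across the reference-condition (C2) samples. These define the
#' binarization threshold mu_g + sigma_g used by [binarize()].
#'
#' The standard deviation uses the population divisor `1/n_ref` (not the
#' usual `n - 1` sample estimator), so a single reference sample yields
#' sigma = 0 for every gene rather than an undefined value.
#'
#' @param x a [gdgse_expr()] object with labels.
#' @param reference reference label level(s); defaults to the one stored in
#'   `x`.
#' @return An object of class `gdgse_refstats`: list with `gene_ids`, `mu`,
#'   `sigma` (both named numeric vectors) and `n_ref`.
#' @examples
#' m <- matrix(c(2, 4, 6, 1, 1, 1), nrow = 1,
#'             dimnames = list("g1", paste0("s", 1:6)))
#' x <- gdgse_expr(m, labels = rep(c("normal", "tumor"), each = 3),
#'                 reference = "normal")
#' st <- reference_stats(x)
#' st$mu     # 4
#' st$sigma  # sqrt(8/3)
#' @export
reference_stats <- function(x, reference = x$reference) {
  .assert(inherits(x, "gdgse_expr"), "input", "'x' must be a gdgse_expr object")
  idx2 <- .c2_idx(x, reference)
  .assert(length(idx2) >= 1L, "config", "no reference (C2) samples")
  ref <- x$values[, idx2, drop = FALSE]
  mu <- rowMeans(ref)
  sigma <- if (length(idx2) == 1L) {
    stats::setNames(numeric(nrow(ref)), rownames(ref))
  } else {
    sqrt(rowMeans((ref - mu)^2))   # population divisor 1/|C2|
  }
  structure(list(gene_ids = rownames(x$values), mu = mu, sigma = sigma,
                 n_ref = length(idx2)),
            class = "gdgse_refstats")
}

#' @export
print.gdgse_refstats <- function(x, ...) {
  cat(sprintf("Reference statistics for %d genes over %d C2 sample(s)\n",
              length(x$gene_ids), x$n_ref))
  cat(sprintf("  mu: [%.4g, %.4g]  sigma: [%.4g, %.4g]\n",
              min(x$mu), max(x$mu), min(x$sigma), max(x$sigma)))
  invisible(x)
}

#' Binarize expression against reference statistics
#'
#' Discretizes the expression matrix: entry (g, s) becomes 1 exactly when
#' v(g, s) strictly exceeds mu_g + sigma_g, and 0 otherwise. Values equal to
#' the threshold map to 0. Genes with sigma = 0 are kept; their threshold
#' degenerates to mu_g.
#'
#' @param x a [gdgse_expr()] object.
#' @param stats a `gdgse_refstats` object; gene identifiers must match those
#'   of `x` as a set (order may differ, statistics are realigned by id).
#' @param which `"C1"` (default) scores only query samples; `"all"` scores
#'   every sample, as needed for one-vs-rest comparisons.
#' @return Integer 0/1 matrix, genes by scored samples.
#' @export
binarize <- function(x, stats = reference_stats(x), which = c("C1", "all")) {
  which <- match.arg(which)
  .assert(inherits(x, "gdgse_expr"), "input", "'x' must be a gdgse_expr object")
  .assert(inherits(stats, "gdgse_refstats"), "input",
          "'stats' must come from reference_stats()")
  .assert(setequal(stats$gene_ids, rownames(x$values)) &&
            length(stats$gene_ids) == nrow(x$values),
          "alignment", "gene identifiers of 'stats' and 'x' do not match")
  ord <- match(rownames(x$values), stats$gene_ids)
  thr <- stats$mu[ord] + stats$sigma[ord]
  cols <- if (which == "C1") .c1_idx(x) else seq_len(ncol(x$values))
  .assert(length(cols) >= 1L, "config", "no samples selected for scoring")
  v <- x$values[, cols, drop = FALSE]
  out <- (v > thr) + 0L
  storage.mode(out) <- "integer"
  out
}

## Build the set-membership machinery once: indicator matrix (sets x genes,
## restricted to measured members) and the scoring denominators.
.set_prep <- function(gene_ids, sets, denominator_mode = c("measured", "full")) {
  denominator_mode <- match.arg(denominator_mode)
  .assert(inherits(sets, "gdgse_sets"), "input",
          "'sets' must be a gene_sets() collection")
  measured <- lapply(unclass(sets), function(m) intersect(m, gene_ids))
  genes_measured <- lengths(measured)
  dropped <- names(sets)[genes_measured == 0L]
  keep <- names(sets)[genes_measured > 0L]
  .assert(length(keep) > 0L, "input",
          "no gene set has any member in the expression matrix")
  if (length(dropped) > 0L)
    warning(sprintf("%d gene set(s) with no measured members dropped: %s",
                    length(dropped), paste(head(dropped, 5L), collapse = ", ")))
  memb <- matrix(0, nrow = length(keep), ncol = length(gene_ids),
                 dimnames = list(keep, gene_ids))
  for (nm in keep) memb[nm, measured[[nm]]] <- 1
  denom <- if (denominator_mode == "measured") genes_measured[keep]
           else lengths(sets)[keep]
  list(memb = memb, denom = denom, genes_measured = genes_measured[keep],
       set_size = lengths(sets)[keep], dropped = dropped,
       denominator_mode = denominator_mode)
}

#' Score gene sets on a binarized matrix
#'
#' The enrichment score of a gene set in a sample is the number of its
#' member genes with binarized value 1 in that sample divided by the set
#' size, hence an exact multiple of 1/denominator in `[0, 1]`.
#'
#' Member genes absent from the expression matrix do not contribute to the
#' count; by default (`denominator_mode = "measured"`) they are also removed
#' from the denominator, so that incomplete measurement does not
#' deterministically deflate scores. `denominator_mode = "full"` divides by
#' the literal set size G instead. Sets with no measured members are dropped
#' with a warning and listed in the result.
#'
#' @param bin 0/1 matrix from [binarize()], genes by samples.
#' @param sets a [gene_sets()] collection.
#' @param denominator_mode `"measured"` (default) or `"full"`.
#' @return An object of class `gdgse` (see [gdgse()]).
#' @export
score_gene_sets <- function(bin, sets, denominator_mode = c("measured", "full")) {
  .assert(is.matrix(bin) && all(bin %in% c(0L, 1L)), "input",
          "'bin' must be a 0/1 matrix")
  prep <- .set_prep(rownames(bin), sets, denominator_mode)
  scores <- (prep$memb %*% bin) / prep$denom
  structure(list(scores = scores,
                 genes_measured = prep$genes_measured,
                 set_size = prep$set_size,
                 dropped_sets = prep$dropped,
                 denominator_mode = prep$denominator_mode),
            class = "gdgse")
}

#' Gene set enrichment by discretized expression
#'
#' End-to-end driver: computes per-gene reference statistics over the C2
#' samples, binarizes expression at the per-gene threshold mu_g + sigma_g,
#' and scores every gene set in every scored sample as the fraction of its
#' member genes above threshold. Scores lie in `[0, 1]`; a score of 1 means
#' every measured member gene exceeds its reference threshold in that
#' sample.
#'
#' The method is deterministic, preserves the input sample order, and is
#' invariant to per-gene affine rescaling applied to all samples (adding a
#' constant to a gene everywhere, or multiplying it by a positive factor,
#' moves the threshold with the data and leaves all scores unchanged).
#'
#' @param x a [gdgse_expr()] object with condition labels and a reference
#'   level.
#' @param sets a [gene_sets()] collection.
#' @param which score only the query (C1) samples (default) or all samples.
#' @param denominator_mode see [score_gene_sets()].
#' @return An object of class `gdgse`: list with `scores` (sets by samples
#'   matrix), `genes_measured`, `set_size`, `dropped_sets`,
#'   `denominator_mode`, `n_ref`, `reference`.
#' @examples
#' sim <- simulate_two_condition(n_genes = 300, n_c1 = 6, n_c2 = 6,
#'                               delta = 3, seed = 1)
#' fit <- gdgse(sim$expr, sim$sets)
#' fit
#' summary(fit)
#' @export
gdgse <- function(x, sets, which = c("C1", "all"),
                  denominator_mode = c("measured", "full")) {
  which <- match.arg(which)
  st <- reference_stats(x)
  bin <- binarize(x, st, which = which)
  fit <- score_gene_sets(bin, sets, denominator_mode)
  fit$n_ref <- st$n_ref
  fit$reference <- x$reference
  fit$which <- which
  fit$call <- match.call()
  fit
}

#' @export
print.gdgse <- function(x, ...) {
  cat(sprintf("Gene set enrichment matrix: %d sets x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  cat(sprintf("  denominator: %s; scores in [%.3f, %.3f]\n",
              x$denominator_mode, min(x$scores), max(x$scores)))
  if (!is.null(x$n_ref))
    cat(sprintf("  reference: %s (%d samples)\n",
                paste(x$reference, collapse = ", "), x$n_ref))
  if (length(x$dropped_sets) > 0L)
    cat(sprintf("  dropped (no measured members): %s\n",
                paste(x$dropped_sets, collapse = ", ")))
  invisible(x)
}

#' @export
summary.gdgse <- function(object, ...) {
  s <- object$scores
  out <- data.frame(
    gene_set = rownames(s),
    genes_measured = as.integer(object$genes_measured[rownames(s)]),
    set_size = as.integer(object$set_size[rownames(s)]),
    mean_es = rowMeans(s),
    min_es = apply(s, 1L, min),
    max_es = apply(s, 1L, max),
    row.names = NULL)
  class(out) <- c("summary.gdgse", "data.frame")
  out
}

#' @export
as.matrix.gdgse <- function(x, ...) x$scores

#' @export
plot.gdgse <- function(x, ...) {
  s <- x$scores
  if (nrow(s) >= 2L && ncol(s) >= 2L) {
    stats::heatmap(s, scale = "none", ...)
  } else {
    barplot(as.numeric(s), names.arg = colnames(s), ylim = c(0, 1),
            ylab = "enrichment score", main = rownames(s)[1L], ...)
  }
  invisible(x)
}

#' One-vs-rest cell-type signature scoring
#'
#' For each cell type t, the reference condition is taken to be all cells
#' NOT of type t; reference statistics are computed from that complement,
#' every cell is binarized against them, and the enrichment score of t's
#' signature set is computed for every cell. Rows are stacked across types
#' into one types-by-cells matrix, enabling in-type versus out-of-type mean
#' comparisons (see [fold_change_of_means()]).
#'
#' @param x a [gdgse_expr()] object whose labels are cell types (at least
#'   two types, each with at least one cell).
#' @param signatures a [gene_sets()] collection whose set names are cell
#'   types present in `x`'s labels; only the named types are scored.
#' @param denominator_mode see [score_gene_sets()].
#' @return An object of class `gdgse_ovr` (inherits `gdgse`), with `scores`
#'   a types-by-cells matrix and `labels` the cell-type vector.
#' @export
one_vs_rest <- function(x, signatures,
                        denominator_mode = c("measured", "full")) {
  denominator_mode <- match.arg(denominator_mode)
  .assert(inherits(x, "gdgse_expr") && !is.null(x$labels), "input",
          "'x' must be a gdgse_expr with cell-type labels")
  types <- unique(x$labels)
  .assert(length(types) >= 2L, "config",
          "one-vs-rest needs at least two cell types")
  .assert(inherits(signatures, "gdgse_sets"), "input",
          "'signatures' must be a gene_sets() collection")
  missing <- setdiff(names(signatures), types)
  .assert(length(missing) == 0L, "config",
          paste0("signature(s) without a matching cell type: ",
                 paste(missing, collapse = ", ")))
  rows <- lapply(names(signatures), function(t) {
    xt <- x
    xt$reference <- setdiff(types, t)   # C2 = every other type
    st <- reference_stats(xt)
    bin <- binarize(xt, st, which = "all")
    score_gene_sets(bin, signatures[t], denominator_mode)$scores
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- names(signatures)
  prep <- .set_prep(rownames(x$values), signatures, denominator_mode)
  structure(list(scores = scores,
                 genes_measured = prep$genes_measured,
                 set_size = prep$set_size,
                 dropped_sets = prep$dropped,
                 denominator_mode = denominator_mode,
                 labels = x$labels),
            class = c("gdgse_ovr", "gdgse"))
}

#' @export
summary.gdgse_ovr <- function(object, ...) {
  out <- do.call(rbind, lapply(rownames(object$scores), function(t) {
    sc <- object$scores[t, ]
    in_t <- object$labels == t
    data.frame(cell_type = t,
               n_cells = sum(in_t),
               mean_in = mean(sc[in_t]),
               mean_out = mean(sc[!in_t]),
               fold_change = fold_change_of_means(sc, in_t))
  }))
  rownames(out) <- NULL
  out
}

#' Fold change of mean enrichment scores
#'
#' Ratio of the mean score in an in-group over the mean score in the
#' out-group, used to summarize how much higher a cell type's signature
#' scores are in its own cells than elsewhere. Conventions: if the
#' out-group mean is 0 and the in-group mean positive, `Inf` is returned;
#' if both means are 0, 1 is returned (the groups are indistinguishable).
#'
#' @param scores numeric vector of enrichment scores.
#' @param groups logical vector (`TRUE` = in-group) or a label vector
#'   combined with `in_level`.
#' @param in_level when `groups` is a label vector, the level forming the
#'   in-group.
#' @return A single number (possibly `Inf`).
#' @examples
#' fold_change_of_means(c(0.8, 0.6, 0.2, 0.3, 0.2),
#'                      c(TRUE, TRUE, FALSE, FALSE, FALSE))  # ~ 3
#' @export
fold_change_of_means <- function(scores, groups, in_level = NULL) {
  if (!is.logical(groups)) {
    .assert(!is.null(in_level), "input",
            "'in_level' required when 'groups' is not logical")
    groups <- as.character(groups) == as.character(in_level)
  }
  .assert(length(scores) == length(groups), "input",
          "'scores' and 'groups' lengths differ")
  .assert(any(groups) && any(!groups), "input",
          "both in-group and out-group must be non-empty")
  m_in <- mean(scores[groups])
  m_out <- mean(scores[!groups])
  if (m_out == 0) {
    if (m_in == 0) return(1)
    return(Inf)
  }
  m_in / m_out
}
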