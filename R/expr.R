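#' Labeled expression matrix
#'
#' Container for a genes-by-samples expression matrix with an optional
#' per-sample condition (or cell-type) label and a designated reference
#' level. The reference condition (often called C2: normal tissue, control
#' cells, or "all other cell types") supplies the per-gene statistics that
#' the binarization threshold is built from; all remaining samples form the
#' query condition (C1).
#'
#' Values are expected on a non-negative normalized scale (e.g. RSEM, CPM);
#' they are consumed as provided, with no internal log-transform or
#' renormalization. Small negative values (e.g. after additive noise
#' injection) are tolerated.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names.
#' @param labels character or factor of per-sample labels. May be named by
#'   sample id (any order) or positional (length `ncol(values)`). `NULL`
#'   leaves the matrix unlabeled until [attach_labels()] is used.
#' @param reference label level(s) whose samples form the reference
#'   condition C2. `NULL` defers the choice (required for cell-type data
#'   scored with [one_vs_rest()]).
#' @param impute_missing if `TRUE`, `NA` entries are replaced by 0 instead
#'   of being rejected.
#' @return An object of class `gdgse_expr`: a list with elements `values`,
#'   `labels` (named by sample, or `NULL`) and `reference`.
#' @examples
#' m <- matrix(c(1, 3, 4, 2, 5, 7), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' x <- gdgse_expr(m, labels = c("tumor", "normal", "normal"), reference = "normal")
#' x
#' @export
gdgse_expr <- function(values, labels = NULL, reference = NULL,
                       impute_missing = FALSE) {
  .assert(is.matrix(values) && is.numeric(values), "input",
          "'values' must be a numeric matrix (genes x samples)")
  .assert(!is.null(rownames(values)) && !is.null(colnames(values)), "input",
          "'values' must have gene row names and sample column names")
  dup_g <- rownames(values)[duplicated(rownames(values))]
  .assert(length(dup_g) == 0L, "data",
          paste0("duplicate gene identifiers: ",
                 paste(unique(dup_g), collapse = ", ")))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  .assert(length(dup_s) == 0L, "data",
          paste0("duplicate sample identifiers: ",
                 paste(unique(dup_s), collapse = ", ")))
  if (anyNA(values)) {
    if (impute_missing) {
      values[is.na(values)] <- 0
    } else {
      bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
      .gdgse_error("data", sprintf(
        "missing value at gene '%s', sample '%s' (use impute_missing = TRUE to zero-fill)",
        rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
    }
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    .gdgse_error("data", sprintf("non-finite value at gene '%s', sample '%s'",
                                 rownames(values)[bad[1L]],
                                 colnames(values)[bad[2L]]))
  }
  if (!is.null(labels)) {
    labels <- .align_labels(labels, colnames(values))
    if (!is.null(reference)) .check_reference(labels, reference)
  } else {
    .assert(is.null(reference), "config",
            "'reference' given but 'labels' is NULL")
  }
  structure(list(values = values, labels = labels,
                 reference = if (is.null(reference)) NULL else as.character(reference)),
            class = "gdgse_expr")
}

.align_labels <- function(labels, sample_ids) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    .assert(length(missing) == 0L, "data",
            paste0("samples without a label: ", paste(missing, collapse = ", ")))
    dup <- names(labels)[duplicated(names(labels))]
    .assert(length(dup) == 0L, "data",
            paste0("duplicated sample ids in labels: ", paste(unique(dup), collapse = ", ")))
    extra <- setdiff(names(labels), sample_ids)
    if (length(extra) > 0L)
      warning(sprintf("%d labeled sample(s) absent from the matrix were ignored: %s",
                      length(extra), paste(head(extra, 5L), collapse = ", ")))
    labels <- labels[sample_ids]
  } else {
    .assert(length(labels) == length(sample_ids), "input",
            sprintf("labels length (%d) != number of samples (%d)",
                    length(labels), length(sample_ids)))
    names(labels) <- sample_ids
  }
  .assert(!anyNA(labels), "data", "labels contain NA")
  labels
}

.check_reference <- function(labels, reference) {
  reference <- as.character(reference)
  .assert(all(reference %in% labels), "config",
          sprintf("reference level(s) %s not present; available levels: %s",
                  paste(setdiff(reference, labels), collapse = ", "),
                  paste(sort(unique(labels)), collapse = ", ")))
  .assert(any(!(labels %in% reference)), "config",
          "all samples are in the reference condition; no query (C1) samples left")
  invisible(TRUE)
}

## column indices of the reference (C2) and query (C1) samples
.c2_idx <- function(x, reference = x$reference) {
  .assert(!is.null(x$labels), "config", "expression matrix has no sample labels")
  .assert(!is.null(reference), "config", "no reference condition set")
  which(x$labels %in% as.character(reference))
}

.c1_idx <- function(x, reference = x$reference) {
  setdiff(seq_len(ncol(x$values)), .c2_idx(x, reference))
}

#' @export
print.gdgse_expr <- function(x, ...) {
  cat(sprintf("Labeled expression matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (is.null(x$labels)) {
    cat("  labels: <none attached>\n")
  } else {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    if (!is.null(x$reference))
      cat("  reference (C2):", paste(x$reference, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.gdgse_expr <- function(x) dim(x$values)

#' @export
as.matrix.gdgse_expr <- function(x, ...) x$values
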