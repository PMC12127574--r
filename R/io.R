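## --- expression matrices ---------------------------------------------------

#' Read an expression matrix
#'
#' Dense TSV/CSV: first column gene identifiers, header row sample
#' identifiers. Sparse MatrixMarket: coordinate `.mtx` file plus sidecar
#' files listing gene and sample/barcode identifiers (10x-style triplet
#' layout; only the first tab-separated field of each sidecar line is
#' used). Identifiers are read as opaque strings and matched
#' case-sensitively; the declared `orientation` is honoured without
#' guessing. Duplicate identifiers, ragged rows and non-numeric cells are
#' rejected with the offending location named.
#'
#' @param path matrix file (`.tsv`/`.csv`/`.mtx`).
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @param genes,samples sidecar identifier files (required for `"mtx"`).
#' @param orientation `"genes_by_samples"` (default) or
#'   `"samples_by_genes"`, in which case the parsed matrix is transposed.
#' @return An unlabeled [gdgse_expr()] object; attach condition labels with
#'   [attach_labels()].
#' @export
read_expression <- function(path,
                            format = c("auto", "tsv", "csv", "mtx"),
                            genes = NULL, samples = NULL,
                            orientation = c("genes_by_samples",
                                            "samples_by_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  .assert(file.exists(path), "parse", paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     .gdgse_error("parse", paste0("cannot infer format from extension: ", path)))
  }
  values <- if (format == "mtx") {
    .read_mtx(path, genes, samples)
  } else {
    .read_dense(path, sep = if (format == "csv") "," else "\t")
  }
  if (orientation == "samples_by_genes") values <- t(values)
  dup <- rownames(values)[duplicated(rownames(values))]
  .assert(length(dup) == 0L, "parse",
          paste0("duplicate gene identifiers: ", paste(unique(dup), collapse = ", ")))
  gdgse_expr(values)
}

.read_dense <- function(path, sep) {
  lines <- readLines(path)
  .assert(length(lines) >= 2L, "parse",
          paste0(path, ": need a header and at least one gene row"))
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  ## header may or may not carry a leading cell for the gene-id column
  n_body <- length(fields[[2L]])
  sample_ids <- if (length(header) == n_body) header[-1L] else header
  .assert(length(sample_ids) == n_body - 1L, "parse",
          sprintf("%s: header has %d sample ids but line 2 has %d data fields",
                  path, length(sample_ids), n_body - 1L))
  dup_s <- sample_ids[duplicated(sample_ids)]
  .assert(length(dup_s) == 0L, "parse",
          paste0(path, ": duplicate sample identifiers in header: ",
                 paste(unique(dup_s), collapse = ", ")))
  body <- fields[-1L]
  n <- lengths(body)
  bad <- which(n != n_body)
  .assert(length(bad) == 0L, "parse",
          sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                  path, bad[1L] + 1L, n[bad[1L]], n_body))
  gene_ids <- vapply(body, `[`, character(1), 1L)
  dup_lines <- which(duplicated(gene_ids))
  .assert(length(dup_lines) == 0L, "parse",
          sprintf("%s: duplicate gene identifier '%s' at line %d",
                  path, gene_ids[dup_lines[1L]], dup_lines[1L] + 1L))
  values <- matrix(NA_real_, nrow = length(body), ncol = n_body - 1L,
                   dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      .gdgse_error("parse", sprintf(
        "%s: non-numeric cell '%s' at line %d (gene '%s', sample '%s')",
        path, body[[i]][j + 1L], i + 1L, gene_ids[i], sample_ids[j]))
    }
    values[i, ] <- v
  }
  values
}

.read_mtx <- function(path, genes, samples) {
  .assert(!is.null(genes) && !is.null(samples), "parse",
          "mtx input needs 'genes' and 'samples' identifier files")
  .assert(file.exists(genes), "parse", paste0("file not found: ", genes))
  .assert(file.exists(samples), "parse", paste0("file not found: ", samples))
  m <- as.matrix(Matrix::readMM(path))
  gene_ids <- vapply(strsplit(readLines(genes), "\t", fixed = TRUE),
                     `[`, character(1), 1L)
  sample_ids <- vapply(strsplit(readLines(samples), "\t", fixed = TRUE),
                       `[`, character(1), 1L)
  .assert(nrow(m) == length(gene_ids), "parse",
          sprintf("mtx has %d rows but %d gene ids", nrow(m), length(gene_ids)))
  .assert(ncol(m) == length(sample_ids), "parse",
          sprintf("mtx has %d columns but %d sample ids", ncol(m), length(sample_ids)))
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' Write an expression matrix
#'
#' Round-trip counterpart of [read_expression()]. Dense output has the gene
#' identifier column first and a header row of sample identifiers; `"mtx"`
#' writes a MatrixMarket coordinate file plus gene and sample sidecars.
#'
#' @param x a [gdgse_expr()] object or genes-by-samples matrix.
#' @param path output file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @param genes,samples sidecar paths (mtx only).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "csv", "mtx"),
                             genes = NULL, samples = NULL) {
  format <- match.arg(format)
  m <- if (inherits(x, "gdgse_expr")) x$values else x
  if (format == "mtx") {
    .assert(!is.null(genes) && !is.null(samples), "input",
            "mtx output needs 'genes' and 'samples' sidecar paths")
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), path)
    writeLines(rownames(m), genes)
    writeLines(colnames(m), samples)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

## --- GMT gene sets ---------------------------------------------------------

#' Read a GMT gene set file
#'
#' Each tab-separated line is `name<TAB>description<TAB>gene1<TAB>gene2...`
#' (at least three fields). Duplicate set names are an error; duplicated
#' members within a set are collapsed with a warning.
#'
#' @param path GMT file.
#' @return A [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "parse", paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) >= 1L, "parse", paste0(path, ": no gene sets"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  .assert(length(short) == 0L, "parse",
          sprintf("%s: line %d has fewer than 3 tab-separated fields",
                  path, short[1L]))
  nms <- vapply(fields, `[`, character(1), 1L)
  dup <- which(duplicated(nms))
  .assert(length(dup) == 0L, "parse",
          sprintf("%s: duplicate set name '%s' at line %d",
                  path, nms[dup[1L]], dup[1L]))
  gene_sets(stats::setNames(lapply(fields, function(f) f[-(1:2)]), nms),
            descriptions = vapply(fields, `[`, character(1), 2L))
}

#' Write a GMT gene set file
#'
#' @param sets a [gene_sets()] collection.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  .assert(inherits(sets, "gdgse_sets"), "input",
          "'sets' must be a gene_sets() collection")
  desc <- attr(sets, "descriptions")
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

## --- labels ----------------------------------------------------------------

#' Attach condition labels to an expression matrix
#'
#' Labels come from a two-column TSV (sample_id, label; no header), a
#' data.frame with those two columns, or a named vector. Every sample in
#' the matrix must be labeled exactly once; labeled samples absent from the
#' matrix are ignored with a warning. The `reference` level must be present
#' among the attached labels.
#'
#' @param x a [gdgse_expr()] object.
#' @param labels path, data.frame or named character vector.
#' @param reference label level(s) forming the reference (C2) condition;
#'   `NULL` leaves the role unassigned (cell-type mode).
#' @return A labeled [gdgse_expr()] object.
#' @export
attach_labels <- function(x, labels, reference = NULL) {
  .assert(inherits(x, "gdgse_expr"), "input", "'x' must be a gdgse_expr")
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    df <- utils::read.table(labels, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
    .assert(ncol(df) >= 2L, "parse",
            paste0(labels, ": expected two tab-separated columns (sample_id, label)"))
    labels <- stats::setNames(df[[2L]], df[[1L]])
  } else if (is.data.frame(labels)) {
    .assert(ncol(labels) >= 2L, "input",
            "labels data.frame needs columns (sample_id, label)")
    labels <- stats::setNames(as.character(labels[[2L]]),
                              as.character(labels[[1L]]))
  } else {
    .assert(!is.null(names(labels)), "input",
            "label vector must be named by sample id")
  }
  dup <- names(labels)[duplicated(names(labels))]
  .assert(length(dup) == 0L, "data",
          paste0("sample(s) labeled more than once: ",
                 paste(unique(dup), collapse = ", ")))
  gdgse_expr(x$values, labels = labels, reference = reference)
}

## --- enrichment output -----------------------------------------------------

#' Write an enrichment matrix with JSON sidecar
#'
#' Writes the sets-by-samples score matrix as TSV (first column `gene_set`,
#' header row of sample identifiers) and, by default, a JSON sidecar at
#' `<path>.json` recording the denominator mode, genes measured per set and
#' any dropped sets.
#'
#' @param fit a `gdgse` fit.
#' @param path output TSV path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_scores <- function(fit, path, sidecar = TRUE) {
  .assert(inherits(fit, "gdgse"), "input", "'fit' must be a gdgse object")
  df <- data.frame(gene_set = rownames(fit$scores), fit$scores,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(denominator_mode = fit$denominator_mode,
           genes_measured = as.list(fit$genes_measured),
           set_size = as.list(fit$set_size),
           dropped_sets = fit$dropped_sets),
      paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read an enrichment matrix written by [write_scores()]
#'
#' @param path TSV path.
#' @return Numeric matrix, sets by samples.
#' @export
read_scores <- function(path) {
  m <- .read_dense(path, sep = "\t")
  m
}
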