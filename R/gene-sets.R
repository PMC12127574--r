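#' Gene set collection
#'
#' A named list of gene sets, each a character vector of gene identifiers.
#' Set names must be unique; duplicated genes within a set are collapsed
#' (order otherwise preserved); empty member lists are rejected.
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param descriptions optional character vector of per-set descriptions,
#'   recycled from `""`.
#' @return An object of class `gdgse_sets`.
#' @examples
#' gs <- gene_sets(list(CYCLE = c("CDK1", "CCNB1"), IMMUNE = c("CD3D", "CD8A")))
#' gs
#' @seealso [read_gmt()], [write_gmt()]
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  .assert(is.list(sets) && length(sets) > 0L, "input",
          "'sets' must be a non-empty named list of character vectors")
  .assert(!is.null(names(sets)) && all(nzchar(names(sets))), "input",
          "every gene set must be named")
  dup <- names(sets)[duplicated(names(sets))]
  .assert(length(dup) == 0L, "input",
          paste0("duplicate gene set names: ", paste(unique(dup), collapse = ", ")))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  .assert(length(descriptions) == length(sets), "input",
          "'descriptions' must match the number of sets")
  cleaned <- lapply(names(sets), function(nm) {
    members <- trimws(as.character(sets[[nm]]))
    members <- members[nzchar(members)]
    .assert(length(members) > 0L, "input",
            sprintf("gene set '%s' has no members", nm))
    if (anyDuplicated(members)) {
      warning(sprintf("gene set '%s': duplicated member(s) collapsed", nm))
      members <- members[!duplicated(members)]
    }
    members
  })
  names(cleaned) <- names(sets)
  structure(cleaned, descriptions = stats::setNames(as.character(descriptions),
                                                    names(sets)),
            class = "gdgse_sets")
}

#' @export
print.gdgse_sets <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("Gene set collection: %d sets (sizes %d-%d)\n",
              length(x), min(sizes), max(sizes)))
  for (nm in head(names(x), 5L))
    cat(sprintf("  %s (%d): %s%s\n", nm, length(x[[nm]]),
                paste(head(x[[nm]], 4L), collapse = ", "),
                if (length(x[[nm]]) > 4L) ", ..." else ""))
  if (length(x) > 5L) cat(sprintf("  ... and %d more\n", length(x) - 5L))
  invisible(x)
}

#' @export
`[.gdgse_sets` <- function(x, i) {
  gene_sets(unclass(x)[i], descriptions = attr(x, "descriptions")[i])
}
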