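#' Read a clade-label table
#'
#' A clade table maps each sequence id to a taxonomic class label (for
#' aromatase: mammal, bird, reptile, amphibian, fish, invertebrate). The file
#' is two-column tab-separated text without a header: `id<TAB>label`.
#'
#' @param path file path.
#' @param labels optional declared label set; labels outside it are an error.
#' @return A data.frame with columns `id` and `clade`, class
#'   `conserv_clades`.
#' @export
read_clade_table <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t",
                   col.names = c("id", "clade"),
                   colClasses = "character", strip.white = TRUE)
  clade_table(df$id, df$clade, labels = labels)
}

#' Construct a clade table from vectors
#'
#' @param ids sequence identifiers.
#' @param clades clade label per id.
#' @param labels optional declared label set.
#' @export
clade_table <- function(ids, clades, labels = NULL) {
  if (length(ids) != length(clades)) stop("ids and clades differ in length")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    # duplicates carrying the same label collapse silently; conflicts are fatal
    for (d in dup) {
      if (length(unique(clades[ids == d])) > 1L)
        stop("id '", d, "' has conflicting clade labels")
    }
    keep <- !duplicated(ids)
    ids <- ids[keep]; clades <- clades[keep]
  }
  if (!is.null(labels)) {
    bad <- setdiff(unique(clades), labels)
    if (length(bad))
      stop("clade labels outside declared set: ", paste(bad, collapse = ", "))
  }
  structure(data.frame(id = ids, clade = clades,
                       stringsAsFactors = FALSE),
            class = c("conserv_clades", "data.frame"))
}

#' Cross-validate a clade table against an alignment
#'
#' Every alignment id must be present in the table (fatal if not); table ids
#' absent from the alignment are reported as a warning and dropped.
#'
#' @param clades a `conserv_clades` table.
#' @param aln a `conserv_alignment`.
#' @return The clade table restricted to alignment ids, in alignment order.
#' @export
validate_clades <- function(clades, aln) {
  missing_in_table <- setdiff(aln_ids(aln), clades$id)
  if (length(missing_in_table))
    stop("alignment ids missing from clade table: ",
         paste(missing_in_table, collapse = ", "))
  extra <- setdiff(clades$id, aln_ids(aln))
  if (length(extra))
    warning("clade table ids not in alignment (dropped): ",
            paste(extra, collapse = ", "))
  out <- clades[match(aln_ids(aln), clades$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("conserv_clades", "data.frame"))
}

#' Write a clade table as TSV
#' @param clades a `conserv_clades` table.
#' @param path output path.
#' @export
write_clade_table <- function(clades, path) {
  write.table(clades, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
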