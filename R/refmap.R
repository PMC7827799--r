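#' Map alignment columns to reference residue numbering
#'
#' All reporting uses the residue numbering of a designated reference
#' sequence (for aromatase, human CYP19A1 / UniProt P11511). The k-th
#' non-gap position of the reference row (1-based) is residue
#' `offset + k - 1`; columns where the reference is gapped have no residue
#' number. `X` in the reference row is a real (if unknown) residue and keeps
#' its number. The `offset` absorbs the difference between a construct
#' sequence (e.g. a crystal construct) and full-length numbering.
#'
#' @param aln a `conserv_alignment`.
#' @param ref_id id of the reference sequence (must be in the alignment).
#' @param offset residue number of the first reference residue (>= 1).
#' @return An object of class `refmap`: list with `ref_id`, `offset`,
#'   `col_to_res` (integer vector over columns, NA where unmapped) and
#'   `res_to_col` (named integer vector).
#' @examples
#' aln <- alignment(c("ref", "b"), c("MK-V", "MKAV"))
#' rm <- build_refmap(aln, "ref", offset = 1)
#' rm$col_to_res   # 1 2 NA 3
#' @export
build_refmap <- function(aln, ref_id, offset = 1) {
  if (!ref_id %in% aln$ids) stop("reference id '", ref_id, "' not in alignment")
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 1L) stop("offset must be >= 1")
  row <- aln$mat[ref_id, ]
  nongap <- which(row != "-")
  if (!length(nongap)) stop("reference row is entirely gaps")
  col_to_res <- rep(NA_integer_, aln$n_cols)
  col_to_res[nongap] <- offset + seq_along(nongap) - 1L
  res_to_col <- setNames(nongap, col_to_res[nongap])
  structure(list(ref_id = ref_id, offset = offset,
                 col_to_res = col_to_res, res_to_col = res_to_col),
            class = "refmap")
}

#' @export
print.refmap <- function(x, ...) {
  rng <- range(x$col_to_res, na.rm = TRUE)
  cat(sprintf("<refmap %s: residues %d-%d over %d columns>\n",
              x$ref_id, rng[1], rng[2], length(x$col_to_res)))
  invisible(x)
}

#' Residue number of an alignment column
#' @param rmap a [build_refmap()] object.
#' @param col column index (vectorized).
#' @return Integer residue numbers, NA where the reference is gapped.
#' @export
col2res <- function(rmap, col) rmap$col_to_res[col]

#' Alignment column of a reference residue
#' @param rmap a [build_refmap()] object.
#' @param res residue number (vectorized).
#' @return Integer column indices, NA for residues outside the map.
#' @export
res2col <- function(rmap, res) {
  unname(rmap$res_to_col[as.character(res)])
}
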