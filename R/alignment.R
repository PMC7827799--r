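#' @importFrom stats cor pgamma qgamma rexp rgamma setNames
#' @importFrom utils read.delim write.table getFromNamespace packageVersion
NULL

#' One-letter codes of the 20 standard amino acids
#'
#' Fixed residue ordering (A R N D C Q E G H I L K M F P S T W Y V) used for
#' all rate matrices, stationary frequency vectors and state encodings in the
#' package. This is the conventional ordering of empirical amino-acid
#' replacement matrices.
#'
#' @export
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# characters accepted in an alignment: residues, unknown, gap
.ALN_ALPHABET <- c(AA_CODES, "X", "-")

#' Construct a protein multiple sequence alignment
#'
#' An alignment is an ordered set of equal-length gapped amino-acid sequences
#' with unique identifiers. Gap characters `.` are normalized to `-`;
#' lowercase letters are uppercased. `X` marks an unknown residue and is
#' treated as missing data by the likelihood machinery, but preserved on
#' output.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of gapped sequences, same length as `ids`.
#' @return An object of class `conserv_alignment`: a list with elements
#'   `ids`, `mat` (character matrix, one row per sequence, rownames = ids)
#'   and `n_cols`.
#' @examples
#' aln <- alignment(c("a", "b"), c("MK-V", "MKAV"))
#' n_cols(aln)
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (length(ids) == 0L)
    stop("alignment must contain at least one sequence")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ")")
  if (lens[1] == 0L)
    stop("alignment has zero columns")
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(ids), byrow = TRUE,
                dimnames = list(ids, NULL))
  bad <- which(!(mat %in% .ALN_ALPHABET))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(mat)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(mat)) + 1L
    stop(sprintf("invalid character '%s' in sequence '%s' at column %d",
                 mat[bad[1]], ids[i], j))
  }
  structure(list(ids = ids, mat = mat, n_cols = ncol(mat)),
            class = "conserv_alignment")
}

#' @export
print.conserv_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d sequences x %d columns>\n",
              length(x$ids), x$n_cols))
  invisible(x)
}

#' Number of alignment columns
#' @param aln a `conserv_alignment`.
#' @export
n_cols <- function(aln) aln$n_cols

#' Sequence identifiers of an alignment
#' @param aln a `conserv_alignment`.
#' @export
aln_ids <- function(aln) aln$ids

#' @export
as.matrix.conserv_alignment <- function(x, ...) x$mat

#' Gapped sequence string for one id
#' @param aln a `conserv_alignment`.
#' @param id sequence identifier.
#' @export
aln_seq <- function(aln, id) {
  if (!id %in% aln$ids) stop("id '", id, "' not in alignment")
  paste(aln$mat[id, ], collapse = "")
}

#' Subset an alignment by sequence id, preserving order
#' @param aln a `conserv_alignment`.
#' @param ids identifiers to keep (alignment order is preserved).
#' @export
aln_subset <- function(aln, ids) {
  miss <- setdiff(ids, aln$ids)
  if (length(miss)) stop("ids not in alignment: ", paste(miss, collapse = ", "))
  keep <- aln$ids[aln$ids %in% ids]
  alignment(keep, apply(aln$mat[keep, , drop = FALSE], 1, paste, collapse = ""))
}

# integer state codes: 1..20 residues, NA for gap or X (missing data)
.aln_codes <- function(aln) {
  codes <- match(aln$mat, AA_CODES)
  matrix(codes, nrow = nrow(aln$mat), dimnames = dimnames(aln$mat))
}

#' Read a protein multiple sequence alignment
#'
#' FASTA files are parsed with Biostrings; Stockholm (single-block or
#' interleaved, as written by HMMER) is parsed directly. In both cases the
#' records are validated into a [alignment()] object: equal lengths, unique
#' ids, alphabet restricted to the 20 amino acids, `X` and gaps.
#'
#' @param path file path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return A `conserv_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no FASTA records in ", path)
    ids <- sub("\\s.*$", "", names(set))
    alignment(ids, as.character(set))
  } else {
    .read_stockholm(path)
  }
}

# Minimal Stockholm parser: sequence lines only, '#' annotations and '//'
# skipped, interleaved blocks concatenated per id.
.read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path)
  seqs <- list()
  order <- character()
  for (ln in lines[-1]) {
    if (grepl("^\\s*$", ln) || grepl("^#", ln) || grepl("^//", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln)
    id <- parts[1]
    if (is.null(seqs[[id]])) {
      seqs[[id]] <- parts[2]
      order <- c(order, id)
    } else {
      seqs[[id]] <- paste0(seqs[[id]], parts[2])
    }
  }
  if (!length(order)) stop("no sequences in Stockholm file: ", path)
  alignment(order, unlist(seqs[order], use.names = FALSE))
}

#' Write an alignment to FASTA or Stockholm
#'
#' @param aln a `conserv_alignment`.
#' @param path output file path.
#' @param format `"fasta"` or `"stockholm"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  if (format == "fasta") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(aln$ids))
      cat(">", aln$ids[i], "\n", seqs[i], "\n", file = con, sep = "")
  } else {
    w <- max(nchar(aln$ids))
    writeLines(c("# STOCKHOLM 1.0",
                 sprintf("%-*s %s", w, aln$ids, seqs),
                 "//"), path)
  }
  invisible(path)
}
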