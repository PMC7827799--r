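#' Define a named region in reference residue numbering
#'
#' A region (e.g. a substrate recognition site or a helix) is a set of
#' 1-based inclusive residue intervals in reference numbering.
#'
#' @param name region name.
#' @param intervals list of `c(start, end)` pairs or a 2-column matrix.
#' @return An object of class `conserv_region`.
#' @export
region <- function(name, intervals) {
  if (is.matrix(intervals))
    intervals <- lapply(seq_len(nrow(intervals)), function(i) intervals[i, ])
  intervals <- lapply(intervals, function(iv) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || anyNA(iv) || iv[1] > iv[2])
      stop("interval must be c(start, end) with start <= end")
    iv
  })
  resid <- unlist(lapply(intervals, function(iv) iv[1]:iv[2]))
  if (anyDuplicated(resid))
    stop("overlapping intervals in region '", name, "'")
  structure(list(name = name, intervals = intervals, residues = resid),
            class = "conserv_region")
}

#' Conserved structural elements of cytochrome P450 aromatase
#'
#' Bundled default regions in human CYP19A1 numbering: the conserved
#' structural elements (helix A, the beta-1/beta-2 sheet, helices E/F/I/K,
#' the K-beta3 loop, strand beta-6, helix L with part of the L-K'' loop).
#' Substrate-recognition-site (SRS) boundaries are deliberately not bundled:
#' they come from external P450 annotation and must be supplied by the user.
#'
#' @return Named list of [region()] objects.
#' @export
aromatase_elements <- function() {
  list(
    helix_A = region("helix_A", list(c(65, 78))),
    beta1_beta2 = region("beta1_beta2", list(c(83, 88), c(93, 97))),
    helix_E = region("helix_E", list(c(187, 205))),
    helix_F_start = region("helix_F_start", list(c(221, 224))),
    helix_I_core = region("helix_I_core", list(c(302, 318))),
    helix_K = region("helix_K", list(c(354, 366))),
    K_beta3 = region("K_beta3", list(c(368, 376))),
    beta6 = region("beta6", list(c(393, 396))),
    helix_L = region("helix_L", list(c(427, 448)))
  )
}

#' Read regions from a YAML file
#'
#' Schema: a mapping `name -> intervals`, each intervals entry a list of
#' `[start, end]` pairs, e.g. `SRS-4: [[302, 318]]`.
#'
#' @param path YAML file path.
#' @return Named list of [region()] objects.
#' @export
read_regions_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  out <- lapply(names(y), function(nm) {
    iv <- y[[nm]]
    if (is.list(iv) && length(iv) == 1L && !is.list(iv[[1]]) &&
        length(iv[[1]]) == 2L)
      iv <- list(iv[[1]])
    region(nm, iv)
  })
  names(out) <- names(y)
  out
}

# round half up to 1 decimal, matching reported-percentage style
.round1 <- function(x) floor(x * 10 + 0.5) / 10

#' Percentage of conserved residues in a region
#'
#' A residue counts as conserved when its conservation grade is at least
#' `conserved_grade` (default 8, i.e. the top two of nine grades — the
#' cut-off is a required, logged analysis choice). The denominator is the
#' number of region residues present in the reference mapping; residues the
#' alignment's reference row does not cover are excluded from the percentage
#' and listed in the `unmapped` attribute.
#'
#' @param scores a `site_scores` table with `ref_residue` and `grade`.
#' @param reg a [region()].
#' @param conserved_grade minimal grade counted as conserved (default 8).
#' @return Percentage (1 decimal, round half up) with attributes
#'   `n_mapped`, `n_conserved`, `unmapped`.
#' @export
region_conservation_percent <- function(scores, reg, conserved_grade = 8) {
  if (conserved_grade < 1 || conserved_grade > 9)
    stop("conserved_grade must be in 1..9")
  hit <- match(reg$residues, scores$ref_residue)
  mapped <- !is.na(hit)
  if (!any(mapped))
    stop("region '", reg$name, "' is entirely unmapped")
  grades <- scores$grade[hit[mapped]]
  n_cons <- sum(!is.na(grades) & grades >= conserved_grade)
  pct <- .round1(100 * n_cons / sum(mapped))
  structure(pct, n_mapped = sum(mapped), n_conserved = n_cons,
            unmapped = reg$residues[!mapped])
}

#' Region conservation summary table
#'
#' @param scores a `site_scores` table.
#' @param regions named list of [region()] objects.
#' @param conserved_grade see [region_conservation_percent()].
#' @return data.frame: `region`, `n_residues`, `n_mapped`, `n_conserved`,
#'   `percent_conserved`.
#' @export
region_summary <- function(scores, regions, conserved_grade = 8) {
  rows <- lapply(regions, function(rg) {
    p <- region_conservation_percent(scores, rg, conserved_grade)
    data.frame(region = rg$name, n_residues = length(rg$residues),
               n_mapped = attr(p, "n_mapped"),
               n_conserved = attr(p, "n_conserved"),
               percent_conserved = as.numeric(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise percent identity and similarity between two aligned sequences
#'
#' Both are computed over mutually non-gap, non-`X` columns: identity is the
#' fraction of identical residue pairs, similarity ("homology") the fraction
#' of pairs with a positive substitution-matrix score (BLOSUM62 by default).
#' Since the matrix diagonal is positive, identity never exceeds similarity.
#'
#' @param aln a `conserv_alignment`.
#' @param idA,idB sequence ids.
#' @param matrix a similarity matrix with residue dimnames; default
#'   BLOSUM62 from Biostrings.
#' @return Named numeric `c(identity =, similarity =)` in percent.
#' @export
pairwise_identity_similarity <- function(aln, idA, idB, matrix = NULL) {
  if (is.null(matrix)) matrix <- .blosum62()
  for (id in c(idA, idB))
    if (!id %in% aln$ids) stop("id '", id, "' not in alignment")
  a <- aln$mat[idA, ]; b <- aln$mat[idB, ]
  ok <- a %in% AA_CODES & b %in% AA_CODES
  if (!any(ok))
    stop("no mutually non-gap columns between '", idA, "' and '", idB, "'")
  a <- a[ok]; b <- b[ok]
  idy <- 100 * sum(a == b) / sum(ok)
  sim <- 100 * sum(matrix[cbind(a, b)] > 0) / sum(ok)
  c(identity = idy, similarity = sim)
}

.blosum62 <- function() {
  if (is.null(.model_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .model_cache$blosum62 <- e$BLOSUM62
  }
  .model_cache$blosum62
}

#' Filter sequences by percent identity to a reference
#'
#' Mirrors the dataset curation step of conservation studies: keep only the
#' sequences with at least `threshold` percent identity to the reference
#' (the reference itself is always retained). Order is preserved. With
#' threshold 0 this is the identity; raising the threshold never adds
#' sequences.
#'
#' @param aln a `conserv_alignment`.
#' @param ref_id reference sequence id.
#' @param threshold identity threshold in percent, within `[0, 100]`.
#' @return The filtered alignment, with attribute `removed` (dropped ids).
#' @export
filter_by_identity <- function(aln, ref_id, threshold = 40) {
  if (!ref_id %in% aln$ids) stop("reference id '", ref_id, "' not in alignment")
  if (threshold < 0 || threshold > 100)
    stop("threshold must be within [0, 100]")
  keep <- vapply(aln$ids, function(id) {
    if (id == ref_id) return(TRUE)
    pairwise_identity_similarity(aln, ref_id, id)[["identity"]] >= threshold
  }, logical(1))
  out <- aln_subset(aln, aln$ids[keep])
  attr(out, "removed") <- aln$ids[!keep]
  out
}

#' Per-residue conservation report with per-clade substitution notes
#'
#' For each requested reference residue: its conservation score and, for
#' each clade, every residue state differing from the global consensus with
#' its within-clade frequency (2 decimals). The consensus is the modal
#' residue over all sequences (gaps and `X` excluded), ties broken
#' alphabetically. A fully conserved column yields empty notes.
#'
#' @param aln a `conserv_alignment`.
#' @param clades a `conserv_clades` covering the alignment.
#' @param scores a `site_scores` with reference numbering.
#' @param residues integer vector of reference residue numbers.
#' @param locations optional named character vector (residue -> location
#'   label, e.g. "I-helix").
#' @return data.frame: `ref_residue`, `location`, `score`, `consensus`,
#'   `notes` (human-readable), plus list-column `notes_by_clade`. Residues
#'   absent from the mapping are returned in the `skipped` attribute.
#' @export
residue_report <- function(aln, clades, scores, residues, locations = NULL) {
  clades <- validate_clades(clades, aln)
  cols <- match(residues, scores$ref_residue)
  skipped <- residues[is.na(cols)]
  keep <- !is.na(cols)
  rows <- vector("list", sum(keep))
  ri <- 0L
  for (i in which(keep)) {
    col <- scores$column[cols[i]]
    states <- aln$mat[, col]
    obs <- states[states %in% AA_CODES]
    if (!length(obs)) next
    tab <- table(obs)
    consensus <- sort(names(tab)[tab == max(tab)])[1]
    notes <- list()
    for (cl in unique(clades$clade)) {
      st <- states[clades$id[clades$clade == cl]]
      st <- st[st %in% AA_CODES | st == "X"]
      nn <- st[st != consensus]
      if (length(nn)) {
        fr <- round(table(nn) / length(clades$id[clades$clade == cl]), 2)
        notes[[cl]] <- setNames(as.numeric(fr), names(fr))
      }
    }
    txt <- paste(unlist(lapply(names(notes), function(cl)
      paste0(cl, ": ", paste0(names(notes[[cl]]), "=",
                              sprintf("%.2f", notes[[cl]]), collapse = ",")))),
      collapse = "; ")
    ri <- ri + 1L
    rows[[ri]] <- data.frame(ref_residue = residues[i],
                             location = if (!is.null(locations))
                               locations[as.character(residues[i])] %||% ""
                             else "",
                             score = scores$score[cols[i]],
                             consensus = consensus,
                             notes = txt, stringsAsFactors = FALSE)
    rows[[ri]]$notes_by_clade <- list(notes)
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
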