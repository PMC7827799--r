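#' Paint conservation scores into a structure's B-factor column
#'
#' Writes the per-residue conservation score (rounded to the 2 decimals the
#' PDB format carries) or grade into the B-factor of every atom of the
#' mapped residues of one chain, for structure coloring. Structure residue
#' numbers must already be in reference numbering. Residues of the chain
#' without a score get a sentinel B-factor: `-1.00` in grade mode (grades
#' are 1..9, so -1 is unambiguous) and `-9.99` in score mode. `HETATM`
#' records (e.g. the heme) and other chains are untouched; coordinates and
#' atom identities are preserved, so painting is idempotent.
#'
#' @param model a `conserv_structure`.
#' @param scores a `site_scores` table with reference numbering.
#' @param chain chain identifier to paint.
#' @param mode `"score"` or `"grade"`.
#' @return The painted `conserv_structure`, with attribute `unmapped`
#'   (residue numbers of the chain that received the sentinel).
#' @export
paint_bfactor <- function(model, scores, chain = "A",
                          mode = c("score", "grade")) {
  mode <- match.arg(mode)
  if (!chain %in% model$chain)
    stop("chain '", chain, "' not present in structure")
  sel <- model$chain == chain & !model$het
  if (!any(sel)) stop("chain '", chain, "' has no ATOM records")
  ok <- !is.na(scores$ref_residue) & !is.na(scores$score)
  vals <- if (mode == "score") round(scores$score[ok], 2)
          else as.numeric(scores$grade[ok])
  lut <- setNames(vals, scores$ref_residue[ok])
  sentinel <- if (mode == "score") -9.99 else -1.00
  resn <- as.character(model$resno[sel])
  b <- unname(lut[resn])
  b[is.na(b)] <- sentinel
  unmapped <- sort(unique(model$resno[sel][is.na(lut[resn])]))
  if (length(unmapped) == length(unique(model$resno[sel])))
    stop("no residues of chain '", chain, "' are mapped by the score table")
  model$b[sel] <- b
  attr(model, "unmapped") <- unmapped
  model
}
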