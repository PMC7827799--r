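#' Read a PDB structure into a structure model
#'
#' Parsing is delegated to `bio3d::read.pdb`; only `ATOM`/`HETATM`/`TER`/`END`
#' records are interpreted. The result is a flat atom table carrying chain,
#' residue number/name, atom name, coordinates, occupancy, B-factor and a
#' `het` flag for `HETATM` records (e.g. the heme). Insertion codes are
#' rejected: the aromatase structures need none, and silent renumbering would
#' corrupt the reference mapping.
#'
#' @param path PDB file path.
#' @return A data.frame of class `conserv_structure` with columns `type`,
#'   `eleno`, `elety`, `resid`, `chain`, `resno`, `x`, `y`, `z`, `o`, `b`,
#'   `elesy`, `het`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    if (nchar(lines[i]) < 54)
      stop(sprintf("malformed PDB record at line %d: too short", i))
    icode <- substr(lines[i], 27, 27)
    if (icode != " ")
      stop(sprintf("insertion code '%s' at line %d not supported", icode, i))
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  df <- data.frame(type = a$type, eleno = a$eleno, elety = a$elety,
                   resid = a$resid, chain = a$chain, resno = a$resno,
                   x = a$x, y = a$y, z = a$z,
                   o = ifelse(is.na(a$o), 1, a$o),
                   b = ifelse(is.na(a$b), 0, a$b),
                   elesy = ifelse(is.na(a$elesy), "", a$elesy),
                   het = a$type == "HETATM",
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("non-finite atom coordinates")
  if (anyDuplicated(df[, c("chain", "resno", "elety", "het", "resid")]))
    stop("duplicate (chain, residue, atom) records")
  structure(df, class = c("conserv_structure", "data.frame"))
}

#' Write a structure model as a PDB file
#'
#' Emits fixed-width `ATOM`/`HETATM` records (B-factor in columns 61-66,
#' `%6.2f`) via `bio3d::write.pdb`, so a written model re-reads bit-exactly
#' at the 2-decimal precision of the format.
#'
#' @param model a `conserv_structure`.
#' @param path output path.
#' @export
write_structure <- function(model, path) {
  if (!inherits(model, "conserv_structure")) stop("not a conserv_structure")
  xyz <- as.vector(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, type = model$type, eleno = model$eleno,
                   elety = model$elety, resid = model$resid,
                   chain = ifelse(is.na(model$chain), "", model$chain),
                   resno = model$resno, xyz = xyz,
                   o = model$o, b = model$b, elesy = model$elesy)
  invisible(path)
}
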