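#' Compile a degenerate consensus pattern
#'
#' Grammar (PROSITE-flavored): tokens separated by `-`; a token is a single
#' residue letter, a residue set `[RK]`, or the wildcard `x` (any of the 20
#' amino acids); an optional repeat suffix `(m)` or `(m,n)` with
#' `1 <= m <= n <= 10`. Examples: the PKA consensus `R-x(1,2)-[ST]-x`, the
#' PKG consensus `[RK](2,3)-x-[ST]-x`, the P450 heme-pocket consensus
#' `F-G-F-G-P-R-[GASTN]-C-[AVLI]-G-[KR]`, the EXXR salt-bridge motif
#' `E-x-x-R`.
#'
#' @param text pattern text.
#' @param name optional motif name (defaults to the text).
#' @return An object of class `motif_pattern`: list with `name`, `tokens`
#'   (each a list `set`, `min`, `max`). `format()` returns the canonical
#'   text, and `compile_pattern(format(p))` reproduces `p`.
#' @export
compile_pattern <- function(text, name = text) {
  toks <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (!length(toks) || any(toks == ""))
    stop("empty token in pattern '", text, "'")
  tokens <- lapply(seq_along(toks), function(i) {
    tk <- toks[i]
    m <- regmatches(tk, regexec(
      "^(?:([A-WYZ])|\\[([A-Z]+)\\]|(x))(?:\\((\\d+)(?:,(\\d+))?\\))?$", tk))[[1]]
    if (!length(m))
      stop("cannot parse token ", i, " ('", tk, "') of pattern '", text, "'")
    set <- if (m[4] == "x" || m[2] == "x") {
      AA_CODES
    } else if (m[3] != "") {
      s <- strsplit(m[3], "")[[1]]
      bad <- setdiff(s, AA_CODES)
      if (length(bad))
        stop("non-residue character(s) ", paste(bad, collapse = ""),
             " in token ", i, " of pattern '", text, "'")
      unique(s)
    } else if (m[2] != "") {
      if (!m[2] %in% AA_CODES)
        stop("non-residue character '", m[2], "' in token ", i,
             " of pattern '", text, "'")
      m[2]
    } else AA_CODES  # the bare wildcard branch (m[4])
    lo <- if (m[5] == "") 1L else as.integer(m[5])
    hi <- if (m[6] == "") lo else as.integer(m[6])
    if (is.na(lo) || is.na(hi) || lo < 1L || hi > 10L || lo > hi)
      stop("bad repeat bounds (", m[5], ",", m[6], ") in token ", i,
           " of pattern '", text, "': need 1 <= min <= max <= 10")
    list(set = sort(set), min = lo, max = hi)
  })
  structure(list(name = name, tokens = tokens), class = "motif_pattern")
}

#' @export
format.motif_pattern <- function(x, ...) {
  paste(vapply(x$tokens, function(tk) {
    base <- if (length(tk$set) == 20L) "x"
            else if (length(tk$set) == 1L) tk$set
            else paste0("[", paste(tk$set, collapse = ""), "]")
    if (tk$min == 1L && tk$max == 1L) base
    else if (tk$min == tk$max) sprintf("%s(%d)", base, tk$min)
    else sprintf("%s(%d,%d)", base, tk$min, tk$max)
  }, character(1)), collapse = "-")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif %s: %s>\n", x$name, format(x)))
  invisible(x)
}

#' Bundled consensus motifs of the aromatase analysis
#'
#' PKA and PKG kinase recognition consensi, the heme-ligating cysteine
#' pocket consensus (with its two degenerate positions), and the EXXR
#' salt-bridge motif of helix K.
#'
#' @return Named list of [compile_pattern()] objects with `window`
#'   attributes (reference residue intervals) where the analysis anchors
#'   them.
#' @export
default_motifs <- function() {
  w <- function(p, win) { attr(p, "window") <- win; p }
  list(
    PKA = w(compile_pattern("R-x(1,2)-[ST]-x", name = "PKA"), c(262, 268)),
    PKG = w(compile_pattern("[RK](2,3)-x-[ST]-x", name = "PKG"), c(262, 268)),
    PKA_S118 = w(compile_pattern("R-x(1,2)-[ST]-x", name = "PKA_S118"),
                 c(115, 119)),
    heme_pocket = w(compile_pattern("F-G-F-G-P-R-[AGNST]-C-[AILV]-G-[KR]",
                                    name = "heme_pocket"), c(430, 440)),
    EXXR = w(compile_pattern("E-x-x-R", name = "EXXR"), c(357, 362))
  )
}

# all hit end positions for pattern tokens starting at position pos
.match_from <- function(chars, tokens, pos, tok_i) {
  if (tok_i > length(tokens)) return(pos - 1L)
  tk <- tokens[[tok_i]]
  n <- length(chars)
  ends <- integer(0)
  reach <- 0L
  while (reach < tk$max) {
    p <- pos + reach
    if (p > n || !(chars[p] %in% tk$set)) break  # X matches nothing
    reach <- reach + 1L
    if (reach >= tk$min)
      ends <- c(ends, .match_from(chars, tokens, pos + reach, tok_i + 1L))
  }
  ends
}

#' Scan an ungapped sequence for all matches of a pattern
#'
#' Every match over every repeat expansion is reported; overlapping and
#' nested matches are allowed. Coordinates are 1-based inclusive positions
#' in the ungapped sequence. `X` in the sequence matches no token (unknown
#' is not a wildcard), which keeps presence calls conservative.
#'
#' @param pattern a [compile_pattern()] object.
#' @param sequence ungapped amino-acid string (may contain `X`).
#' @return data.frame sorted by (start, end): `start`, `end`, `match`.
#' @examples
#' scan_sequence(compile_pattern("R-x(1,2)-[ST]-x"), "KRRRIST")
#' @export
scan_sequence <- function(pattern, sequence) {
  sequence <- toupper(sequence)
  if (grepl("-", sequence, fixed = TRUE))
    stop("sequence must be ungapped (strip gaps first)")
  chars <- strsplit(sequence, "")[[1]]
  hits <- list()
  for (s in seq_along(chars)) {
    ends <- unique(.match_from(chars, pattern$tokens, s, 1L))
    for (e in ends)
      hits[[length(hits) + 1L]] <- c(s, e)
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0)))
  hm <- unique(do.call(rbind, hits))
  hm <- hm[order(hm[, 1], hm[, 2]), , drop = FALSE]
  data.frame(start = hm[, 1], end = hm[, 2],
             match = substring(sequence, hm[, 1], hm[, 2]),
             stringsAsFactors = FALSE)
}

#' Per-clade presence of a motif in a reference-anchored window
#'
#' For each sequence, the reference window `[window[1], window[2]]` is
#' translated into that sequence's own ungapped coordinates through the
#' alignment columns the reference window spans; the sequence counts as
#' positive when at least one motif hit lies entirely inside that image.
#' The per-clade fraction of positive sequences is reported with clade
#' sizes. Adding all-gap columns to the alignment cannot change the result,
#' since both the window image and the scan operate on ungapped coordinates.
#'
#' @param aln a `conserv_alignment`.
#' @param clades a `conserv_clades` covering the alignment.
#' @param rmap a [build_refmap()] for the alignment.
#' @param pattern a [compile_pattern()] object.
#' @param window length-2 reference residue interval; both endpoints must
#'   be mapped.
#' @return data.frame: `motif`, `clade`, `n`, `fraction` (in `[0, 1]`).
#' @export
anchored_clade_presence <- function(aln, clades, rmap, pattern, window) {
  clades <- validate_clades(clades, aln)
  c1 <- res2col(rmap, window[1]); c2 <- res2col(rmap, window[2])
  if (is.na(c1) || is.na(c2))
    stop("window [", window[1], ", ", window[2],
         "] is not mapped by the reference row")
  cols <- c1:c2
  present <- vapply(aln$ids, function(id) {
    row <- aln$mat[id, ]
    nongap <- row != "-"
    if (!any(nongap[cols])) return(FALSE)
    upos <- cumsum(nongap)           # ungapped index of each non-gap column
    win_u <- range(upos[cols][nongap[cols]])
    hits <- scan_sequence(pattern, paste(row[nongap], collapse = ""))
    any(hits$start >= win_u[1] & hits$end <= win_u[2])
  }, logical(1))
  labs <- unique(clades$clade)
  rows <- lapply(labs, function(cl) {
    ids <- clades$id[clades$clade == cl]
    if (!length(ids)) {
      warning("empty clade '", cl, "' omitted")
      return(NULL)
    }
    data.frame(motif = pattern$name, clade = cl, n = length(ids),
               fraction = mean(present[ids]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
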