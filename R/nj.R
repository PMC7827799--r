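#' Pairwise Kimura-corrected protein distances
#'
#' For each pair, the mismatch fraction `p` over mutually non-gap, non-`X`
#' columns is corrected as `d = -ln(1 - p - p^2/5)`. Pairs with `p >= 0.85`,
#' where the correction is undefined, are capped at `d = 5.2` with a warning.
#'
#' @param aln a `conserv_alignment`.
#' @return A symmetric distance matrix with sequence ids as dimnames.
#' @export
kimura_distances <- function(aln) {
  codes <- .aln_codes(aln)
  n <- nrow(codes)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  capped <- character()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(codes[i, ]) & !is.na(codes[j, ])
      m <- sum(ok)
      if (m == 0L)
        stop("no mutually non-gap columns between '", aln$ids[i],
             "' and '", aln$ids[j], "'")
      p <- sum(codes[i, ok] != codes[j, ok]) / m
      if (p >= 0.85) {
        d[i, j] <- d[j, i] <- 5.2
        capped <- c(capped, paste0(aln$ids[i], "/", aln$ids[j]))
      } else {
        d[i, j] <- d[j, i] <- -log(1 - p - p * p / 5)
      }
    }
  }
  if (length(capped))
    warning("distance correction undefined (p >= 0.85), capped at 5.2 for: ",
            paste(capped, collapse = ", "))
  d
}

#' Neighbor-joining guide tree from an alignment
#'
#' Builds the guide tree for conservation scoring: Kimura-corrected pairwise
#' distances ([kimura_distances()]) followed by neighbor joining
#' (`ape::nj`), with negative NJ branch lengths clamped to zero. On additive
#' distances NJ recovers the generating topology and branch lengths exactly.
#'
#' @param aln a `conserv_alignment` with at least 2 sequences.
#' @return An unrooted `phylo`; for exactly two sequences, a two-leaf tree
#'   whose leaf-to-leaf path length equals their distance.
#' @export
build_nj_tree <- function(aln) {
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences")
  d <- kimura_distances(aln)
  if (n == 2L) {
    tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                         edge.length = rep(d[1, 2] / 2, 2),
                         tip.label = aln$ids, Nnode = 1L),
                    class = "phylo", order = "cladewise")
    return(tr)
  }
  nj_tree(d)
}

#' Neighbor joining on a distance matrix
#'
#' Thin wrapper over `ape::nj` that clamps the (rare) negative branch
#' lengths NJ can produce to zero. On an additive matrix the generating
#' topology and branch lengths are recovered exactly, so leaf-to-leaf path
#' lengths reproduce the input distances.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3L) stop("need at least 3 taxa; see build_nj_tree for 2")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
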