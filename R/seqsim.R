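# Synthetic-data generator: clade-labelled alignments evolved on a simulated
# tree with known per-site rates and planted motifs, giving every downstream
# stage a ground truth. All outputs are pure functions of (arguments, seed).

#' Simulate a birth-process tree topology with exponential branch lengths
#'
#' Topology grows by pure-birth (Yule) leaf splitting: starting from a
#' two-leaf cherry, a uniformly chosen extant leaf is repeatedly split until
#' `n_taxa` leaves exist, giving a rooted binary tree with `n_taxa - 1`
#' internal splits. Every edge then receives an independent
#' exponential(mean = `mean_branch_length`) length. Leaves are labelled
#' `t001, t002, ...` in tree traversal order.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed fixing all randomness.
#' @param mean_branch_length mean edge length in substitutions/site
#'   (default 0.1).
#' @return A rooted binary `phylo`.
#' @export
simulate_tree <- function(n_taxa, seed, mean_branch_length = 0.1) {
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 2L) stop("n_taxa must be >= 2")
  withr::with_seed(seed, {
    nwk <- "(<1>,<2>)"
    nl <- 2L
    while (nl < n_taxa) {
      k <- sample.int(nl, 1L)
      nl <- nl + 1L
      nwk <- sub(sprintf("<%d>", k),
                 sprintf("(<%d>,<%d>)", k, nl), nwk, fixed = TRUE)
    }
    tr <- ape::read.tree(text = paste0(gsub("[<>]", "x", nwk), ";"))
    tr$edge.length <- rexp(nrow(tr$edge), rate = 1 / mean_branch_length)
    tr <- stats::reorder(tr, "cladewise")
    # relabel in traversal order so clade plans cut contiguous blocks
    tips <- tr$edge[tr$edge[, 2] <= n_taxa, 2]
    tr$tip.label[tips] <- sprintf("t%03d", seq_len(n_taxa))
    tr
  })
}

#' Per-site rates from homogeneous blocks
#'
#' Convenience constructor for designed rate truth: `blocks` is a list of
#' `c(n_sites, rate)` pairs concatenated in order.
#'
#' @param blocks list of length-2 numeric vectors (n_sites, rate > 0).
#' @return Numeric vector of per-site true rates.
#' @export
rates_from_blocks <- function(blocks) {
  out <- unlist(lapply(blocks, function(b) {
    if (length(b) != 2L || b[1] < 1 || b[2] <= 0)
      stop("each block must be c(n_sites >= 1, rate > 0)")
    rep(b[2], b[1])
  }))
  if (!length(out)) stop("empty site specification")
  out
}

#' Evolve a gap-free alignment along a tree at known site rates
#'
#' The root sequence is drawn from the model's stationary frequencies; each
#' site `i` then evolves independently down the tree with transition
#' matrices `P(t * r_i)`. No indels are simulated, so alignment column `i`
#' is site `i` and the returned truth table is unambiguous.
#'
#' @param tree a `phylo` with branch lengths.
#' @param site_rates numeric vector of true relative rates, one per site
#'   (all > 0); see [rates_from_blocks()] or draw from
#'   `rgamma(n, alpha, alpha)` for gamma truth.
#' @param seed integer seed.
#' @param model a [subst_model()], default [jtt_model()].
#' @return A list with `alignment` (a `conserv_alignment`, rows in tree tip
#'   order) and `truth` (data.frame `site`, `true_rate`).
#' @export
simulate_alignment <- function(tree, site_rates, seed, model = jtt_model()) {
  site_rates <- as.numeric(site_rates)
  if (any(!is.finite(site_rates) | site_rates <= 0))
    stop("all site rates must be positive")
  S <- length(site_rates)
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  withr::with_seed(seed, {
    states <- matrix(NA_integer_, ntip + tree$Nnode, S)
    root <- ntip + 1L
    states[root, ] <- sample.int(20L, S, replace = TRUE, prob = model$pi)
    rate_groups <- split(seq_len(S), site_rates)
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      t <- tree$edge.length[e]
      for (g in rate_groups) {
        P <- .prob_matrix(model, t * site_rates[g[1]])
        pa <- states[p, g]
        for (a in unique(pa)) {
          idx <- g[pa == a]
          states[ch, idx] <- sample.int(20L, length(idx), replace = TRUE,
                                        prob = P[a, ])
        }
      }
    }
    seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1,
                  function(row) paste(AA_CODES[row], collapse = ""))
    list(alignment = alignment(tree$tip.label, seqs),
         truth = data.frame(site = seq_len(S), true_rate = site_rates))
  })
}

#' Partition taxa into labelled clades by tree traversal order
#'
#' Leaves are taken in cladewise traversal order and cut into consecutive
#' blocks of the requested sizes, so each clade is a union of adjacent
#' subtrees — mimicking a taxonomy laid over the tree.
#'
#' @param tree a `phylo`.
#' @param sizes named integer vector (label -> count) summing to the number
#'   of leaves.
#' @return A `conserv_clades` table.
#' @export
clade_plan <- function(tree, sizes) {
  ntip <- length(tree$tip.label)
  if (sum(sizes) != ntip)
    stop("clade sizes must sum to the number of leaves (", ntip, ")")
  if (is.null(names(sizes)) || any(names(sizes) == ""))
    stop("sizes must be a named vector")
  tree <- stats::reorder(tree, "cladewise")
  tips <- tree$tip.label[tree$edge[tree$edge[, 2] <= ntip, 2]]
  clade_table(tips, rep(names(sizes), times = sizes))
}

#' Overwrite a motif into the sequences of selected clades
#'
#' Planting happens after evolution, so planted windows are exact: the truth
#' about where a motif lies is not entangled with substitution noise. Only
#' sequences of the listed clades are touched. Overlapping plants applied in
#' sequence follow last-writer-wins.
#'
#' @param aln a gap-free `conserv_alignment` (columns = sites).
#' @param clades a `conserv_clades` table covering the alignment.
#' @param clade_set character vector of clade labels to modify (empty set =
#'   no-op).
#' @param positions integer site positions, length = `nchar(residues)`.
#' @param residues amino-acid string written at `positions`.
#' @return The modified alignment.
#' @export
plant_motif <- function(aln, clades, clade_set, positions, residues) {
  res <- strsplit(toupper(residues), "")[[1]]
  if (length(positions) != length(res))
    stop("positions and residues must have equal length")
  if (any(positions < 1 | positions > aln$n_cols))
    stop("plant position out of range 1..", aln$n_cols)
  if (!all(res %in% AA_CODES)) stop("residues must be standard amino acids")
  if (!length(clade_set)) return(aln)
  ids <- clades$id[clades$clade %in% clade_set]
  ids <- intersect(aln$ids, ids)
  mat <- aln$mat
  for (id in ids) mat[id, positions] <- res
  alignment(aln$ids, apply(mat, 1, paste, collapse = ""))
}

#' Simulate a full clade-labelled conservation study
#'
#' One-call generator for the package's standard synthetic study: a
#' birth-process tree, clade labels in the proportions of the aromatase
#' dataset (mammal : bird : reptile : amphibian : fish : invertebrate
#' roughly 66 : 8 : 12 : 18 : 259 : 2, rescaled), sites evolved at designed
#' or gamma-distributed true rates, and optional planted motifs.
#'
#' @param seed integer master seed.
#' @param n_taxa number of sequences (default 60).
#' @param n_sites number of sites (default 300); ignored when `site_rates`
#'   is given.
#' @param site_rates explicit per-site rates; default: 10% of sites at rate
#'   0.1 (designed conserved) and the rest at 1.5.
#' @param gamma_alpha if non-NULL, draw per-site rates from
#'   gamma(`gamma_alpha`, `gamma_alpha`) instead.
#' @param clade_sizes named vector of clade sizes; default scales the
#'   aromatase clade counts to `n_taxa`.
#' @param plants optional list of plants, each a list with `clades`,
#'   `positions`, `residues`, applied in order via [plant_motif()].
#' @param model a [subst_model()].
#' @return List with `alignment`, `tree`, `clades`, `truth`, `plants`.
#' @export
simulate_study <- function(seed, n_taxa = 60, n_sites = 300,
                           site_rates = NULL, gamma_alpha = NULL,
                           clade_sizes = NULL, plants = NULL,
                           model = jtt_model()) {
  tree <- simulate_tree(n_taxa, seed = seed)
  if (is.null(site_rates)) {
    if (!is.null(gamma_alpha)) {
      site_rates <- withr::with_seed(seed + 1L,
        rgamma(n_sites, shape = gamma_alpha, rate = gamma_alpha))
      site_rates <- pmax(site_rates, 1e-4)
    } else {
      n_cons <- round(0.1 * n_sites)
      site_rates <- c(rep(0.1, n_cons), rep(1.5, n_sites - n_cons))
    }
  }
  sim <- simulate_alignment(tree, site_rates, seed = seed + 2L, model = model)
  if (is.null(clade_sizes)) clade_sizes <- .default_clade_sizes(n_taxa)
  clades <- clade_plan(tree, clade_sizes)
  aln <- sim$alignment
  if (!is.null(plants)) {
    for (p in plants)
      aln <- plant_motif(aln, clades, p$clades, p$positions, p$residues)
  }
  list(alignment = aln, tree = tree, clades = clades, truth = sim$truth,
       plants = plants)
}

# aromatase study proportions (66/8/12/18/259/2 of 365) rescaled to n leaves
.default_clade_sizes <- function(n_taxa) {
  ref <- c(mammal = 66, bird = 8, reptile = 12, amphibian = 18,
           fish = 259, invertebrate = 2)
  raw <- ref / sum(ref) * n_taxa
  sz <- pmax(floor(raw), 1L)
  # distribute the remainder to the largest fractional parts
  while (sum(sz) < n_taxa) {
    i <- which.max(raw - sz)
    sz[i] <- sz[i] + 1L
  }
  while (sum(sz) > n_taxa) {
    ok <- sz > 1L
    i <- which(ok)[which.min((raw - sz)[ok])]
    sz[i] <- sz[i] - 1L
  }
  sz
}
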