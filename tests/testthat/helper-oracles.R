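# Independent oracles used to check the implementation by a different route.

# Column likelihood by exhaustive enumeration of all internal-state
# assignments (feasible for <= 4 leaves). Transition matrices come from
# Matrix::expm, independent of the package's eigendecomposition path.
oracle_site_loglik <- function(column, tree, model, rate) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  leafstates <- lapply(tree$tip.label, function(id) {
    a <- match(toupper(column[[id]]), AA_CODES)
    if (is.na(a)) 1:20 else a
  })
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(model$Q * tree$edge.length[e] * rate)))
  grid <- as.matrix(expand.grid(rep(list(1:20), nn)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    pr <- model$pi[[st[1]]]                      # root is node ntip + 1
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      ps <- st[p - ntip]
      pr <- pr * if (ch <= ntip) sum(P[[e]][ps, leafstates[[ch]]])
                 else P[[e]][ps, st[ch - ntip]]
      if (pr == 0) break
    }
    tot <- tot + pr
  }
  log(tot)
}

# random leaf column (with optional gaps) for a tree
random_column <- function(tree, p_gap = 0.15) {
  states <- c(AA_CODES, "-")
  pr <- c(rep((1 - p_gap) / 20, 20), p_gap)
  setNames(sample(states, length(tree$tip.label), TRUE, prob = pr),
           tree$tip.label)
}

# Brute-force motif scanner: enumerate every repeat expansion of the
# pattern, slide each concrete token sequence over every start position.
oracle_scan <- function(pattern, sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  combos <- expand.grid(lapply(pattern$tokens, function(t) t$min:t$max))
  hits <- matrix(integer(0), 0, 2)
  for (ci in seq_len(nrow(combos))) {
    concrete <- list()
    for (j in seq_along(pattern$tokens))
      concrete <- c(concrete,
                    rep(list(pattern$tokens[[j]]$set), combos[ci, j]))
    L <- length(concrete)
    if (L > length(chars)) next
    for (s in seq_len(length(chars) - L + 1)) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!(chars[s + j - 1] %in% concrete[[j]])) { ok <- FALSE; break }
      }
      if (ok) hits <- rbind(hits, c(s, s + L - 1L))
    }
  }
  hits <- unique(hits)
  hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
}

# Mann-Whitney AUC: probability that a 'positive' carries a lower score
# than a 'negative' (ties count half).
auc_lower <- function(pos, neg) {
  mean(outer(neg, pos, ">") + 0.5 * outer(neg, pos, "=="))
}

# random gapped amino-acid string
random_seq <- function(n, alphabet = AA_CODES) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}
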