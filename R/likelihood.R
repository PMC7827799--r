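# Felsenstein pruning engine.
#
# Partial likelihoods are propagated tip-to-root in postorder over all sites
# at once (20 x n_sites matrices per node), with per-node rescaling by column
# sums so deep trees do not underflow. Gaps and X are missing data: their
# partial vector is all ones, so a fully missing column has likelihood 1
# under every rate.

# leaf partial matrices (independent of rate), in tree tip order
.leaf_partials <- function(codes, tree) {
  S <- ncol(codes)
  lapply(tree$tip.label, function(id) {
    if (!id %in% rownames(codes))
      stop("tree leaf '", id, "' not found in alignment")
    m <- matrix(0, 20, S)
    obs <- codes[id, ]
    seen <- which(!is.na(obs))
    m[cbind(obs[seen], seen)] <- 1
    if (length(seen) < S) m[, setdiff(seq_len(S), seen)] <- 1
    m
  })
}

# log-likelihood of every site at every rate: n_sites x length(rates) matrix
.pruning_loglik <- function(codes, tree, model, rates) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- ncol(codes)
  edge <- tree$edge
  elen <- tree$edge.length
  leafp <- .leaf_partials(codes, tree)
  root <- ntip + 1L
  out <- matrix(NA_real_, S, length(rates))
  for (k in seq_along(rates)) {
    r <- rates[k]
    if (!is.finite(r) || r <= 0) stop("rates must be positive")
    part <- vector("list", ntip + nnode)
    lsc <- vector("list", ntip + nnode)
    for (nd in (ntip + 1L):(ntip + nnode)) {
      part[[nd]] <- matrix(1, 20, S)
      lsc[[nd]] <- numeric(S)
    }
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1L]; ch <- edge[e, 2L]
      P <- .prob_matrix(model, elen[e] * r)
      cp <- if (ch <= ntip) leafp[[ch]] else part[[ch]]
      part[[p]] <- part[[p]] * (P %*% cp)
      if (ch > ntip) lsc[[p]] <- lsc[[p]] + lsc[[ch]]
      sc <- .colSums(part[[p]], 20L, S)
      part[[p]] <- part[[p]] / rep(sc, each = 20L)
      lsc[[p]] <- lsc[[p]] + log(sc)
    }
    out[, k] <- log(as.vector(model$pi %*% part[[root]])) + lsc[[root]]
  }
  if (any(!is.finite(out))) stop("non-finite site log-likelihood")
  out
}

#' Log-likelihood of one alignment column on a tree
#'
#' Felsenstein pruning with transition matrices `P(t * r) = expm(Q t r)`.
#' Gap and `X` states contribute all-ones partial vectors (missing data).
#' Per-node rescaling keeps the computation finite on large trees.
#'
#' @param column named character vector of residues, names = tree leaf
#'   labels; or a `conserv_alignment` together with `site`.
#' @param tree a `phylo` with branch lengths in substitutions/site.
#' @param model a [subst_model()].
#' @param rate relative rate multiplier (> 0).
#' @param site column index when `column` is an alignment.
#' @return The log-probability of the column (finite scalar).
#' @examples
#' m <- jtt_model()
#' tr <- read_tree(text = "(a:0.1,b:0.2);")
#' site_log_likelihood(c(a = "M", b = "M"), tr, m, rate = 1)
#' @export
site_log_likelihood <- function(column, tree, model, rate, site = NULL) {
  if (inherits(column, "conserv_alignment")) {
    if (is.null(site)) stop("give 'site' when passing an alignment")
    codes <- .aln_codes(column)[, site, drop = FALSE]
  } else {
    if (is.null(names(column))) stop("column must be named by leaf id")
    codes <- matrix(match(toupper(column), AA_CODES), ncol = 1,
                    dimnames = list(names(column), NULL))
  }
  if (!setequal(rownames(codes), tree$tip.label))
    stop("column names do not match tree leaves")
  .pruning_loglik(codes, tree, model, rate)[1, 1]
}

# golden-section maximization of f on [lo, hi]
.golden_max <- function(f, lo, hi, tol = 1e-3) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  xm <- (a + b) / 2
  list(x = xm, value = f(xm))
}

#' Maximum-likelihood gamma shape for among-site rate variation
#'
#' Maximizes the discrete-gamma mixture log-likelihood
#' `sum_i log( (1/K) sum_k L_i(r_k) )` over the shape `alpha` by
#' golden-section search on `log(alpha)` in `[log 0.05, log 10]`
#' (tolerance 1e-3). An estimate pinned at a search bound — e.g. for an
#' alignment with no observed variation — is flagged.
#'
#' @param aln a `conserv_alignment`.
#' @param tree a `phylo` covering the alignment ids.
#' @param model a [subst_model()].
#' @param K number of gamma categories.
#' @return The shape estimate, with attributes `loglik` and `at_bound`.
#' @export
estimate_alpha <- function(aln, tree, model = jtt_model(), K = 16) {
  codes <- .aln_codes(aln)
  lo <- log(0.05); hi <- log(10)
  obj <- function(la) {
    pr <- discretize_gamma(exp(la), K)
    ll <- .pruning_loglik(codes, tree, model, pr$rates)
    sum(.row_logmeanexp(ll))
  }
  opt <- .golden_max(obj, lo, hi, tol = 1e-3)
  alpha <- exp(opt$x)
  at_bound <- (opt$x - lo < 2e-3) || (hi - opt$x < 2e-3)
  if (at_bound)
    warning("alpha estimate at search bound (", signif(alpha, 3),
            "); data may be degenerate")
  structure(alpha, loglik = opt$value, at_bound = at_bound)
}

# row-wise log(mean(exp(x))) with max-shift stabilization
.row_logmeanexp <- function(x) {
  m <- apply(x, 1, max)
  m + log(rowMeans(exp(x - m)))
}

#' Empirical-Bayes posterior mean site rates
#'
#' For each column `i`, the posterior mean relative rate under the discrete
#' gamma prior is `r_hat_i = sum_k r_k w_k L_i(r_k) / sum_k w_k L_i(r_k)`
#' with equal prior weights `w_k = 1/K`. Columns with no observed residue
#' (all gap/X) carry no information: they are assigned the prior mean rate 1
#' and flagged.
#'
#' @param aln a `conserv_alignment`.
#' @param tree a `phylo` covering the alignment ids.
#' @param model a [subst_model()].
#' @param prior a [discretize_gamma()] prior.
#' @return Numeric vector of positive posterior mean rates, one per column,
#'   with attribute `all_gap` (logical vector flagging uninformative
#'   columns).
#' @export
posterior_mean_rates <- function(aln, tree, model, prior) {
  codes <- .aln_codes(aln)
  all_gap <- apply(codes, 2, function(col) all(is.na(col)))
  ll <- .pruning_loglik(codes, tree, model, prior$rates)
  m <- apply(ll, 1, max)
  w <- exp(ll - m)                      # proportional to posterior weights
  rhat <- as.vector(w %*% prior$rates) / rowSums(w)
  rhat[all_gap] <- 1
  if (any(rhat <= 0)) stop("non-positive posterior rate")
  structure(rhat, all_gap = all_gap)
}
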