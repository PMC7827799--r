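# the scoring engine: gamma discretization, NJ guide tree, pruning
# likelihood, alpha estimation, posterior rates, normalization, grades

test_that("discrete gamma categories have mean one and match quadrature", {
  expect_equal(discretize_gamma(1, 1)$rates, 1)
  for (alpha in c(0.2, 0.5, 1, 2, 8)) {
    for (K in c(2, 4, 16)) {
      pr <- discretize_gamma(alpha, K)
      expect_equal(mean(pr$rates), 1, tolerance = 1e-9)
      expect_true(all(diff(pr$rates) > 0))
    }
  }
  expect_error(discretize_gamma(0, 4), "positive")

  # alpha = 1, K = 4: conditional means of the exponential over quartile
  # bins, by direct numerical integration
  pr <- discretize_gamma(1, 4)
  qb <- qgamma(seq(0, 1, 0.25), 1, 1)
  oracle <- vapply(1:4, function(k) {
    integrate(function(x) x * dgamma(x, 1, 1), qb[k], qb[k + 1])$value * 4
  }, numeric(1))
  expect_equal(pr$rates, oracle, tolerance = 1e-6)
})

test_that("Kimura-corrected distances follow the closed form and cap", {
  aln <- alignment(c("a", "b"), c("MKVLWA", "MKILWA"))  # p = 1/6
  p <- 1 / 6
  expect_equal(kimura_distances(aln)[1, 2], -log(1 - p - p^2 / 5))
  # saturated pair: correction undefined, capped
  sat <- alignment(c("a", "b"), c("ARNDCQEGHIKL", "LKIHGEQCDNRA"))
  expect_warning(d <- kimura_distances(sat), "capped")
  expect_equal(d[1, 2], 5.2)
  # disjoint coverage is an error naming the pair
  gap <- alignment(c("a", "b"), c("MK--", "--MK"))
  expect_error(kimura_distances(gap), "'a' and 'b'")
})

test_that("NJ recovers additive 4- and 5-taxon metrics exactly", {
  # build additive matrices from known trees, then demand exact recovery
  for (nwk in c("((a:0.11,b:0.23):0.08,(c:0.15,d:0.31):0.05);",
                "(((a:0.1,b:0.2):0.07,c:0.3):0.04,(d:0.12,e:0.22):0.06);")) {
    tr0 <- ape::unroot(ape::read.tree(text = nwk))
    d <- ape::cophenetic.phylo(tr0)
    tr <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), tr0)[1], 0)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-10)
  }
})

test_that("guide trees handle two-taxon and identical-sequence alignments", {
  two <- alignment(c("a", "b"), c("MKVLWA", "MKILWA"))
  tr <- build_nj_tree(two)
  d <- kimura_distances(two)[1, 2]
  expect_equal(ape::cophenetic.phylo(tr)["a", "b"], d)

  same <- alignment(c("a", "b", "c", "d"), rep("MKVLWA", 4))
  star <- build_nj_tree(same)
  expect_true(all(star$edge.length == 0))

  sim <- simulate_study(seed = 17, n_taxa = 25, n_sites = 80)
  trs <- suppressWarnings(build_nj_tree(sim$alignment))  # saturation warnings ok
  expect_true(all(trs$edge.length >= 0))
  expect_setequal(trs$tip.label, aln_ids(sim$alignment))
})

test_that("pruning likelihood equals exhaustive enumeration on small trees", {
  set.seed(101)
  model <- jtt_model()
  for (i in 1:25) {
    ntaxa <- sample(2:4, 1)
    tr <- simulate_tree(ntaxa, seed = i)
    col <- random_column(tr)
    r <- runif(1, 0.2, 3)
    expect_equal(site_log_likelihood(col, tr, model, r),
                 oracle_site_loglik(col, tr, model, r),
                 tolerance = 1e-10)
  }
})

test_that("degenerate tree limits reduce to the stationary distribution", {
  model <- jtt_model()
  # single-leaf tree: likelihood of residue a is pi_a
  tr1 <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                        edge.length = 0.3, tip.label = "a", Nnode = 1L),
                   class = "phylo", order = "cladewise")
  expect_equal(site_log_likelihood(c(a = "W"), tr1, model, 1),
               log(unname(model$pi["W"])), tolerance = 1e-12)

  # star tree, all t = 0, invariant column: log pi_a independent of rate
  star <- read_tree(text = "(a:0,b:0,c:0,d:0);")
  for (r in c(0.1, 1, 7)) {
    expect_equal(site_log_likelihood(c(a = "M", b = "M", c = "M", d = "M"),
                                     star, model, r),
                 log(unname(model$pi["M"])), tolerance = 1e-10)
  }
  expect_error(site_log_likelihood(c(a = "M", z = "M"),
                                   read_tree(text = "(a:1,b:1);"), model, 1),
               "match")
})

test_that("likelihoods are invariant to branch-rate rescaling", {
  model <- jtt_model()
  tr <- simulate_tree(6, seed = 8)
  col <- random_column(tr, p_gap = 0.2)
  base <- site_log_likelihood(col, tr, model, 1.3)
  for (cc in c(0.25, 4)) {
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * cc
    expect_equal(site_log_likelihood(col, tr2, model, 1.3 / cc), base,
                 tolerance = 1e-10)
  }
})

test_that("alpha estimation satisfies the optimizer contract and recovers truth", {
  model <- jtt_model()
  sim <- simulate_study(seed = 19, n_taxa = 30, n_sites = 120,
                        gamma_alpha = 0.5)
  K <- 8
  ahat <- estimate_alpha(sim$alignment, sim$tree, model, K)
  expect_gt(as.numeric(ahat), 0.2)
  expect_lt(as.numeric(ahat), 1.2)
  expect_false(attr(ahat, "at_bound"))

  # objective at the optimum beats both bracket ends
  obj <- function(alpha) {
    pr <- discretize_gamma(alpha, K)
    ll <- vapply(pr$rates, function(r) {
      vapply(seq_len(n_cols(sim$alignment)), function(s)
        site_log_likelihood(sim$alignment, sim$tree, model, r, site = s),
        numeric(1))
    }, numeric(n_cols(sim$alignment)))
    m <- apply(ll, 1, max)
    sum(m + log(rowMeans(exp(ll - m))))
  }
  expect_gte(obj(as.numeric(ahat)), obj(0.05) - 1e-6)
  expect_gte(obj(as.numeric(ahat)), obj(10) - 1e-6)

  # invariant alignment pins the estimate at the lower bound, flagged
  inv <- alignment(c("a", "b", "c"), rep(strrep("MKV", 10), 3))
  tri <- read_tree(text = "(a:0.2,(b:0.1,c:0.1):0.1);")
  expect_warning(a0 <- estimate_alpha(inv, tri, model, 4), "bound")
  expect_equal(as.numeric(a0), 0.05, tolerance = 0.01)
  expect_true(attr(a0, "at_bound"))
})

test_that("posterior mean rates obey closed-form and no-information limits", {
  model <- jtt_model()
  aln <- alignment(c("a", "b"), c("AMKV", "AMRV"))
  tr <- read_tree(text = "(a:0.1,b:0.2);")

  # K = 1: posterior equals the single category rate
  pr1 <- discretize_gamma(2, 1)
  expect_equal(as.numeric(posterior_mean_rates(aln, tr, model, pr1)),
               rep(1, 4))

  # star tree with t = 0: no information, posterior equals prior mean
  star <- read_tree(text = "(a:0,b:0);")
  pr <- discretize_gamma(0.7, 4)
  expect_equal(as.numeric(posterior_mean_rates(aln, star, model, pr)),
               rep(1, 4), tolerance = 1e-9)

  # two-taxon, K = 2: hand-computed two-term Bayes quotient
  pr2 <- discretize_gamma(0.7, 2)
  L <- vapply(pr2$rates, function(r) vapply(1:4, function(s)
    exp(oracle_site_loglik(setNames(aln$mat[, s], aln$ids), tr, model, r)),
    numeric(1)), numeric(4))
  expected <- (L[, 1] * pr2$rates[1] + L[, 2] * pr2$rates[2]) /
    (L[, 1] + L[, 2])
  expect_equal(as.numeric(posterior_mean_rates(aln, tr, model, pr2)),
               expected, tolerance = 1e-9)

  # all-gap columns are flagged and fixed at the prior mean
  g <- alignment(c("a", "b"), c("A-KV", "A-RV"))
  out <- posterior_mean_rates(g, tr, model, pr2)
  expect_equal(as.numeric(out[2]), 1)
  expect_equal(attr(out, "all_gap"), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("duplicate taxa on zero-length branches do not move the rates", {
  model <- jtt_model()
  sim <- simulate_study(seed = 23, n_taxa = 8, n_sites = 50)
  pr <- discretize_gamma(1, 4)
  base <- as.numeric(posterior_mean_rates(sim$alignment, sim$tree, model, pr))

  # graft two zero-length duplicates of the first taxon
  tip <- aln_ids(sim$alignment)[1]
  nwk <- ape::write.tree(sim$tree)
  nwk2 <- sub(paste0(tip, ":"),
              paste0("(", tip, ":0,", tip, "_d1:0,", tip, "_d2:0):"), nwk,
              fixed = TRUE)
  tr2 <- read_tree(text = nwk2)
  seqs <- apply(as.matrix(sim$alignment), 1, paste, collapse = "")
  aln2 <- alignment(c(names(seqs), paste0(tip, "_d1"), paste0(tip, "_d2")),
                    c(seqs, seqs[tip], seqs[tip]))
  dup <- as.numeric(posterior_mean_rates(aln2, tr2, model, pr))
  expect_equal(dup, base, tolerance = 1e-8)
})

test_that("normalization centers and scales with the population sd", {
  s <- normalize_scores(c(0.5, 1.0, 1.5))
  expect_equal(s, c(-1.2247, 0, 1.2247), tolerance = 1e-4)  # sd = sqrt(1/6)
  x <- rgamma(200, 0.5, 0.5)
  z <- normalize_scores(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  expect_error(normalize_scores(c(1, 1, 1)), "zero variance|degenerate")
  expect_error(normalize_scores(1), "at least 2")
})

test_that("grades bin scores into nine conservation levels", {
  s <- c(-2.1, -1.5, -0.9, -0.4, 0, 0.3, 0.8, 1.4, 2.2)
  g <- assign_grades(s)
  expect_equal(sort(g), 1:9)           # distinct scores: a permutation
  expect_equal(g[which.min(s)], 9L)    # most conserved
  expect_equal(g[which.max(s)], 1L)    # most variable
  expect_true(all(diff(g[order(s)]) < 0))

  # ties break toward the conserved side
  expect_equal(assign_grades(c(rep(-1, 3), 0:5)),
               c(9L, 9L, 9L, 6L, 5L, 4L, 3L, 2L, 1L))
})

test_that("score tables satisfy the normalization contract end to end", {
  sim <- simulate_study(seed = 29, n_taxa = 15, n_sites = 60)
  sc <- score_alignment(sim$alignment, alpha = 1, ref_id = "t001")
  ok <- !is.na(sc$score)
  expect_equal(mean(sc$score[ok]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(sc$score[ok]^2)), 1, tolerance = 1e-9)
  expect_true(all(sc$raw_rate > 0))
  expect_equal(sc$ref_residue, seq_len(60))  # gap-free reference
  expect_true(all(sc$grade[ok] %in% 1:9))
  # scores TSV round-trips through the writer
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores(sc, path, comments = "unit test")
  back <- read_scores(path)
  expect_equal(back$score, sc$score, tolerance = 1e-5)
  expect_equal(back$grade, sc$grade)
})
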