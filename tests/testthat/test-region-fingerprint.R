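# helper: a hand-built score table in reference numbering
fake_scores <- function(residues, scores, grades) {
  df <- data.frame(column = seq_along(residues), ref_residue = residues,
                   raw_rate = 1, score = scores, grade = grades,
                   coverage = 1)
  class(df) <- c("site_scores", "data.frame")
  df
}

test_that("identity and similarity percentages follow the definitions", {
  aln <- alignment(c("a", "b"), c("MKVL", "MKIA"))
  out <- pairwise_identity_similarity(aln, "a", "b")
  expect_equal(out[["identity"]], 50)  # 2 of 4 identical
  # V/I is BLOSUM62-positive, L/A is not: 3 of 4 similar
  expect_equal(out[["similarity"]], 75)

  idd <- pairwise_identity_similarity(aln, "a", "a")
  expect_equal(unname(idd), c(100, 100))

  # property: identity never exceeds similarity (positive diagonal)
  sim <- simulate_study(seed = 3, n_taxa = 10, n_sites = 50)
  ids <- aln_ids(sim$alignment)
  for (j in 2:10) {
    v <- pairwise_identity_similarity(sim$alignment, ids[1], ids[j])
    expect_lte(v[["identity"]], v[["similarity"]])
  }
  gap <- alignment(c("a", "b"), c("MK--", "--MK"))
  expect_error(pairwise_identity_similarity(gap, "a", "b"), "non-gap")
})

test_that("identity filtering keeps exactly the sequences above threshold", {
  # copy-with-k-mismatches construction: identities 35%, 45%, 80%
  ref <- strrep("ARNDCQEGHILKMFPSTWYV", 5)  # 100 residues
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq_len(k)
    ch[idx] <- ifelse(ch[idx] == "A", "G", "A")
    paste(ch, collapse = "")
  }
  aln <- alignment(c("ref", "s35", "s45", "s80"),
                   c(ref, mutate(ref, 65), mutate(ref, 55), mutate(ref, 20)))
  kept <- filter_by_identity(aln, "ref", 40)
  expect_equal(aln_ids(kept), c("ref", "s45", "s80"))
  expect_equal(attr(kept, "removed"), "s35")

  expect_equal(aln_ids(filter_by_identity(aln, "ref", 0)), aln_ids(aln))
  expect_equal(aln_ids(filter_by_identity(aln, "ref", 100)), "ref")
  expect_error(filter_by_identity(aln, "ref", 101), "\\[0, 100\\]")

  # monotone: raising the threshold never adds sequences
  prev <- aln_ids(aln)
  for (thr in c(20, 40, 60, 90)) {
    cur <- aln_ids(filter_by_identity(aln, "ref", thr))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("region conservation percentages count mapped conserved residues", {
  sc <- fake_scores(1:20, rep(0, 20), c(rep(9L, 10), rep(1L, 10)))
  expect_equal(as.numeric(region_conservation_percent(
    sc, region("all9", list(c(1, 10))))), 100)
  expect_equal(as.numeric(region_conservation_percent(
    sc, region("none", list(c(11, 20))))), 0)

  # 13-residue region with 2 conserved -> 15.4 (one-decimal, half-up)
  sc2 <- fake_scores(1:13, rep(0, 13), c(9L, 8L, rep(2L, 11)))
  p <- region_conservation_percent(sc2, region("srs3ish", list(c(1, 13))))
  expect_equal(as.numeric(p), 15.4)
  expect_equal(attr(p, "n_conserved"), 2)

  # unmapped residues are excluded from the denominator but reported
  p2 <- region_conservation_percent(sc2, region("r", list(c(10, 16))))
  expect_equal(attr(p2, "n_mapped"), 4)
  expect_equal(attr(p2, "unmapped"), 14:16)
  expect_error(region_conservation_percent(sc2, region("x", list(c(50, 60)))),
               "unmapped")

  # splitting a region into its intervals and pooling counts is invariant
  whole <- region_conservation_percent(sc, region("w", list(c(1, 20))))
  parts <- lapply(list(c(1, 7), c(8, 15), c(16, 20)), function(iv)
    region_conservation_percent(sc, region("p", list(iv))))
  pooled <- 100 * sum(sapply(parts, attr, "n_conserved")) /
    sum(sapply(parts, attr, "n_mapped"))
  expect_equal(as.numeric(whole), floor(pooled * 10 + 0.5) / 10)

  # summary table covers the bundled structural elements
  reg <- aromatase_elements()
  sc3 <- fake_scores(1:500, rep(0, 500), rep(c(9L, 1L), 250))
  tab <- region_summary(sc3, reg)
  expect_equal(nrow(tab), length(reg))
  expect_true(all(tab$percent_conserved >= 0 & tab$percent_conserved <= 100))
})

test_that("residue reports note per-clade deviations from the consensus", {
  # mostly frozen columns plus a variable tail so scores are well defined
  sim <- simulate_study(seed = 41, n_taxa = 20,
                        site_rates = c(rep(1e-6, 25), rep(1.5, 5)))
  ct <- sim$clades
  sc <- score_alignment(sim$alignment, alpha = 1, ref_id = aln_ids(sim$alignment)[1])

  # fully conserved column: empty notes everywhere
  rep0 <- residue_report(sim$alignment, ct, sc, residues = 5)
  expect_equal(rep0$notes, "")

  # plant a substitution into every mammal (a minority clade, so the
  # global consensus is untouched): note {mammal: T = 1.00}
  col5 <- substr(aln_seq(sim$alignment, ct$id[1]), 5, 5)
  planted <- plant_motif(sim$alignment, ct, "mammal",
                         5, if (col5 == "T") "S" else "T")
  sc2 <- score_alignment(planted, alpha = 1, ref_id = aln_ids(planted)[1])
  rep1 <- residue_report(planted, ct, sc2, residues = 5)
  mam_note <- rep1$notes_by_clade[[1]][["mammal"]]
  expect_equal(unname(mam_note[1]), 1.00)

  # frequencies per clade sum to <= 1 over random plants
  set.seed(5)
  aln <- sim$alignment
  for (k in 1:5) {
    cl <- sample(unique(ct$clade), 1)
    aln <- plant_motif(aln, ct, cl, sample(30, 1),
                       sample(AA_CODES, 1))
  }
  sc3 <- score_alignment(aln, alpha = 1, ref_id = aln_ids(aln)[1])
  rp <- residue_report(aln, ct, sc3, residues = 1:30)
  for (notes in rp$notes_by_clade)
    for (cl in names(notes))
      expect_lte(sum(notes[[cl]]), 1)

  # unmapped residues are skipped, not fatal
  rp2 <- residue_report(aln, ct, sc3, residues = c(2, 999))
  expect_equal(attr(rp2, "skipped"), 999)
})

test_that("fingerprint labels partition comparable residues", {
  w <- fake_scores(1:6, c(-1.0, -1.0, 0.5, -1.0, -0.6, -2), rep(5L, 6))
  x <- fake_scores(1:5, c(-1.0, 1.0, -1.0, -0.2, 0.4), rep(5L, 5))
  calls <- fingerprint_classify(w, x, tau_c = -0.5, tau_v = 0)
  expect_equal(calls$label[calls$ref_residue == 1], "shared-conserved")
  expect_equal(calls$label[calls$ref_residue == 2], "family-unique")
  expect_equal(calls$label[calls$ref_residue == 3], "variable")
  expect_equal(calls$label[calls$ref_residue == 4], "ambiguous")
  expect_equal(calls$label[calls$ref_residue == 5], "family-unique")
  expect_equal(calls$label[calls$ref_residue == 6], "uncomparable")
  comp <- calls$label != "uncomparable"
  expect_true(all(calls$label[comp] %in%
    c("shared-conserved", "family-unique", "variable", "ambiguous")))
  expect_error(fingerprint_classify(w, x, tau_c = 0, tau_v = -1), "tau_v")
})

test_that("planted family-only conserved sites are recovered", {
  # family-vs-superfamily pair at study scale: shared conserved core
  # (sites 1-45), ten family-only conserved positions (46-55), variable rest
  rates_within <- c(rep(0.05, 45), rep(0.05, 10), rep(2, 95))
  rates_cross <- c(rep(0.05, 45), rep(2, 10), rep(2, 95))
  win <- simulate_study(seed = 17, site_rates = rates_within)
  crs <- simulate_study(seed = 18, site_rates = rates_cross)
  sw <- score_alignment(win$alignment, alpha = "estimate", ref_id = "t001")
  sx <- score_alignment(crs$alignment, alpha = "estimate", ref_id = "t001")
  calls <- fingerprint_classify(sw, sx)
  found <- calls$ref_residue[calls$label == "family-unique"]
  truth <- 46:55
  precision <- length(intersect(found, truth)) / max(1, length(found))
  recall <- length(intersect(found, truth)) / length(truth)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})
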