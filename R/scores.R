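#' Z-normalize raw conservation rates
#'
#' Centers and scales posterior mean rates so that the mean over scored
#' columns is exactly 0 and the standard deviation exactly 1, using the
#' population (1/N) standard deviation: the normalization is a rescaling of
#' the full score set, not an estimate from a sample. Because low rate means
#' slow evolution, a lower normalized score means a more conserved site.
#'
#' @param raw numeric vector of raw rates (>= 2 values, nonzero variance).
#' @return Numeric scores with `mean == 0` and population `sd == 1`.
#' @export
normalize_scores <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) < 2L) stop("need at least 2 scored columns")
  if (any(!is.finite(raw))) stop("non-finite raw rates")
  mu <- mean(raw)
  sdev <- sqrt(mean((raw - mu)^2))
  if (sdev == 0) stop("degenerate alignment: zero variance in rates")
  (raw - mu) / sdev
}

#' Bin normalized scores into nine conservation grades
#'
#' Grades follow the structure-coloring convention: 9 = most conserved,
#' 1 = most variable. Scores are cut into the nine equal-count quantile bins
#' of their own distribution; ties are broken toward the more-conserved
#' grade, which is conservative for "highly conserved" calls.
#'
#' @param scores normalized conservation scores.
#' @return Integer grades in 1..9, same length as `scores`.
#' @export
assign_grades <- function(scores) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores))) stop("non-finite scores")
  n <- length(scores)
  rk <- rank(scores, ties.method = "min")
  bin <- ceiling(rk * 9 / n)
  as.integer(10L - bin)
}

#' Score every column of an alignment for evolutionary conservation
#'
#' The full scoring engine: build (or accept) a guide tree, fix or estimate
#' the gamma shape, compute empirical-Bayes posterior mean rates per column
#' by Felsenstein pruning under a discrete-gamma rate prior, z-normalize
#' them into conservation scores and bin into nine grades. Optionally maps
#' columns to reference residue numbering.
#'
#' Columns with zero coverage (all gap/`X`) are excluded from normalization
#' and carry `NA` score and grade; their raw rate is the prior mean 1.
#'
#' @param aln a `conserv_alignment`.
#' @param tree optional `phylo`; defaults to [build_nj_tree()] on the
#'   alignment. Branch lengths are used as-is (no ML re-optimization).
#' @param model a [subst_model()], default [jtt_model()].
#' @param K number of discrete gamma categories (default 16).
#' @param alpha `"estimate"` (default) to fit the gamma shape by maximum
#'   likelihood, or a fixed positive number.
#' @param ref_id optional reference sequence id for residue numbering.
#' @param offset residue number of the first reference residue (default 1).
#' @return A data.frame of class `site_scores` with one row per column:
#'   `column`, `ref_residue` (NA where the reference is absent or gapped),
#'   `raw_rate`, `score`, `grade`, `coverage`. Attributes: `alpha`, `K`,
#'   `model`, `tree`.
#' @examples
#' sim <- simulate_study(seed = 1, n_taxa = 12, n_sites = 40)
#' sc <- score_alignment(sim$alignment, alpha = 1)
#' head(sc)
#' @export
score_alignment <- function(aln, tree = NULL, model = jtt_model(), K = 16,
                            alpha = "estimate", ref_id = NULL, offset = 1) {
  if (is.null(tree)) tree <- build_nj_tree(aln)
  validate_tree(tree, aln)
  if (identical(alpha, "estimate")) {
    alpha_hat <- estimate_alpha(aln, tree, model, K)
  } else {
    if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
    alpha_hat <- alpha
  }
  prior <- discretize_gamma(as.numeric(alpha_hat), K)
  rhat <- posterior_mean_rates(aln, tree, model, prior)
  all_gap <- attr(rhat, "all_gap")
  coverage <- colMeans(!is.na(.aln_codes(aln)))
  score <- rep(NA_real_, aln$n_cols)
  grade <- rep(NA_integer_, aln$n_cols)
  scored <- !all_gap
  if (sum(scored) < 2L) stop("fewer than 2 scorable columns")
  score[scored] <- normalize_scores(rhat[scored])
  grade[scored] <- assign_grades(score[scored])
  ref_residue <- rep(NA_integer_, aln$n_cols)
  if (!is.null(ref_id)) {
    rm <- build_refmap(aln, ref_id, offset)
    ref_residue <- rm$col_to_res
  }
  out <- data.frame(column = seq_len(aln$n_cols), ref_residue = ref_residue,
                    raw_rate = as.numeric(rhat), score = score, grade = grade,
                    coverage = coverage)
  attr(out, "alpha") <- as.numeric(alpha_hat)
  attr(out, "K") <- K
  attr(out, "model") <- model$name
  attr(out, "tree") <- tree
  class(out) <- c("site_scores", "data.frame")
  out
}

#' Write a site score table as TSV
#' @param scores a `site_scores` data.frame.
#' @param path output path.
#' @param comments optional character vector written as leading `#` lines.
#' @export
write_scores <- function(scores, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  df <- as.data.frame(scores)
  df$raw_rate <- sprintf("%.6f", df$raw_rate)
  df$score <- ifelse(is.na(df$score), "NA", sprintf("%.6f", df$score))
  df$coverage <- sprintf("%.4f", df$coverage)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site score table written by [write_scores()]
#' @param path TSV path.
#' @export
read_scores <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  class(df) <- c("site_scores", "data.frame")
  df
}
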