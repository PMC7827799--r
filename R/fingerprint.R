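#' Classify residues as family-unique, shared-conserved or variable
#'
#' Dual-alignment fingerprinting: a within-family score table (e.g. the
#' aromatase alignment) and a cross-superfamily score table (e.g. all human
#' P450s structurally aligned) are joined on reference residue numbering.
#' With conservation threshold `tau_c` and variability threshold `tau_v` on
#' the normalized score scale (lower = more conserved):
#'
#' * `variable` — not conserved within the family (`s_within > tau_c`);
#' * `shared-conserved` — conserved in both (`s_within <= tau_c`,
#'   `s_cross <= tau_c`);
#' * `family-unique` — conserved in the family but variable across the
#'   superfamily (`s_within <= tau_c`, `s_cross > tau_v`);
#' * `ambiguous` — conserved in the family with `tau_c < s_cross <= tau_v`.
#'
#' Residues present in only one table are labelled `uncomparable`. Over
#' comparable residues the four labels partition the set.
#'
#' @param within a `site_scores` table with reference numbering.
#' @param cross a second `site_scores` table sharing the same reference
#'   numbering (its own alignment and refmap).
#' @param tau_c conservation threshold (default -0.5).
#' @param tau_v variability threshold (default 0.0, must be >= `tau_c`).
#' @return data.frame: `ref_residue`, `s_within`, `s_cross`, `label`.
#' @export
fingerprint_classify <- function(within, cross, tau_c = -0.5, tau_v = 0.0) {
  if (tau_v < tau_c) stop("tau_v must be >= tau_c")
  w <- within[!is.na(within$ref_residue) & !is.na(within$score),
              c("ref_residue", "score")]
  x <- cross[!is.na(cross$ref_residue) & !is.na(cross$score),
             c("ref_residue", "score")]
  names(w)[2] <- "s_within"; names(x)[2] <- "s_cross"
  all_res <- sort(union(w$ref_residue, x$ref_residue))
  df <- data.frame(ref_residue = all_res,
                   s_within = w$s_within[match(all_res, w$ref_residue)],
                   s_cross = x$s_cross[match(all_res, x$ref_residue)])
  lab <- character(nrow(df))
  comp <- !is.na(df$s_within) & !is.na(df$s_cross)
  lab[!comp] <- "uncomparable"
  sw <- df$s_within[comp]; sx <- df$s_cross[comp]
  l <- ifelse(sw > tau_c, "variable",
       ifelse(sx <= tau_c, "shared-conserved",
       ifelse(sx > tau_v, "family-unique", "ambiguous")))
  lab[comp] <- l
  df$label <- lab
  attr(df, "tau_c") <- tau_c
  attr(df, "tau_v") <- tau_v
  df
}
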