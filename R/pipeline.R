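# End-to-end orchestration: (simulate | read) -> filter -> tree -> score ->
# regions -> fingerprint -> motifs -> paint, with every resolved default and
# seed written to run.log so no threshold is silent.

.cfg_get <- function(cfg, path, default = NULL) {
  for (k in path) {
    if (is.null(cfg[[k]])) return(default)
    cfg <- cfg[[k]]
  }
  cfg
}

# order-insensitive checksum of the resolved config, for output provenance
.cfg_hash <- function(cfg) {
  txt <- yaml::as.yaml(cfg)
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 997)) %%
            .Machine$integer.max)
}

#' Run the full conservation-analysis pipeline
#'
#' Executes every stage the configuration enables and writes plain-text
#' results plus a `run.log` recording versions, the seed and every resolved
#' default. Outputs are deterministic given the config and seed. A stage
#' whose inputs are absent (e.g. motifs without a clade table) is skipped
#' with a logged reason; a stage error aborts the run naming the stage.
#'
#' @param config a named list or path to a YAML file. Recognized fields:
#'   `seed` (integer, default 1); `out_dir` (required); either `simulate`
#'   (arguments of [simulate_study()]) or `inputs` (`alignment`, `format`,
#'   `tree`, `clades`, `structure` paths); `reference` (`id`, `offset`);
#'   `filter` (`identity_threshold` in percent, optional);
#'   `score` (`K`, `alpha`); `regions` (YAML path, `"elements"` for the
#'   bundled aromatase elements, or a named list of interval lists);
#'   `conserved_grade`; `motifs` (`"default"`, a YAML path with entries
#'   `name: {pattern, window}`, or `FALSE`); `fingerprint`
#'   (`cross_alignment`, `cross_format`, `cross_ref_id`, `cross_offset`,
#'   `tau_c`, `tau_v`); `paint` (`chain`, `mode`).
#' @return Invisibly, the output directory; files `scores.tsv`,
#'   `regions.tsv`, `motifs.tsv`, `fingerprint.tsv`, `painted.pdb` and
#'   `run.log` as enabled.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- .cfg_get(config, "out_dir")
  if (is.null(out_dir)) stop("config must name an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  logline <- function(...) cat(paste0(..., "\n"), file = logf, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- as.integer(.cfg_get(config, "seed", 1L))
  # hash covers the analysis parameters, not the output location
  hash <- .cfg_hash(config[setdiff(names(config), "out_dir")])
  logline("conservscape ", as.character(utils::packageVersion("conservscape")),
          " | R ", R.version.string)
  logline("seed: ", seed)
  logline("config_hash: ", hash)

  # ---- inputs -------------------------------------------------------------
  clades <- NULL; tree <- NULL; struct <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    sim <- stage("simulate", do.call(simulate_study, sim_args))
    aln <- sim$alignment; tree <- sim$tree; clades <- sim$clades
    logline("simulate: n_taxa=", length(aln_ids(aln)),
            " n_sites=", n_cols(aln))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    fmt <- inp$format %||% "fasta"
    aln <- stage("read_alignment", read_alignment(inp$alignment, fmt))
    if (!is.null(inp$tree))
      tree <- stage("read_tree", read_tree(inp$tree))
    if (!is.null(inp$clades))
      clades <- stage("read_clades",
                      validate_clades(read_clade_table(inp$clades), aln))
    if (!is.null(inp$structure))
      struct <- stage("read_structure", read_structure(inp$structure))
    logline("inputs: alignment=", inp$alignment)
  } else stop("config must contain either 'simulate' or 'inputs'")

  ref_id <- .cfg_get(config, c("reference", "id"), aln_ids(aln)[1])
  ref_offset <- .cfg_get(config, c("reference", "offset"), 1L)
  logline("reference: id=", ref_id, " offset=", ref_offset,
          if (is.null(.cfg_get(config, c("reference", "id"))))
            " (default: first sequence)" else "")

  thr <- .cfg_get(config, c("filter", "identity_threshold"))
  if (!is.null(thr)) {
    aln <- stage("filter", filter_by_identity(aln, ref_id, thr))
    logline("filter: identity_threshold=", thr, "%, removed=",
            length(attr(aln, "removed")))
    if (!is.null(tree) &&
        !setequal(tree$tip.label, aln_ids(aln))) {
      tree <- NULL
      logline("filter: provided tree dropped (leaf set changed); NJ rebuilt")
    }
    if (!is.null(clades)) clades <- validate_clades(clades, aln)
  }

  # ---- scoring ------------------------------------------------------------
  K <- .cfg_get(config, c("score", "K"), 16L)
  alpha <- .cfg_get(config, c("score", "alpha"), "estimate")
  if (is.null(tree)) {
    tree <- stage("nj_tree", build_nj_tree(aln))
    logline("tree: neighbor joining (Kimura-corrected p-distance), ",
            "negative branches clamped to 0")
  } else logline("tree: provided")
  scores <- stage("score", score_alignment(aln, tree = tree, K = K,
                                           alpha = alpha, ref_id = ref_id,
                                           offset = ref_offset))
  logline("score: model=JTT K=", K, " alpha=",
          sprintf("%.4f", attr(scores, "alpha")),
          if (identical(alpha, "estimate")) " (ML estimate)" else " (fixed)")
  write_scores(scores, file.path(out_dir, "scores.tsv"),
               comments = c(paste0("config_hash: ", hash),
                            paste0("seed: ", seed)))

  # ---- regions ------------------------------------------------------------
  regs <- config$regions
  if (!isFALSE(regs)) {
    regions <- if (is.null(regs) || identical(regs, "elements")) {
      logline("regions: bundled aromatase structural elements")
      aromatase_elements()
    } else if (is.character(regs)) {
      stage("regions", read_regions_yaml(regs))
    } else {
      stage("regions", {
        out <- lapply(names(regs), function(nm) region(nm, regs[[nm]]))
        names(out) <- names(regs); out
      })
    }
    cg <- .cfg_get(config, "conserved_grade", 8L)
    logline("regions: conserved_grade>=", cg,
            if (is.null(config$conserved_grade)) " (default)" else "")
    rs <- tryCatch(region_summary(scores, regions, cg), error = function(e) {
      logline("regions: skipped (", conditionMessage(e), ")")
      NULL
    })
    if (!is.null(rs))
      write.table(rs, file.path(out_dir, "regions.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }

  # ---- fingerprint --------------------------------------------------------
  fp <- config$fingerprint
  if (!is.null(fp)) {
    tau_c <- fp$tau_c %||% -0.5
    tau_v <- fp$tau_v %||% 0.0
    logline("fingerprint: tau_c=", tau_c, " tau_v=", tau_v)
    cross_aln <- stage("fingerprint",
                       read_alignment(fp$cross_alignment,
                                      fp$cross_format %||% "fasta"))
    cross_scores <- stage("fingerprint", score_alignment(
      cross_aln, K = K, alpha = alpha,
      ref_id = fp$cross_ref_id %||% ref_id,
      offset = fp$cross_offset %||% ref_offset))
    calls <- fingerprint_classify(scores, cross_scores, tau_c, tau_v)
    write.table(calls, file.path(out_dir, "fingerprint.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # ---- motifs -------------------------------------------------------------
  mcfg <- config$motifs
  if (!isFALSE(mcfg)) {
    if (is.null(clades)) {
      logline("motifs: skipped (no clade table)")
    } else {
      motifs <- if (is.null(mcfg) || identical(mcfg, "default")) {
        logline("motifs: bundled PKA/PKG/heme/EXXR set")
        default_motifs()
      } else {
        y <- yaml::read_yaml(mcfg)
        out <- lapply(names(y), function(nm) {
          p <- compile_pattern(y[[nm]]$pattern, name = nm)
          attr(p, "window") <- as.integer(y[[nm]]$window)
          p
        })
        names(out) <- names(y); out
      }
      rmap <- build_refmap(aln, ref_id, ref_offset)
      rows <- list()
      for (p in motifs) {
        win <- attr(p, "window")
        res <- tryCatch(
          anchored_clade_presence(aln, clades, rmap, p, win),
          error = function(e) {
            logline("motifs: '", p$name, "' skipped (",
                    conditionMessage(e), ")")
            NULL
          })
        if (!is.null(res)) rows[[length(rows) + 1L]] <- res
      }
      if (length(rows)) {
        mt <- do.call(rbind, rows)
        mt$fraction <- sprintf("%.4f", mt$fraction)
        write.table(mt, file.path(out_dir, "motifs.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
    }
  }

  # ---- structure painting -------------------------------------------------
  if (!is.null(struct)) {
    chain <- .cfg_get(config, c("paint", "chain"), "A")
    mode <- .cfg_get(config, c("paint", "mode"), "grade")
    painted <- stage("paint", paint_bfactor(struct, scores, chain, mode))
    logline("paint: chain=", chain, " mode=", mode, " unmapped=",
            length(attr(painted, "unmapped")))
    write_structure(painted, file.path(out_dir, "painted.pdb"))
  }

  logline("done")
  invisible(out_dir)
}
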