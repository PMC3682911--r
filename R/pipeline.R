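#' Configuration for the end-to-end supermatrix pipeline
#'
#' Collects paths, assembly thresholds and search settings; every
#' convention-derived constant (250 bp minimum, 11 search starts, the
#' strong-support threshold 85, RELL replicates) is surfaced here with its
#' default.
#'
#' @param genes named list: per-gene input, either FASTA paths or
#'   `sequence_records` / character matrices (aligned).
#' @param taxonomy optional `taxonomy_table` or TSV path.
#' @param out_dir output directory (created if needed).
#' @param aligned are inputs already aligned (default `TRUE`)? If `FALSE`,
#'   coding genes are translation-aligned and others progressively aligned.
#' @param coding_genes gene names to translation-align when `aligned =
#'   FALSE`.
#' @param min_total_bp assembly minimum-data threshold (default 250).
#' @param deduplicate drop identical-sequence taxa (default `TRUE`).
#' @param trim_occupancy end-trim occupancy when aligning (default 0.5).
#' @param n_starts parsimony starting trees (default 11).
#' @param support_replicates RELL replicates for SH-like support (default
#'   1000).
#' @param strong_support strong-support threshold (default 85).
#' @param rogue_support weak-support threshold for rogue flagging (default
#'   50).
#' @param seed master seed; stages derive their own seeds from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(genes, taxonomy = NULL, out_dir = tempfile("sparsephy"),
                       aligned = TRUE, coding_genes = character(0),
                       min_total_bp = 250, deduplicate = TRUE,
                       trim_occupancy = 0.5, n_starts = 11,
                       support_replicates = 1000, strong_support = 85,
                       rogue_support = 50, seed = 1) {
  stopifnot(length(genes) > 0, !is.null(names(genes)), n_starts >= 1)
  structure(list(genes = genes, taxonomy = taxonomy, out_dir = out_dir,
                 aligned = aligned, coding_genes = coding_genes,
                 min_total_bp = min_total_bp, deduplicate = deduplicate,
                 trim_occupancy = trim_occupancy, n_starts = n_starts,
                 support_replicates = support_replicates,
                 strong_support = strong_support,
                 rogue_support = rogue_support, seed = seed),
            class = "run_config")
}

#' Run the full supermatrix pipeline
#'
#' Orchestrates assemble (+ optional align) -> maximum-likelihood search
#' from parsimony starts -> NNI optimization -> SH-like branch support ->
#' missing-data diagnostics -> taxonomy audit, writing every artifact under
#' the configured output directory. Deterministic given the master seed; a
#' failing stage aborts with the stage name while earlier artifacts remain
#' on disk.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list: `matrix`, `stats`, `tree` (support
#'   annotated), `lnL`, `model`, `support_table`, `support_summary`,
#'   `regression`, `audit`, `rogues`, `artifacts` (file paths).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run.log")
  cat("", file = logfile)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", file = logfile, append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  artifacts <- character(0)

  aln <- stage("assemble", {
    lapply(cfg$genes, function(g) {
      if (is.character(g) && length(g) == 1 && file.exists(g)) {
        read_gene_fasta(g, gene = "gene")
      } else {
        g
      }
    })
  })
  if (!cfg$aligned) {
    aln <- stage("align", {
      out <- list()
      for (g in names(aln)) {
        rec <- aln[[g]]
        if (!inherits(rec, "sequence_records")) {
          rec <- sequence_records(rownames(rec), apply(rec, 1, paste,
                                                       collapse = ""), g)
        }
        al <- if (g %in% cfg$coding_genes) {
          translation_align(rec)
        } else {
          prof <- progressive_align(setNames(rec$sequence, rec$taxon))
          sequence_records(rownames(prof$members),
                           apply(prof$members, 1, paste, collapse = ""), g)
        }
        out[[g]] <- trim_ends(al, cfg$trim_occupancy)
      }
      out
    })
  }
  sm <- stage("assemble", {
    named <- aln
    for (g in names(named)) {
      if (inherits(named[[g]], "sequence_records")) {
        named[[g]] <- select_longest_per_species(named[[g]])
        named[[g]]$gene <- g
      }
    }
    m <- concatenate_genes(named)
    m <- filter_min_total(m, cfg$min_total_bp)
    if (cfg$deduplicate) m <- deduplicate_identical(m)
    if (nrow(m$seq) == 0) {
      stop("no taxa survive the ", cfg$min_total_bp,
           "-bp minimum-data filter")
    }
    m
  })
  note("assembled %d taxa x %d bp", nrow(sm$seq), ncol(sm$seq))
  stats <- matrix_statistics(sm)
  nex <- file.path(cfg$out_dir, "matrix.nex")
  write_nexus_matrix(sm, nex)
  write_partition_file(sm, file.path(cfg$out_dir, "partitions.txt"))
  write.table(stats$per_gene, file.path(cfg$out_dir, "matrix_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, nex, file.path(cfg$out_dir, "partitions.txt"),
                 file.path(cfg$out_dir, "matrix_stats.tsv"))

  search <- stage("search", {
    ml_search(sm, n_starts = cfg$n_starts, seed = derive_seed(cfg$seed, 10))
  })
  note("best of %d start(s): lnL = %.4f", cfg$n_starts, search$lnL)
  best_path <- file.path(cfg$out_dir, "best_tree.nwk")
  write_newick(search$tree, best_path)
  write.table(search$per_start, file.path(cfg$out_dir, "search_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, best_path, file.path(cfg$out_dir, "search_log.tsv"))

  sup_tree <- stage("support", {
    annotate_support(search$tree, sm, search$model,
                     B = cfg$support_replicates,
                     seed = derive_seed(cfg$seed, 20))
  })
  sup_path <- file.path(cfg$out_dir, "support_tree.nwk")
  write_newick(sup_tree, sup_path)
  write.table(attr(sup_tree, "support_table"),
              file.path(cfg$out_dir, "support_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, sup_path, file.path(cfg$out_dir, "support_table.tsv"))

  diag <- stage("diagnose", {
    list(regression = completeness_regression(search$tree, sm),
         summary = support_summary(sup_tree, cfg$strong_support))
  })
  note("completeness regression: r = %.3f (P = %.3f); %.0f%% of nodes > %g",
       diag$regression$r, diag$regression$p_value,
       diag$summary$fraction_above, cfg$strong_support)
  write.table(cbind(diag$regression, diag$summary),
              file.path(cfg$out_dir, "diagnostics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, file.path(cfg$out_dir, "diagnostics.tsv"))

  audit <- NULL; rogues <- NULL
  if (!is.null(cfg$taxonomy)) {
    tax <- if (is.character(cfg$taxonomy)) read_taxonomy(cfg$taxonomy) else cfg$taxonomy
    audit <- stage("audit", {
      audit_classification(sup_tree, tax, threshold = cfg$strong_support)
    })
    rogues <- stage("audit", {
      flag_rogues(sup_tree, tax, support_threshold = cfg$rogue_support)
    })
    write.table(audit, file.path(cfg$out_dir, "audit.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(rogues, file.path(cfg$out_dir, "rogues.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, file.path(cfg$out_dir, "audit.tsv"),
                   file.path(cfg$out_dir, "rogues.tsv"))
    note("audited %d taxa; %d non-monophyletic", nrow(audit),
         sum(!audit$status %in% c("monophyletic", "trivial")))
  }

  invisible(list(matrix = sm, stats = stats, tree = sup_tree,
                 lnL = search$lnL, model = search$model,
                 support_table = attr(sup_tree, "support_table"),
                 support_summary = diag$summary, regression = diag$regression,
                 audit = audit, rogues = rogues, artifacts = artifacts))
}
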