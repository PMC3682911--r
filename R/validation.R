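#' Topology-recovery study under gene-wise missingness
#'
#' End-to-end validation of the inference stack: simulate a known tree and a
#' sparse supermatrix with structured gene-wise occupancy, run the full
#' maximum-likelihood protocol (parsimony starts, NNI search, model
#' optimization), and measure the Robinson-Foulds distance to the truth and
#' the log-likelihood margin between the found tree and the
#' branch-length-optimized true topology.
#'
#' The default conditions use the six best-sampled loci of the reference
#' squamate matrix (two rRNA and two protein-coding mitochondrial genes plus
#' two nuclear scaffold genes) at their published coverage fractions, 3000 bp
#' per partition, on 8-taxon Yule trees — a desk-scale rendition of the
#' scaffold portion of the emulated matrix (the methods vignette discusses
#' the choice).
#'
#' @param n_seeds number of independent replicates (default 20).
#' @param n_taxa taxa per replicate (default 8).
#' @param length_bp per-partition length (default 3000).
#' @param n_starts parsimony starting trees per search (default 11).
#' @param tree_depth root-to-tip depth in substitutions/site (default 0.5).
#' @param seed master seed.
#' @return data.frame: `seed`, `rf` (Robinson-Foulds distance to the true
#'   topology), `lnl_diff` (found minus optimized-truth log-likelihood),
#'   `n_taxa`.
#' @export
recovery_study <- function(n_seeds = 20, n_taxa = 8, length_bp = 3000,
                           n_starts = 11, tree_depth = 0.5, seed = 1) {
  ref <- squamate_gene_table()
  genes <- ref[ref$gene %in% c("12S", "16S", "cytb", "ND2", "cmos", "RAG1"), ]
  genes$length_bp <- as.integer(length_bp)
  out <- data.frame(seed = integer(), rf = integer(), lnl_diff = numeric(),
                    n_taxa = integer())
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(n_taxa = n_taxa, genes = genes,
                             tree_depth = tree_depth,
                             fragment_range = c(1, 1), # occupancy-driven only
                             scaffold_fraction = 0.25,
                             seed = derive_seed(seed, 100 + s))
    sim <- simulate_dataset(cfg)
    res <- suppressWarnings(ml_search(sim$matrix, n_starts = n_starts,
                                      seed = derive_seed(seed, 200 + s)))
    truth <- ape::unroot(sim$tree)
    rf <- robinson_foulds(ape::unroot(res$tree), truth)
    topt <- suppressWarnings(
      optimize_branch_lengths(truth, sim$matrix, res$model))
    out <- rbind(out, data.frame(seed = s, rf = rf,
                                 lnl_diff = res$lnL - attr(topt, "lnL"),
                                 n_taxa = ape::Ntip(res$tree)))
  }
  out
}

# Unnormalized Robinson-Foulds distance via internal-split comparison.
robinson_foulds <- function(t1, t2) {
  splits_of <- function(tr) {
    tr <- ape::unroot(tr)
    sets <- node_tip_sets(tr)
    labs <- tr$tip.label
    keys <- character(0)
    for (e in internal_edge_rows(tr)) {
      side <- sort(labs[sets[[tr$edge[e, 2]]]])
      other <- sort(setdiff(labs, side))
      key <- if (paste(side, collapse = "|") < paste(other, collapse = "|")) {
        paste(side, collapse = "|")
      } else {
        paste(other, collapse = "|")
      }
      keys <- c(keys, key)
    }
    unique(keys)
  }
  s1 <- splits_of(t1); s2 <- splits_of(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Calibration study for SH-like aLRT support
#'
#' Simulates single-partition alignments on trees whose internal branches
#' are either (effectively) zero — the null the test addresses — or long,
#' then measures the SH-like supports on the generating topology with
#' re-optimized branch lengths. Under the null, supports should be low;
#' for well-supported branches with many sites they should saturate.
#'
#' @param n_replicates datasets per condition (default 10; with `n_taxa`
#'   = 8 each contributes 5 internal edges).
#' @param n_taxa taxa per dataset (default 8).
#' @param null_sites sites in the zero-branch condition (default 1000).
#' @param strong_sites sites in the long-branch condition (default 5000).
#' @param strong_branch internal branch length in the strong condition
#'   (default 0.5).
#' @param terminal_branch terminal branch length (default 0.2).
#' @param B RELL replicates (default 1000).
#' @param seed master seed.
#' @return list: `null_supports`, `strong_supports` (numeric vectors, one
#'   entry per internal edge per replicate).
#' @export
shl_calibration_study <- function(n_replicates = 10, n_taxa = 8,
                                  null_sites = 1000, strong_sites = 5000,
                                  strong_branch = 0.5, terminal_branch = 0.2,
                                  B = 1000, seed = 1) {
  mod <- gtr_model(alpha = 1)
  run_condition <- function(internal_len, nsites, offset) {
    sup <- numeric(0)
    for (r in seq_len(n_replicates)) {
      s <- derive_seed(seed, offset + r)
      set.seed(s)
      tree <- ape::unroot(ape::rtree(n_taxa, br = NULL))
      ntip <- ape::Ntip(tree)
      term <- tree$edge[, 2] <= ntip
      tree$edge.length <- ifelse(term, terminal_branch, internal_len)
      aln <- simulate_alignment(tree, mod, c(locus = as.integer(nsites)),
                                seed = s + 1)
      sm <- concatenate_genes(aln)
      fit <- suppressWarnings(
        optimize_branch_lengths(tree, sm, mod, tol = 0.05))
      ann <- annotate_support(fit, sm, mod, B = B, seed = s + 2)
      sup <- c(sup, attr(ann, "support_table")$shl)
    }
    sup
  }
  list(null_supports = run_condition(1e-8, null_sites, 1000),
       strong_supports = run_condition(strong_branch, strong_sites, 2000))
}

#' Null behavior of the completeness regression
#'
#' Assigns completeness values completely at random (MCAR) to the tips of
#' simulated trees and regresses the true terminal branch lengths on them.
#' Because the missingness carries no information about the tree, the
#' correlation should be near zero and the slope's test should reject at
#' the nominal rate.
#'
#' @param n_seeds number of replicates (default 100).
#' @param n_taxa tips per tree (default 100).
#' @param completeness_range range of the random completeness values
#'   (default `c(0.02, 0.9)`, spanning sparse-supermatrix practice).
#' @param seed master seed.
#' @return data.frame: `seed`, `r`, `p_value`.
#' @export
regression_null_study <- function(n_seeds = 100, n_taxa = 100,
                                  completeness_range = c(0.02, 0.9),
                                  seed = 1) {
  out <- data.frame(seed = integer(), r = numeric(), p_value = numeric())
  for (s in seq_len(n_seeds)) {
    tree <- simulate_tree(n_taxa, seed = derive_seed(seed, s))
    set.seed(derive_seed(seed, 10000 + s))
    comp <- setNames(runif(n_taxa, completeness_range[1],
                           completeness_range[2]), tree$tip.label)
    reg <- completeness_regression(tree, comp)
    out <- rbind(out, data.frame(seed = s, r = reg$r, p_value = reg$p_value))
  }
  out
}
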