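#' Per-taxon proportional completeness
#'
#' Non-missing base pairs divided by the full matrix length, per taxon.
#'
#' @param m a `supermatrix`.
#' @return named numeric vector in [0, 1].
#' @export
completeness <- function(m) {
  present_bp(m) / ncol(m$seq)
}

#' Regress terminal branch length on data completeness
#'
#' The standard missing-data diagnostic for sparse supermatrices: ordinary
#' least squares of each terminal branch's length on its taxon's
#' proportional completeness, with the Pearson correlation and its
#' two-sided t-test p-value. No relationship (r near 0) indicates that
#' terminal branch lengths are not systematically biased by missing data.
#'
#' @param tree a `phylo` with branch lengths; leaves must be matrix taxa.
#' @param m a `supermatrix`, or a named numeric vector of completeness
#'   values (names = taxa) for pre-computed input.
#' @return a data.frame (one row): `r`, `p_value`, `n`, `slope`,
#'   `intercept`.
#' @export
completeness_regression <- function(tree, m) {
  comp <- if (inherits(m, "supermatrix")) completeness(m) else m
  if (!all(tree$tip.label %in% names(comp))) {
    stop("tree leaf absent from completeness data")
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  ntip <- ape::Ntip(tree)
  term <- tree$edge[, 2] <= ntip
  tbl <- tree$edge.length[term]
  taxa <- tree$tip.label[tree$edge[term, 2]]
  x <- comp[taxa]
  if (length(x) < 3) stop("need >= 3 taxa")
  if (stats::sd(x) == 0) stop("degenerate regression: completeness is constant")
  fit <- lm(tbl ~ x)
  ct <- suppressWarnings(cor.test(x, tbl))
  cf <- stats::coef(fit)
  data.frame(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
             slope = unname(cf[2]), intercept = unname(cf[1]))
}

#' Summarize branch supports against a threshold
#'
#' Counts internal edges whose support exceeds (strictly, by default) a
#' threshold — the conventional "fraction of strongly supported nodes"
#' summary, with 85 as the strong-support convention for SH-like aLRT
#' values.
#'
#' @param tree a `phylo` with numeric supports in `node.label`.
#' @param threshold support threshold (default 85).
#' @param strict use `> threshold` (default); `FALSE` uses `>=`.
#' @return a data.frame: `n_internal_edges`, `n_with_support`, `n_above`,
#'   `threshold`, `fraction_above` (percent of edges with support values).
#' @export
support_summary <- function(tree, threshold = 85, strict = TRUE) {
  rows <- internal_edge_rows(tree)
  ntip <- ape::Ntip(tree)
  sup <- branch_supports(tree)[tree$edge[rows, 2] - ntip]
  sup <- sup[!is.na(sup)]
  if (length(sup) == 0) stop("tree has no internal-edge support values")
  above <- if (strict) sup > threshold else sup >= threshold
  data.frame(n_internal_edges = length(rows), n_with_support = length(sup),
             n_above = sum(above), threshold = threshold,
             fraction_above = 100 * mean(above))
}

#' Flag candidate rogue taxa
#'
#' Report-only screen for unstable, misplaced terminals: a tip is flagged
#' when the internal edge subtending its attachment point is weakly
#' supported (below `support_threshold`) AND the smallest enclosing clade
#' with at least `min_neighbors` family-labeled tips is majority a
#' different family than the tip's own. This is a reproducible proxy for
#' the manual screen of poorly supported, taxonomically suspect placements;
#' nothing is removed automatically.
#'
#' @param tree a support-annotated, rooted `phylo`.
#' @param taxonomy a `taxonomy_table` covering (at least some) tips.
#' @param support_threshold weak-support cutoff (default 50).
#' @param min_neighbors minimum labeled tips in the evaluated neighborhood.
#' @return data.frame: `taxon`, `attachment_support`, `own_family`,
#'   `neighborhood_family`, `reason` — one row per flagged tip.
#' @export
flag_rogues <- function(tree, taxonomy, support_threshold = 50,
                        min_neighbors = 5) {
  ntip <- ape::Ntip(tree)
  fam <- setNames(taxonomy$family, taxonomy$species)
  sup <- branch_supports(tree)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  tips_below <- node_tip_sets(tree)
  out <- data.frame(taxon = character(), attachment_support = numeric(),
                    own_family = character(), neighborhood_family = character(),
                    reason = character())
  for (tip in seq_len(ntip)) {
    own <- fam[tree$tip.label[tip]]
    if (is.na(own) || !nzchar(own)) next
    anc <- parent_of[tip]
    s <- sup[anc - ntip]
    if (is.na(s) || s >= support_threshold) next
    # climb to the smallest clade with enough family-labeled tips
    node <- anc
    repeat {
      labs <- fam[tree$tip.label[setdiff(tips_below[[node]], tip)]]
      labs <- labs[!is.na(labs) & nzchar(labs)]
      if (length(labs) >= min_neighbors || parent_of[node] == 0) break
      node <- parent_of[node]
    }
    if (length(labs) == 0) next
    tt <- sort(table(labs), decreasing = TRUE)
    major <- names(tt)[1]
    if (tt[1] > length(labs) / 2 && major != own) {
      out <- rbind(out, data.frame(
        taxon = tree$tip.label[tip], attachment_support = s,
        own_family = unname(own), neighborhood_family = major,
        reason = sprintf("support %.0f < %g and neighborhood is %s",
                         s, support_threshold, major)))
    }
  }
  out
}

# Tip indices below every node (tips included as themselves).
node_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}
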