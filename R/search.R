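#' The two nearest-neighbour-interchange rearrangements of an internal edge
#'
#' Every internal edge of a binary tree defines exactly two alternative
#' topologies, obtained by swapping one subtree from each side of the edge.
#' Branch lengths travel with their subtrees; the focal edge keeps its
#' length.
#'
#' @param tree a binary `phylo` (unrooted trees in the usual
#'   basal-trifurcation representation).
#' @param edge_row row index into `tree$edge` of an internal edge (both ends
#'   internal nodes).
#' @return list of two `phylo` objects.
#' @export
nni_alternatives <- function(tree, edge_row) {
  ntip <- ape::Ntip(tree)
  u <- tree$edge[edge_row, 1]
  v <- tree$edge[edge_row, 2]
  if (v <= ntip) stop("edge is terminal; NNI needs an internal edge")
  kids_v <- which(tree$edge[, 1] == v)
  if (length(kids_v) < 2) stop("node below the edge is not bifurcating")
  c_row <- kids_v[1]
  # partners on the far side of the edge: the other children of u
  sibs <- setdiff(which(tree$edge[, 1] == u), edge_row)
  if (length(sibs) == 0) stop("cannot NNI across the root edge")
  if (length(sibs) == 1) {
    # u is a plain internal node: swap sibling b with child c, then with d
    alts <- list(swap_subtrees(tree, sibs[1], kids_v[1]),
                 swap_subtrees(tree, sibs[1], kids_v[2]))
  } else {
    # u is the (trifurcating) root: the two distinct alternatives swap one
    # child of v with each of the two root-side subtrees
    alts <- list(swap_subtrees(tree, sibs[1], kids_v[1]),
                 swap_subtrees(tree, sibs[2], kids_v[1]))
  }
  alts
}

# As nni_alternatives(), but also report which pair of child nodes each
# rearrangement exchanges, so that node-disjoint swaps can be replayed on a
# later version of the tree.
nni_candidate_swaps <- function(tree, edge_row) {
  ntip <- ape::Ntip(tree)
  u <- tree$edge[edge_row, 1]
  v <- tree$edge[edge_row, 2]
  kids_v <- which(tree$edge[, 1] == v)
  sibs <- setdiff(which(tree$edge[, 1] == u), edge_row)
  pairs <- if (length(sibs) == 1) {
    list(c(sibs[1], kids_v[1]), c(sibs[1], kids_v[2]))
  } else {
    list(c(sibs[1], kids_v[1]), c(sibs[2], kids_v[1]))
  }
  lapply(pairs, function(p) {
    list(tree = swap_subtrees(tree, p[1], p[2]),
         swap = c(tree$edge[p[1], 2], tree$edge[p[2], 2]),
         nodes = c(u, v))
  })
}

# Copy the optimized lengths of the edges touching `nodes` from a donor
# tree (matched by child node id) into `tree`.
install_local_lengths <- function(tree, donor, nodes) {
  rows <- which(donor$edge[, 1] %in% nodes | donor$edge[, 2] %in% nodes)
  for (r in rows) {
    child <- donor$edge[r, 2]
    tr <- which(tree$edge[, 2] == child)
    if (length(tr) == 1) tree$edge.length[tr] <- donor$edge.length[r]
  }
  tree
}

# Exchange the subtrees hanging from two edge rows by swapping the rows'
# child entries (lengths follow the child).
swap_subtrees <- function(tree, row_a, row_b) {
  tmp <- tree$edge[row_a, 2]
  tree$edge[row_a, 2] <- tree$edge[row_b, 2]
  tree$edge[row_b, 2] <- tmp
  attr(tree, "order") <- NULL # force a genuine reorder of the edited edges
  ape::reorder.phylo(tree, "postorder")
}

internal_edge_rows <- function(tree) {
  ntip <- ape::Ntip(tree)
  which(tree$edge[, 1] > ntip & tree$edge[, 2] > ntip)
}

#' Nearest-neighbour-interchange hill climb
#'
#' Greedy NNI search: every internal edge's two rearrangements are evaluated
#' with local re-optimization of the branches incident to the edge; the best
#' strictly improving move is applied and the scan repeats until no edge
#' improves. A final full branch-length optimization (and optional model
#' re-optimization) polishes the returned tree.
#'
#' @param tree starting binary `phylo` with branch lengths.
#' @param m a `supermatrix` or [compile_matrix()] object.
#' @param pm a [partitioned_model()] or [gtr_model()].
#' @param max_iter maximum accepted moves (default 100).
#' @param final_model_opt re-optimize the model after the topology settles
#'   (default `FALSE`).
#' @param tol lnL improvement below which a move is not accepted
#'   (default 0.01 log units; gains below this are within the numerical
#'   tolerance of the branch-length sweeps).
#' @return list: `tree` (optimized), `lnL`, `model`, `n_moves`.
#' @export
nni_search <- function(tree, m, pm, max_iter = 100, final_model_opt = FALSE,
                       tol = 0.01) {
  lld <- compile_matrix(m)
  pm <- as_partitioned(pm, names(lld$parts))
  prep <- prepare_models(pm)
  if (ape::Ntip(tree) < 4) {
    tr <- optimize_branch_lengths(tree, lld, pm)
    return(list(tree = tr, lnL = attr(tr, "lnL"), model = pm, n_moves = 0L))
  }
  cur_tree <- ape::reorder.phylo(tree, "postorder")
  cur <- local_polish(cur_tree, NULL, lld, prep, sweeps = 3)
  cur_tree <- cur$tree
  cur_lnl <- cur$lnL
  n_moves <- 0L
  # Candidate evaluations are cached per internal edge (keyed by its two
  # node ids, which topology edits never renumber) and invalidated only in
  # the neighbourhood of an accepted swap, so each round re-scores just the
  # regions that changed. Every accepted swap is verified against the
  # advancing full-tree likelihood before being kept, and a stall triggers
  # one global branch-length refresh (with a cache flush) before giving up.
  cache <- list()
  refreshed <- FALSE
  repeat {
    if (n_moves >= max_iter) break
    for (e in internal_edge_rows(cur_tree)) {
      key <- paste(sort(cur_tree$edge[e, ]), collapse = "_")
      if (is.null(cache[[key]])) {
        cache[[key]] <- lapply(nni_candidate_swaps(cur_tree, e), function(cd) {
          # re-fit the five local branches; accepted swaps are re-verified
          # against the full-tree likelihood before being applied
          pol <- local_polish(cd$tree, cd$nodes, lld, prep, sweeps = 2,
                              brent_tol = 1e-2)
          cd$lnL <- pol$lnL
          cd$tree <- pol$tree
          cd
        })
      }
    }
    cand <- unlist(unname(cache), recursive = FALSE)
    lnls <- vapply(cand, `[[`, 0, "lnL")
    alive <- lnls > cur_lnl + tol
    applied <- 0L
    while (any(alive)) {
      ci <- which(alive)[which.max(lnls[alive])]
      alive[ci] <- FALSE
      cd <- cand[[ci]]
      rows <- match(cd$swap, cur_tree$edge[, 2])
      if (anyNA(rows) ||
          !all(cur_tree$edge[rows, 1] %in% cd$nodes)) next # stale entry
      trial <- swap_subtrees(cur_tree, rows[1], rows[2])
      trial <- install_local_lengths(trial, cd$tree, cd$nodes)
      trial_lnl <- lnl_eval(postorder_info(trial), lld, prep)$lnL
      if (trial_lnl > cur_lnl + tol) {
        cur_tree <- trial
        cur_lnl <- trial_lnl
        applied <- applied + 1L
        n_moves <- n_moves + 1L
        refreshed <- FALSE
        # invalidate cached evaluations whose edge touches this quartet
        local_rows <- which(cd$tree$edge[, 1] %in% cd$nodes |
                              cd$tree$edge[, 2] %in% cd$nodes)
        zone <- unique(as.vector(cd$tree$edge[local_rows, ]))
        for (key in names(cache)) {
          uv <- as.integer(strsplit(key, "_")[[1]])
          if (any(uv %in% zone)) cache[[key]] <- NULL
        }
        overlap <- vapply(cand, function(x) any(x$nodes %in% zone), TRUE)
        alive[overlap] <- FALSE
      }
    }
    if (applied == 0L) {
      if (refreshed) break
      full <- local_polish(cur_tree, NULL, lld, prep, sweeps = 3)
      gain <- full$lnL - cur_lnl
      cur_tree <- full$tree
      cur_lnl <- max(cur_lnl, full$lnL)
      refreshed <- TRUE
      if (gain > 0.5) cache <- list() else break # rescan only if lengths moved
    }
  }
  out_tree <- optimize_branch_lengths(cur_tree, lld, pm, tol = 0.01)
  out_lnl <- attr(out_tree, "lnL")
  if (final_model_opt) {
    mo <- optimize_model(out_tree, lld, pm, rounds = 1)
    pm <- mo$model
    out_tree <- optimize_branch_lengths(mo$tree, lld, pm, tol = 0.01)
    out_lnl <- attr(out_tree, "lnL")
  }
  list(tree = out_tree, lnL = out_lnl, model = pm, n_moves = n_moves)
}

focal_nodes <- function(tree, edge_row) {
  tree$edge[edge_row, ]
}

# Re-optimize a small set of branches (those touching the focal nodes), or
# every branch when nodes is NULL, with a cheap single-pass sweep.
local_polish <- function(tree, nodes, lld, prep, sweeps = 1,
                         focal_only = FALSE, reset = FALSE, tol = 0.05,
                         brent_tol = 5e-3) {
  info <- postorder_info(tree)
  edges <- if (is.null(nodes)) {
    seq_len(nrow(info$edge))
  } else if (focal_only) {
    which(info$edge[, 1] %in% nodes & info$edge[, 2] %in% nodes)
  } else {
    which(info$edge[, 1] %in% nodes | info$edge[, 2] %in% nodes)
  }
  # after a topology change the inherited local lengths can be degenerate
  # (e.g. pinned at the lower bound); optionally restart them neutrally
  if (reset) info$brlen[edges] <- pmax(info$brlen[edges], 0.05)
  res <- brlen_sweeps(info, lld, prep, tol = tol, max_sweeps = sweeps,
                      brent_tol = brent_tol, edges = edges, warn = FALSE)
  tree$edge.length <- res$brlen
  list(tree = tree, lnL = res$lnL)
}

#' Maximum-likelihood search from multiple parsimony starts
#'
#' The standard search protocol for sparse supermatrices: `n_starts` seeded
#' random-addition parsimony starting trees, each NNI-optimized under the
#' partitioned GTR+Gamma model; the best final log-likelihood wins (ties go
#' to the earliest start). The model is optimized once on the first starting
#' tree and reused across starts, then re-optimized on the winning topology.
#'
#' @param m a `supermatrix` or [compile_matrix()] object.
#' @param pm optional starting [partitioned_model()]; default builds one
#'   GTR+Gamma model per partition from the data.
#' @param n_starts number of parsimony starting trees (default 11).
#' @param seed master seed; start `i` uses `derive_seed(seed, i)`.
#' @param optimize_model_first estimate model parameters on the first start
#'   (default `TRUE`).
#' @return list: `tree`, `lnL`, `model`, `per_start` (data.frame of seed,
#'   start and final lnL).
#' @export
ml_search <- function(m, pm = NULL, n_starts = 11, seed = 1,
                      optimize_model_first = TRUE) {
  lld <- compile_matrix(m)
  if (is.null(pm)) pm <- partitioned_model(gtr_model(alpha = 0.5),
                                           names(lld$parts))
  pm <- as_partitioned(pm, names(lld$parts))
  starts <- list()
  topo_keys <- character(0)
  for (i in seq_len(n_starts)) {
    st <- stepwise_addition_tree(lld, derive_seed(seed, i))
    st$edge.length <- rep(0.05, nrow(st$edge))
    key <- topology_key(st)
    if (!key %in% topo_keys) { # identical starts would repeat identical work
      starts[[length(starts) + 1L]] <- list(seed_index = i, tree = st)
      topo_keys <- c(topo_keys, key)
    }
  }
  if (optimize_model_first) {
    bl <- optimize_branch_lengths(starts[[1]]$tree, lld, pm, tol = 0.1)
    mo <- optimize_model(bl, lld, pm, rounds = 1)
    pm <- mo$model
  }
  per_start <- data.frame(seed_index = integer(), start_lnL = numeric(),
                          final_lnL = numeric())
  best <- NULL
  prep <- prepare_models(pm)
  for (s in starts) {
    start_lnl <- lnl_eval(postorder_info(s$tree), lld, prep)$lnL
    res <- nni_search(s$tree, lld, pm)
    per_start <- rbind(per_start,
                       data.frame(seed_index = s$seed_index,
                                  start_lnL = start_lnl,
                                  final_lnL = res$lnL))
    if (is.null(best) || res$lnL > best$lnL + 1e-9) best <- res
  }
  mo <- optimize_model(best$tree, lld, best$model, rounds = 1)
  final_tree <- optimize_branch_lengths(mo$tree, lld, mo$model, tol = 0.01)
  list(tree = final_tree, lnL = attr(final_tree, "lnL"), model = mo$model,
       per_start = per_start)
}

# Topology fingerprint ignoring branch lengths.
topology_key <- function(tree) {
  t2 <- tree
  t2$edge.length <- NULL
  t2$node.label <- NULL
  canonical_newick(t2)
}
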