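#' Fitch parsimony score
#'
#' Minimum number of unordered state changes required by a tree, summed over
#' sites (with pattern weights). Missing states are wildcards.
#'
#' @param tree a `phylo` (branch lengths ignored).
#' @param m a `supermatrix`, a [compile_matrix()] object, or a named
#'   character vector giving a single column (names = taxa).
#' @return integer parsimony length.
#' @export
fitch_score <- function(tree, m) {
  if (is.character(m) && !is.null(names(m))) {
    taxa <- names(m)
    codes <- match(toupper(m), DNA_STATES)
    codes[is.na(codes)] <- 5L
    masks <- matrix(fitch_mask(codes - 1L), ncol = 1,
                    dimnames = list(taxa, NULL))
    weights <- 1
  } else {
    lld <- compile_matrix(m)
    taxa <- lld$taxa
    masks <- do.call(cbind, lapply(lld$parts, function(p)
      matrix(fitch_mask(p$states), nrow = nrow(p$states))))
    weights <- unlist(lapply(lld$parts, function(p) p$weights), use.names = FALSE)
  }
  if (!all(tree$tip.label %in% taxa)) stop("tree leaf absent from matrix")
  info <- postorder_info(tree)
  out <- .cpp_fitch(info$edge, info$ntip, info$nnode,
                    masks[match(info$tips, taxa), , drop = FALSE], weights)
  as.integer(round(out$score))
}

fitch_mask <- function(codes) {
  ifelse(codes >= 4L, 15L, bitwShiftL(1L, codes))
}

#' Random-addition parsimony starting tree
#'
#' Builds a starting tree by seeded random stepwise addition: taxa are added
#' in a random order, each on the edge that minimizes the total Fitch
#' parsimony length of the growing tree (ties broken by the first edge in a
#' deterministic traversal). This is the conventional way of generating the
#' independent starting points for multiple maximum-likelihood searches.
#'
#' @param m a `supermatrix` or [compile_matrix()] object with >= 3 taxa.
#' @param seed integer seed controlling the addition order.
#' @return an unrooted binary `phylo` (basal trifurcation, no branch
#'   lengths).
#' @export
stepwise_addition_tree <- function(m, seed) {
  lld <- compile_matrix(m)
  taxa <- lld$taxa
  n <- length(taxa)
  if (n < 3) stop("stepwise addition needs >= 3 taxa")
  masks <- do.call(cbind, lapply(lld$parts, function(p)
    matrix(fitch_mask(p$states), nrow = nrow(p$states))))
  weights <- unlist(lapply(lld$parts, function(p) p$weights), use.names = FALSE)
  set.seed(seed)
  ord <- sample.int(n)

  # edges over ids: tips are 1..n (taxon index), internal ids n+1, n+2, ...
  root <- n + 1L
  nxt <- n + 2L
  edges <- rbind(c(root, ord[1]), c(root, ord[2]), c(root, ord[3]))
  score_of <- function(ed) {
    po <- postorder_edges(ed, root, n)
    out <- .cpp_fitch(po$edge, po$ntip, po$nnode,
                      masks[po$tip_ids, , drop = FALSE], weights)
    out$score
  }
  for (k in seq(4, length.out = max(0, n - 3))) {
    tip <- ord[k]
    best <- NULL; best_score <- Inf
    for (e in seq_len(nrow(edges))) {
      cand <- rbind(edges[-e, , drop = FALSE],
                    c(edges[e, 1], nxt), c(nxt, edges[e, 2]), c(nxt, tip))
      sc <- score_of(cand)
      if (sc < best_score) { best_score <- sc; best <- cand }
    }
    edges <- best
    nxt <- nxt + 1L
  }
  structure_to_phylo(edges, root, taxa)
}

# Relabel an id-based edge list into ape/postorder form. Tips keep their
# taxon index as row lookup; internal ids are renumbered in the order they
# close during an iterative DFS.
postorder_edges <- function(edges, root, n_total_taxa) {
  ids <- unique(as.vector(edges))
  tip_ids <- sort(ids[ids <= n_total_taxa])
  ntip <- length(tip_ids)
  children <- split(edges[, 2], edges[, 1])
  new_id <- integer(max(ids))
  new_id[tip_ids] <- seq_len(ntip)
  rankv <- integer(max(ids))
  cnt_node <- ntip
  seqno <- 0L
  # iterative DFS; nodes are numbered / ranked in closing (postorder) order
  st_node <- c(root); st_ptr <- c(0L)
  while (length(st_node)) {
    i <- length(st_node)
    node <- st_node[i]
    kids <- children[[as.character(node)]]
    ptr <- st_ptr[i] + 1L
    if (is.null(kids) || ptr > length(kids)) {
      seqno <- seqno + 1L
      rankv[node] <- seqno
      if (node > n_total_taxa) {
        cnt_node <- cnt_node + 1L
        new_id[node] <- cnt_node
      }
      st_node <- st_node[-i]; st_ptr <- st_ptr[-i]
    } else {
      st_ptr[i] <- ptr
      st_node <- c(st_node, kids[ptr]); st_ptr <- c(st_ptr, 0L)
    }
  }
  ord <- order(rankv[edges[, 2]])
  po <- cbind(new_id[edges[ord, 1]], new_id[edges[ord, 2]])
  list(edge = po, ntip = ntip, nnode = cnt_node, tip_ids = tip_ids)
}

structure_to_phylo <- function(edges, root, taxa) {
  children <- split(edges[, 2], edges[, 1])
  n <- length(taxa)
  build <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) return(taxa[node])
    paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(root), ";"))
}
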