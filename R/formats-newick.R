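#' Read a Newick tree with optional branch supports
#'
#' Parses a Newick file into an [ape::read.tree()] `phylo` object. Internal
#' node labels that are numeric are interpreted as branch support values for
#' the edge subtending the node (the PhyML/RAxML dialect). Supports are kept
#' on the 0-100 scale; `support_scale = "unit"` declares that the file stores
#' them in [0, 1] and rescales.
#'
#' @param path path to a Newick file (or a Newick string ending in `;`).
#' @param support_scale `"percent"` (default) or `"unit"`.
#' @return a `phylo` object; numeric supports live in `node.label`.
#' @export
read_newick <- function(path, support_scale = c("percent", "unit")) {
  support_scale <- match.arg(support_scale)
  text <- if (file.exists(path)) paste(readLines(path, warn = FALSE), collapse = "") else path
  check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick input")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (!is.null(tree$node.label) && support_scale == "unit") {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label <- ifelse(is.na(sup), tree$node.label,
                              format(100 * sup, trim = TRUE))
  }
  tree
}

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced '(': ", depth, " unclosed at end of input")
  invisible(TRUE)
}

#' Extract per-internal-edge support values
#'
#' @param tree a `phylo` with numeric internal node labels.
#' @return numeric vector indexed by internal node number minus `Ntip(tree)`;
#'   `NA` where absent. The root entry is always `NA` (no subtending edge).
#' @export
branch_supports <- function(tree) {
  n_int <- tree$Nnode
  sup <- rep(NA_real_, n_int)
  if (!is.null(tree$node.label)) {
    val <- suppressWarnings(as.numeric(tree$node.label))
    sup[seq_along(val)] <- val
  }
  root <- ape::Ntip(tree) + 1L
  sup[root - ape::Ntip(tree)] <- NA_real_
  sup
}

#' Write a tree to Newick, branch lengths at fixed precision
#'
#' @param tree a `phylo` object (supports, if any, in `node.label`).
#' @param path output path; if `NULL` the Newick string is returned.
#' @param digits branch-length decimals (default 6).
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, digits)
  }
  txt <- ape::write.tree(tree, digits = digits + 1)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Canonical Newick form of a tree
#'
#' Rotates every internal node so that children are ordered by their smallest
#' descendant tip label (lexicographic), then writes branch lengths with fixed
#' precision. Two trees with the same topology, lengths and supports produce
#' byte-identical canonical strings, which makes round-trip and determinism
#' checks exact.
#'
#' @inheritParams write_newick
#' @return a Newick string.
#' @export
canonical_newick <- function(tree, digits = 6) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  minlab <- character(nnode)
  minlab[seq_len(ntip)] <- tree$tip.label
  children <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    children[[p]] <- c(children[[p]], ch)
    lab <- minlab[ch]
    if (!nzchar(minlab[p]) || lab < minlab[p]) minlab[p] <- lab
  }
  # minlab is filled bottom-up because edges are postordered
  for (p in (ntip + 1L):nnode) {
    kids <- children[[p]]
    if (!is.null(kids)) {
      children[[p]] <- kids[order(minlab[kids], method = "radix")]
    }
  }
  brlen <- numeric(nnode)
  if (!is.null(tree$edge.length)) {
    brlen[tree$edge[, 2]] <- tree$edge.length
  }
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) rep("", tree$Nnode) else tree$node.label)
  fmt_len <- function(x) {
    if (is.null(tree$edge.length)) "" else paste0(":", formatC(x, digits = digits, format = "f"))
  }
  build <- function(node, is_root) {
    if (node <= ntip) {
      paste0(labels[node], if (!is_root) fmt_len(brlen[node]))
    } else {
      inner <- paste(vapply(children[[node]], build, "", is_root = FALSE),
                     collapse = ",")
      paste0("(", inner, ")", labels[node], if (!is_root) fmt_len(brlen[node]))
    }
  }
  root <- ntip + 1L
  paste0(build(root, TRUE), ";")
}
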