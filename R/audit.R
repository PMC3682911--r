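#' Classify a tip set as mono-, para- or polyphyletic
#'
#' On a rooted tree, computes the most recent common ancestor of the tip set
#' `S`, the number of maximal S-pure clades, and the intruder tips inside
#' the MRCA clade. `S` is monophyletic when it forms one clade; otherwise it
#' is paraphyletic when the intruders themselves form exactly one clade
#' within the MRCA (a single nested lineage), and polyphyletic when the
#' intruders are scattered.
#'
#' @param tree a rooted `phylo` (root the tree on its outgroup first for
#'   taxonomically meaningful calls).
#' @param tips character vector of tip labels (the sampled members of the
#'   taxon), length >= 1.
#' @return a list of class `monophyly_report`: `status` (one of
#'   `"monophyletic"`, `"paraphyletic"`, `"polyphyletic"`, `"trivial"`),
#'   `n_sampled_tips`, `k_maximal_clades`, `intruders` (character),
#'   `mrca` (node id or `NA` for trivial sets).
#' @export
classify_taxon <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  idx <- match(tips, tree$tip.label)
  if (length(idx) < 2) {
    return(structure(list(status = "trivial", n_sampled_tips = length(idx),
                          k_maximal_clades = 1L, intruders = character(0),
                          mrca = NA_integer_), class = "monophyly_report"))
  }
  ntip <- ape::Ntip(tree)
  sets <- node_tip_sets(tree)
  mrca <- ape::getMRCA(tree, idx)
  clade <- sets[[mrca]]
  intruders_idx <- setdiff(clade, idx)
  k <- count_pure_clades(tree, idx, sets)
  status <- if (k == 1) {
    "monophyletic"
  } else if (length(intruders_idx) &&
             is_single_clade(tree, intruders_idx, sets)) {
    "paraphyletic"
  } else {
    "polyphyletic"
  }
  structure(list(status = status, n_sampled_tips = length(idx),
                 k_maximal_clades = k,
                 intruders = tree$tip.label[intruders_idx], mrca = mrca),
            class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat(sprintf("%s (%d tips, %d maximal clades, %d intruders)\n", x$status,
              x$n_sampled_tips, x$k_maximal_clades, length(x$intruders)))
  invisible(x)
}

# Number of maximal clades whose tips are all in S.
count_pure_clades <- function(tree, idx, sets = node_tip_sets(tree)) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  pure <- vapply(seq_len(nnode), function(nd) all(sets[[nd]] %in% idx), TRUE)
  parent_of <- integer(nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  # a pure clade only ever contains members of S; count the maximal ones
  sum(pure & (parent_of == 0 | !pure[pmax(parent_of, 1)]))
}

is_single_clade <- function(tree, idx, sets = node_tip_sets(tree)) {
  if (length(idx) == 1) return(TRUE)
  mrca <- ape::getMRCA(tree, idx)
  setequal(sets[[mrca]], idx)
}

#' Maximum support among edges conflicting with a taxon's monophyly
#'
#' An internal edge conflicts with the monophyly of tip set `S` when its
#' bipartition groups a proper, non-empty subset of `S` together with at
#' least one non-member, against the rest of `S`. Returns the maximum
#' support value among conflicting edges, or `NA` if none of them carries a
#' support value.
#'
#' @param tree a support-annotated `phylo`.
#' @param tips tip labels of a non-monophyletic taxon.
#' @return a single numeric value (or `NA`).
#' @export
conflict_support <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tip label(s)")
  sets <- node_tip_sets(tree)
  rep_status <- classify_taxon(tree, tips)
  if (rep_status$status == "monophyletic") {
    stop("taxon is monophyletic; no conflicting edges")
  }
  ntip <- ape::Ntip(tree)
  sup <- branch_supports(tree)
  best <- NA_real_
  for (e in internal_edge_rows(tree)) {
    child <- tree$edge[e, 2]
    side <- sets[[child]]
    in_s <- sum(side %in% idx)
    if (in_s > 0 && in_s < length(idx) && length(side) > in_s) {
      s <- sup[child - ntip]
      if (!is.na(s) && (is.na(best) || s > best)) best <- s
    }
  }
  best
}

#' Audit a classification against a tree
#'
#' Classifies every named taxon at every rank (genus, subfamily, family by
#' default) as monophyletic / paraphyletic / polyphyletic / trivial on the
#' tree, records intruders and the maximum support among conflicting edges,
#' and flags strongly supported conflicts (max conflict support >=
#' `threshold`, the SH-like strong-support convention). Tips that cannot be
#' matched to the taxonomy are reported and excluded.
#'
#' @param tree a rooted, optionally support-annotated `phylo`.
#' @param taxonomy a `taxonomy_table`.
#' @param threshold strong-conflict support threshold (default 85).
#' @param ranks character vector of taxonomy columns to audit.
#' @return a data.frame (one row per taxon x rank): `taxon`, `rank`,
#'   `status`, `n_tips`, `k_clades`, `n_intruders`, `max_conflict_support`,
#'   `strongly_supported_conflict`; unmatched tips in
#'   `attr(, "unmatched_tips")`.
#' @export
audit_classification <- function(tree, taxonomy, threshold = 85,
                                 ranks = c("genus", "subfamily", "family")) {
  matched <- tree$tip.label %in% taxonomy$species
  unmatched <- tree$tip.label[!matched]
  out <- data.frame(taxon = character(), rank = character(),
                    status = character(), n_tips = integer(),
                    k_clades = integer(), n_intruders = integer(),
                    max_conflict_support = numeric(),
                    strongly_supported_conflict = logical())
  for (rank in ranks) {
    vals <- taxonomy[[rank]]
    names(vals) <- taxonomy$species
    groups <- split(taxonomy$species, vals)
    groups <- groups[nzchar(names(groups))]
    for (taxon in names(groups)) {
      tips <- intersect(groups[[taxon]], tree$tip.label)
      if (length(tips) == 0) next
      rp <- classify_taxon(tree, tips)
      mcs <- NA_real_
      if (!rp$status %in% c("monophyletic", "trivial")) {
        mcs <- conflict_support(tree, tips)
      }
      out <- rbind(out, data.frame(
        taxon = taxon, rank = rank, status = rp$status,
        n_tips = rp$n_sampled_tips, k_clades = rp$k_maximal_clades,
        n_intruders = length(rp$intruders), max_conflict_support = mcs,
        strongly_supported_conflict = !is.na(mcs) && mcs >= threshold))
    }
  }
  attr(out, "unmatched_tips") <- unmatched
  out
}
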