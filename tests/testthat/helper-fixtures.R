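# Shared fixtures and independent oracles for the test suite.

# Build a supermatrix directly from named residue strings and a partition map.
make_sm <- function(rows, partitions = NULL) {
  m <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(m) <- names(rows)
  if (is.null(partitions)) {
    partitions <- data.frame(gene = "g1", start = 1L, end = ncol(m))
  }
  sparsephy:::new_supermatrix(m, partitions)
}

# Brute-force tree likelihood: sum over all internal-node state assignments.
# Entirely independent of the pruning implementation.
brute_force_lnl <- function(tree, sm, model) {
  stopifnot(inherits(model, "gtr_model"))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  cat_rates <- gamma_rates(model$alpha, model$k) * model$rate_mult
  seqs <- sm$seq[tr$tip.label, , drop = FALSE]
  states <- match(seqs, c("A", "C", "G", "T")) # NA = missing
  dim(states) <- dim(seqs)
  root <- tr$edge[nrow(tr$edge), 1]
  internal <- sort(unique(tr$edge[, 1]))
  total <- 0
  for (site in seq_len(ncol(seqs))) {
    site_lik <- 0
    for (r in cat_rates) {
      P <- list()
      for (e in seq_len(nrow(tr$edge))) {
        P[[e]] <- transition_probabilities(model, tr$edge.length[e], r)
      }
      lik <- 0
      grid <- expand.grid(rep(list(1:4), length(internal)))
      for (gi in seq_len(nrow(grid))) {
        assign_state <- integer(nnode)
        assign_state[internal] <- as.integer(grid[gi, ])
        assign_state[seq_len(ntip)] <- states[, site]
        p <- model$pi[assign_state[root]]
        ok <- TRUE
        for (e in seq_len(nrow(tr$edge))) {
          a <- assign_state[tr$edge[e, 1]]
          b <- assign_state[tr$edge[e, 2]]
          if (is.na(b)) next # missing tip: sums over its states to 1
          p <- p * P[[e]][a, b]
        }
        lik <- lik + p
      }
      site_lik <- site_lik + lik / length(cat_rates)
    }
    total <- total + log(site_lik)
  }
  as.numeric(total)
}

# Brute-force global affine alignment score by enumerating all alignments.
brute_force_align_score <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  S <- scheme$matrix
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  best <- -Inf
  # state: 0 none, 1 gap-in-b, 2 gap-in-a (for affine run accounting)
  rec <- function(i, j, score, state) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (score + 50 * (length(A) + length(B)) < best) return(invisible())
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1, j + 1, score + S[A[i], B[j]], 0)
    }
    if (i <= length(A)) {
      cost <- if (state == 1) ge else go + ge
      rec(i + 1, j, score - cost, 1)
    }
    if (j <= length(B)) {
      cost <- if (state == 2) ge else go + ge
      rec(i, j + 1, score - cost, 2)
    }
  }
  rec(1, 1, 0, 0)
  best
}

# Brute-force Fitch length: minimize changes over all internal labelings.
brute_force_fitch <- function(tree, column) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  states <- match(toupper(column[tr$tip.label]), c("A", "C", "G", "T"))
  internal <- sort(unique(tr$edge[, 1]))
  grid <- expand.grid(rep(list(1:4), length(internal)))
  best <- Inf
  for (gi in seq_len(nrow(grid))) {
    assign_state <- integer(nnode)
    assign_state[internal] <- as.integer(grid[gi, ])
    changes <- 0
    for (e in seq_len(nrow(tr$edge))) {
      a <- assign_state[tr$edge[e, 1]]
      child <- tr$edge[e, 2]
      b <- if (child <= ntip) states[child] else assign_state[child]
      if (is.na(b)) next
      if (a != b) changes <- changes + 1
    }
    best <- min(best, changes)
  }
  best
}

# A small aligned gene set (3 taxa x 2 genes) used across assembly tests.
tiny_gene_set <- function() {
  list(
    gA = make_records(c(Aus_bus = "ACGTACGT", Aus_cus = "ACGTACGA",
                        Bus_dus = "ACGTTCGA"), "gA"),
    gB = make_records(c(Aus_bus = "TTTT", Bus_dus = "TTAT"), "gB"))
}

make_records <- function(x, gene) sequence_records(names(x), unname(x), gene)

random_resolved_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr
}
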