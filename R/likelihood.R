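#' Precompile a supermatrix for likelihood evaluation
#'
#' Compresses every partition into its unique site patterns with counts
#' (pattern compression), coding states A, C, G, T as 0-3 and everything else
#' (gaps, `?`, `N`, ambiguity codes) as fully missing. The returned object
#' can be passed wherever a `supermatrix` is accepted by the likelihood,
#' parsimony and support functions, and caches work shared by the thousands
#' of evaluations a tree search performs.
#'
#' @param m a `supermatrix`.
#' @param genes optional subset of partitions.
#' @return an object of class `ll_data`.
#' @export
compile_matrix <- function(m, genes = NULL) {
  if (inherits(m, "ll_data")) return(m)
  stopifnot(inherits(m, "supermatrix"))
  genes <- genes %||% m$partitions$gene
  taxa <- rownames(m$seq)
  parts <- list()
  for (g in genes) {
    sub <- partition_columns(m, g)
    codes <- match(toupper(sub), DNA_STATES)
    codes[is.na(codes)] <- 5L
    codes <- matrix(codes - 1L, nrow = nrow(sub)) # 0..3, 4 = missing
    key <- vapply(seq_len(ncol(codes)), function(j)
      paste(codes[, j], collapse = ""), "")
    first <- !duplicated(key)
    pat_of_site <- match(key, key[first])
    pat <- codes[, first, drop = FALSE]
    w <- as.numeric(tabulate(pat_of_site, nbins = sum(first)))
    parts[[g]] <- list(states = pat, weights = w, site_pattern = pat_of_site,
                       nsites = ncol(codes))
  }
  structure(list(taxa = taxa, parts = parts), class = "ll_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Postorder edge representation shared by likelihood and parsimony.
postorder_info <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, brlen = tr$edge.length, tips = tr$tip.label,
       ntip = length(tr$tip.label), nnode = length(tr$tip.label) + tr$Nnode)
}

as_partitioned <- function(pm, genes) {
  if (inherits(pm, "gtr_model")) return(partitioned_model(pm, genes))
  stopifnot(inherits(pm, "partitioned_model"), all(genes %in% names(pm)))
  pm
}

# Precompute eigensystems and category rates for every partition.
prepare_models <- function(pm) {
  lapply(pm, function(mod) {
    es <- gtr_eigen(mod)
    list(pi = as.numeric(mod$pi), V = es$V, Vinv = es$Vinv, lambda = es$lambda,
         rates = gamma_rates(mod$alpha, mod$k) * mod$rate_mult)
  })
}

#' Partitioned GTR+Gamma log-likelihood of a tree
#'
#' Felsenstein pruning over compressed site patterns, mixing over the
#' discrete gamma categories with equal weights; partition log-likelihoods
#' are summed under a shared set of branch lengths. Missing cells contribute
#' a flat partial likelihood, so an all-missing column adds exactly zero.
#'
#' @param tree a `phylo` with branch lengths; its tips must be a subset of
#'   the matrix taxa.
#' @param m a `supermatrix` or precompiled [compile_matrix()] object.
#' @param pm a [partitioned_model()] whose names match the partitions.
#' @return a list: `lnL` (total), `site_lnl` (named list of per-site
#'   log-likelihood vectors per partition, in matrix column order), and
#'   `per_partition` (named totals).
#' @export
tree_log_likelihood <- function(tree, m, pm) {
  lld <- compile_matrix(m)
  if (!all(tree$tip.label %in% lld$taxa)) {
    stop("tree leaf absent from matrix: ",
         paste(setdiff(tree$tip.label, lld$taxa), collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  info <- postorder_info(tree)
  pm <- as_partitioned(pm, names(lld$parts))
  prep <- prepare_models(pm)
  res <- lnl_eval(info, lld, prep, want_sites = TRUE)
  list(lnL = res$lnL, site_lnl = res$site_lnl, per_partition = res$per_partition)
}

# Core evaluation. info: postorder_info(); lld: ll_data; prep: prepare_models().
lnl_eval <- function(info, lld, prep, want_sites = FALSE) {
  row_idx <- match(info$tips, lld$taxa)
  total <- 0
  per_part <- numeric(0)
  site_lnl <- if (want_sites) list() else NULL
  for (g in names(lld$parts)) {
    p <- lld$parts[[g]]
    mp <- prep[[g]]
    out <- .cpp_pruning_lnl(info$edge, info$brlen, info$ntip, info$nnode,
                            p$states[row_idx, , drop = FALSE], p$weights,
                            mp$pi, mp$V, mp$Vinv, mp$lambda, mp$rates)
    total <- total + out$lnL
    per_part[g] <- out$lnL
    if (want_sites) site_lnl[[g]] <- out$site_lnl[p$site_pattern]
  }
  list(lnL = total, per_partition = per_part, site_lnl = site_lnl)
}
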