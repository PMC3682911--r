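#' Reference per-gene conditions of the emulated squamate supermatrix
#'
#' The per-gene summary of the 12-gene, 4162-taxon squamate supermatrix
#' whose structure the synthetic-data generator emulates: alignment length,
#' number of covered species, gene role (mitochondrial vs nuclear; the
#' well-sampled nuclear loci form the "scaffold"), and the implied coverage
#' fraction.
#'
#' @return data.frame: `gene`, `role`, `length_bp`, `n_species`,
#'   `coverage` (fraction of the 4162 taxa with the gene).
#' @export
squamate_gene_table <- function() {
  tab <- data.frame(
    gene = c("12S", "16S", "BDNF", "cmos", "cytb", "NT3",
             "ND2", "ND4", "PDC", "R35", "RAG1", "RAG2"),
    role = c("mito", "mito", "nuclear", "nuclear", "mito", "nuclear",
             "mito", "mito", "nuclear", "nuclear", "nuclear", "nuclear"),
    length_bp = c(1395L, 1970L, 714L, 903L, 1000L, 675L,
                  960L, 696L, 395L, 768L, 2700L, 720L),
    n_species = c(2335L, 2377L, 730L, 1671L, 1985L, 437L,
                  1860L, 1556L, 393L, 401L, 1379L, 471L),
    stringsAsFactors = FALSE)
  tab$coverage <- tab$n_species / 4162
  tab
}

#' Simulation configuration for paper-style sparse supermatrices
#'
#' Bundles the knobs of the synthetic-data generator. Defaults emulate the
#' reference squamate matrix: 12 gene partitions with the published lengths
#' and coverage fractions (about 81% missing cells overall), a nuclear
#' scaffold of well-sampled taxa, and mitochondrial partitions evolving
#' faster than nuclear ones.
#'
#' @param n_taxa number of species to simulate.
#' @param birth_rate Yule speciation rate.
#' @param tree_depth root-to-tip depth in expected substitutions per site
#'   (the simulated tree is rescaled to it; default 0.5).
#' @param genes data.frame with `gene`, `role`, `length_bp`, `coverage`
#'   columns (default [squamate_gene_table()]).
#' @param length_scale multiplier applied to gene lengths (default 1).
#' @param models a [partitioned_model()] over the genes, or `NULL` for the
#'   default: GTR+Gamma with alpha 0.5 and rate multiplier 2 for
#'   mitochondrial vs 1 for nuclear partitions (renormalized to mean 1).
#' @param scaffold_fraction fraction of taxa complete for all scaffold
#'   (nuclear) genes; the scaffold is carved out of, not added on top of,
#'   each gene's nominal coverage (default 0.08).
#' @param min_total_bp minimum total data per retained taxon (default 250).
#' @param fragment_range range of the contiguous fraction a retained
#'   non-scaffold gene keeps. The default `c(0.26, 0.66)` (mean 0.46)
#'   reproduces the reference matrix's ~81% overall missingness together
#'   with the per-gene coverage fractions; `c(1, 1)` keeps whole genes.
#' @param seed master seed (mandatory).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 64, birth_rate = 1, tree_depth = 0.5,
                              genes = squamate_gene_table(), length_scale = 1,
                              models = NULL, scaffold_fraction = 0.08,
                              min_total_bp = 250,
                              fragment_range = c(0.26, 0.66), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(c("gene", "role", "length_bp", "coverage") %in% names(genes)),
            all(genes$coverage > 0), all(genes$coverage <= 1),
            all(genes$length_bp > 0))
  genes$length_bp <- as.integer(round(genes$length_bp * length_scale))
  if (is.null(models)) {
    mods <- lapply(genes$role, function(r)
      gtr_model(pi = c(0.30, 0.25, 0.15, 0.30),
                rates = c(2, 8, 1.5, 1, 12, 1), alpha = 0.5,
                rate_mult = if (r == "mito") 2 else 1))
    models <- partitioned_model(setNames(mods, genes$gene), genes$gene)
  }
  structure(list(n_taxa = n_taxa, birth_rate = birth_rate,
                 tree_depth = tree_depth, genes = genes, models = models,
                 scaffold_fraction = scaffold_fraction,
                 min_total_bp = min_total_bp, fragment_range = fragment_range,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate an ultrametric Yule tree
#'
#' @param n number of leaves (>= 3).
#' @param birth_rate speciation rate.
#' @param seed integer seed.
#' @param depth optional root-to-tip depth to rescale to.
#' @return a rooted ultrametric `phylo` with leaves `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n, birth_rate = 1, seed = 1, depth = NULL) {
  if (n < 3) stop("need >= 3 leaves")
  set.seed(seed)
  tree <- ape::rphylo(n, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  if (!is.null(depth)) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * depth / h
  }
  tree
}

#' Simulate per-gene alignments on a tree
#'
#' Sites evolve independently under each partition's GTR+Gamma model: root
#' states are drawn from the stationary frequencies and propagated along
#' branches with the model's transition probabilities, each site carrying a
#' gamma rate-category (times the partition multiplier).
#'
#' @param tree a `phylo` with branch lengths.
#' @param pm a [partitioned_model()] (or [gtr_model()], recycled).
#' @param lengths named integer vector of partition lengths (names are the
#'   partition names).
#' @param seed integer seed.
#' @return named list of taxa x sites character matrices.
#' @export
simulate_alignment <- function(tree, pm, lengths, seed = 1) {
  if (is.null(names(lengths))) stop("lengths must be named by partition")
  pm <- as_partitioned_sim(pm, names(lengths))
  set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise") # parents before children
  ntip <- ape::Ntip(tr)
  root <- ntip + 1L
  out <- list()
  for (g in names(lengths)) {
    mod <- pm[[g]]
    L <- lengths[[g]]
    es <- gtr_eigen(mod)
    cat_rates <- gamma_rates(mod$alpha, mod$k) * mod$rate_mult
    site_cat <- sample.int(length(cat_rates), L, replace = TRUE)
    nnode <- ntip + tr$Nnode
    states <- matrix(0L, nnode, L)
    states[root, ] <- sample.int(4, L, replace = TRUE, prob = mod$pi)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
      for (c in seq_along(cat_rates)) {
        P <- es$V %*% diag(exp(es$lambda * cat_rates[c] * t)) %*% es$Vinv
        P[P < 0] <- 0
        P <- P / rowSums(P)
        for (s in 1:4) {
          sel <- which(site_cat == c & states[p, ] == s)
          if (length(sel)) {
            states[ch, sel] <- sample.int(4, length(sel), replace = TRUE,
                                          prob = P[s, ])
          }
        }
      }
    }
    m <- matrix(DNA_STATES[states[seq_len(ntip), , drop = FALSE]], nrow = ntip,
                dimnames = list(tr$tip.label, NULL))
    out[[g]] <- m
  }
  out
}

as_partitioned_sim <- function(pm, genes) {
  if (inherits(pm, "gtr_model")) return(partitioned_model(pm, genes))
  stopifnot(all(genes %in% names(pm)))
  pm
}

#' Impose structured gene-wise missingness
#'
#' Emulates the occupancy structure of published sparse supermatrices:
#' whole genes are present or absent per taxon (Bernoulli with per-gene
#' coverage probabilities), a scaffold of designated taxa always keeps all
#' scaffold genes (the well-sampled nuclear loci), an optional set of taxa
#' is restricted to mitochondrial data only, and taxa falling below the
#' minimum-data threshold are re-drawn a bounded number of times, then
#' dropped (logged).
#'
#' @param alignments named list of taxa x sites character matrices.
#' @param coverage named numeric vector of per-gene retention probabilities.
#' @param scaffold_fraction fraction of taxa forced complete for
#'   `scaffold_genes` (default 0.25).
#' @param min_total_bp minimum retained bp per taxon (default 250).
#' @param seed integer seed.
#' @param scaffold_genes genes the scaffold keeps (default: all genes whose
#'   name is in the nuclear set of [squamate_gene_table()], else none).
#' @param mtdna_only_tips optional tips restricted to `mito_genes`.
#' @param mito_genes genes such tips may keep.
#' @param fragment_range range of the contiguous fraction each retained
#'   non-scaffold gene keeps (default `c(1, 1)`, whole genes). Published
#'   sparse matrices hold many partial sequences; drawing fragment
#'   fractions from about `c(0.26, 0.66)` reproduces their overall
#'   missingness (see [simulation_config()]).
#' @param max_redraw redraw attempts per sub-threshold taxon (default 20).
#' @return a `supermatrix`; dropped taxa (if any) are recorded in
#'   `attr(, "dropped")`, realized coverage in `attr(, "realized_coverage")`.
#' @export
apply_missingness <- function(alignments, coverage, scaffold_fraction = 0.08,
                              min_total_bp = 250, seed = 1,
                              scaffold_genes = NULL, mtdna_only_tips = NULL,
                              mito_genes = NULL, fragment_range = c(1, 1),
                              max_redraw = 20) {
  stopifnot(all(names(alignments) %in% names(coverage)))
  genes <- names(alignments)
  if (is.null(scaffold_genes)) {
    ref <- squamate_gene_table()
    scaffold_genes <- intersect(genes, ref$gene[ref$role == "nuclear"])
  }
  taxa <- rownames(alignments[[1]])
  lens <- vapply(alignments, ncol, 0L)
  set.seed(seed)
  n_scaffold <- round(scaffold_fraction * length(taxa))
  scaffold <- if (n_scaffold > 0) sample(taxa, n_scaffold) else character(0)
  # scaffold taxa always carry the scaffold loci; non-scaffold retention is
  # thinned so each gene's overall coverage stays at its nominal fraction
  f_s <- n_scaffold / length(taxa)
  p_eff <- vapply(genes, function(g) {
    p <- coverage[[g]]
    if (g %in% scaffold_genes && f_s < 1) max(0, (p - f_s) / (1 - f_s)) else p
  }, 0)
  names(p_eff) <- genes
  draw_mask <- function(is_scaffold, mito_only) {
    keep <- runif(length(genes)) < (if (is_scaffold) pmax(
      p_eff, as.numeric(genes %in% scaffold_genes)) else p_eff)
    names(keep) <- genes
    if (is_scaffold) keep[scaffold_genes] <- TRUE
    if (mito_only) keep[setdiff(genes, mito_genes)] <- FALSE
    # retained genes hold a contiguous fragment; scaffold loci stay complete
    frac <- runif(length(genes), fragment_range[1], fragment_range[2])
    names(frac) <- genes
    if (is_scaffold) frac[scaffold_genes] <- 1
    fraglen <- ifelse(keep, pmax(1L, round(lens * frac)), 0L)
    start <- vapply(seq_along(genes), function(i) {
      if (fraglen[i] == 0) 0L else sample.int(lens[i] - fraglen[i] + 1L, 1)
    }, 0L)
    list(keep = keep, fraglen = as.integer(fraglen), start = start)
  }
  mask <- matrix(FALSE, length(taxa), length(genes),
                 dimnames = list(taxa, genes))
  windows <- array(0L, dim = c(length(taxa), length(genes), 2),
                   dimnames = list(taxa, genes, c("start", "len")))
  dropped <- character(0)
  for (tx in taxa) {
    ok <- FALSE
    for (try in seq_len(max_redraw)) {
      d <- draw_mask(tx %in% scaffold,
                     !is.null(mtdna_only_tips) && tx %in% mtdna_only_tips)
      if (sum(d$fraglen) >= min_total_bp) { ok <- TRUE; break }
    }
    if (ok) {
      mask[tx, ] <- d$keep
      windows[tx, , 1] <- d$start
      windows[tx, , 2] <- d$fraglen
    } else {
      dropped <- c(dropped, tx)
    }
  }
  keep_taxa <- setdiff(taxa, dropped)
  sm <- concatenate_genes(lapply(alignments, function(a)
    a[keep_taxa, , drop = FALSE]), genes)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    cols <- partition_range(sm, g)
    for (tx in keep_taxa) {
      if (!mask[tx, g]) {
        sm$seq[tx, cols] <- "?"
      } else if (windows[tx, g, 2] < lens[gi]) {
        s <- windows[tx, g, 1]; l <- windows[tx, g, 2]
        keep_cols <- cols[s:(s + l - 1L)]
        sm$seq[tx, setdiff(cols, keep_cols)] <- "?"
      }
    }
  }
  attr(sm, "dropped") <- dropped
  attr(sm, "scaffold") <- scaffold
  attr(sm, "realized_coverage") <-
    colSums(mask[keep_taxa, , drop = FALSE]) / length(keep_taxa)
  sm
}

#' Plant a ranked taxonomy on a simulated tree
#'
#' Assigns genera (nested inside families) to clades of the tree, so that
#' with no violations every named taxon is monophyletic by construction.
#' Families are obtained by repeatedly splitting the largest clade until
#' `length(family_sizes)` clades exist; genera are split the same way
#' within families. Requested sizes are matched to realized clade sizes by
#' rank; exact sizes cannot always be realized on an arbitrary tree (a
#' warning reports mismatches). A violation specification then moves named
#' tips across genera to create known non-monophyly for auditor tests.
#'
#' @param tree a rooted `phylo`.
#' @param genera_sizes integer vector, one entry per genus, summing to the
#'   number of leaves.
#' @param violation_spec either an integer `v` (move the first tip of each
#'   of `v` genera into the next genus) or a data.frame with columns `tip`
#'   and `genus` giving explicit reassignments.
#' @param n_families number of families (default: about one per 4 genera).
#' @return a `taxonomy_table` with `species`, `genus`, `subfamily`,
#'   `family`; moved tips recorded in `attr(, "violations")`.
#' @export
plant_taxonomy <- function(tree, genera_sizes, violation_spec = 0,
                           n_families = max(1L, length(genera_sizes) %/% 4L)) {
  ntip <- ape::Ntip(tree)
  if (sum(genera_sizes) != ntip) {
    stop("genera sizes sum to ", sum(genera_sizes), ", tree has ", ntip,
         " leaves")
  }
  n_genera <- length(genera_sizes)
  fam_clades <- split_into_clades(tree, n_families)
  # distribute genera over families proportionally to family size
  gen_per_fam <- pmax(1L, round(n_genera * vapply(fam_clades, length, 0L) / ntip))
  while (sum(gen_per_fam) > n_genera) {
    i <- which.max(gen_per_fam)
    gen_per_fam[i] <- gen_per_fam[i] - 1L
  }
  while (sum(gen_per_fam) < n_genera) {
    i <- which.max(vapply(fam_clades, length, 0L) / gen_per_fam)
    gen_per_fam[i] <- gen_per_fam[i] + 1L
  }
  species <- character(0); genus <- character(0); family <- character(0)
  gidx <- 0L
  for (f in seq_along(fam_clades)) {
    sub <- ape::keep.tip(tree, fam_clades[[f]])
    clades <- split_into_clades(sub, gen_per_fam[f])
    for (cl in clades) {
      gidx <- gidx + 1L
      species <- c(species, cl)
      genus <- c(genus, rep(sprintf("Genus%02d", gidx), length(cl)))
      family <- c(family, rep(sprintf("Family%02d", f), length(cl)))
    }
  }
  realized <- as.vector(table(factor(genus, levels = unique(genus))))
  if (!identical(sort(realized), sort(as.integer(genera_sizes)))) {
    warning("requested genus sizes could not all be realized as clades; ",
            "realized sizes: ", paste(realized, collapse = ", "))
  }
  tab <- data.frame(species = species, genus = genus, subfamily = "",
                    family = family, stringsAsFactors = FALSE)
  fam_of_genus <- tab$family[match(unique(tab$genus), tab$genus)]
  names(fam_of_genus) <- unique(tab$genus)
  moved <- data.frame(tip = character(), from = character(), to = character())
  if (is.data.frame(violation_spec)) {
    for (i in seq_len(nrow(violation_spec))) {
      j <- match(violation_spec$tip[i], tab$species)
      if (is.na(j)) stop("violation tip not in tree: ", violation_spec$tip[i])
      to <- violation_spec$genus[i]
      moved <- rbind(moved, data.frame(tip = tab$species[j],
                                       from = tab$genus[j], to = to))
      tab$genus[j] <- to
      if (to %in% names(fam_of_genus)) tab$family[j] <- fam_of_genus[[to]]
    }
  } else if (violation_spec > 0) {
    gl <- names(fam_of_genus)
    v <- min(violation_spec, length(gl) %/% 2L)
    for (i in seq_len(v)) {
      # pick a donor tip whose relabelling provably breaks the target's
      # monophyly (the union of target tips and donor must not be a clade);
      # donors and targets are disjoint genus sets so later moves cannot
      # undo an earlier violation
      donor_tips <- setdiff(tab$species[tab$genus == gl[i]], moved$tip)
      placed <- FALSE
      for (off in seq_len(length(gl) - 1L)) {
        to <- gl[(i + v + off - 2L) %% length(gl) + 1L]
        if (to == gl[i] || to %in% c(moved$to, gl[seq_len(v)])) next
        target_idx <- match(tab$species[tab$genus == to], tree$tip.label)
        for (tip in donor_tips) {
          un <- c(target_idx, match(tip, tree$tip.label))
          if (!is_single_clade(tree, un)) {
            j <- match(tip, tab$species)
            moved <- rbind(moved, data.frame(tip = tip, from = gl[i], to = to))
            tab$genus[j] <- to
            tab$family[j] <- fam_of_genus[[to]]
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
    }
  }
  tab <- tab[match(tree$tip.label, tab$species), ]
  rownames(tab) <- NULL
  out <- validate_taxonomy(tab)
  attr(out, "violations") <- moved
  out
}

# Split a tree's leaves into k clades by repeatedly dividing the clade with
# the most leaves at its root.
split_into_clades <- function(tree, k) {
  ntip <- ape::Ntip(tree)
  sets <- node_tip_sets(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  active <- ntip + 1L # root
  while (length(active) < k) {
    sizes <- vapply(active, function(nd) length(sets[[nd]]), 0L)
    splittable <- active[sizes > 1]
    if (!length(splittable)) break
    nd <- splittable[which.max(vapply(splittable, function(x)
      length(sets[[x]]), 0L))]
    active <- c(setdiff(active, nd), kids[[as.character(nd)]])
  }
  lapply(active, function(nd) tree$tip.label[sets[[nd]]])
}

#' Simulate a complete paper-style dataset
#'
#' Convenience wrapper running the whole generator: Yule tree, per-gene
#' GTR+Gamma alignments, structured gene-wise missingness, minimum-data
#' filtering, and a planted taxonomy.
#'
#' @param config a [simulation_config()].
#' @param genera_sizes optional genus sizes for [plant_taxonomy()] (default:
#'   balanced, about 4 tips per genus).
#' @param violations passed to [plant_taxonomy()].
#' @return list: `tree` (true tree, pruned to retained taxa), `matrix`
#'   (`supermatrix`), `alignments` (pre-mask), `taxonomy`, `model`,
#'   `config`.
#' @export
simulate_dataset <- function(config, genera_sizes = NULL, violations = 0) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- simulate_tree(config$n_taxa, config$birth_rate,
                        seed = derive_seed(config$seed, 1),
                        depth = config$tree_depth)
  lengths <- setNames(config$genes$length_bp, config$genes$gene)
  aln <- simulate_alignment(tree, config$models, lengths,
                            seed = derive_seed(config$seed, 2))
  coverage <- setNames(config$genes$coverage, config$genes$gene)
  scaffold_genes <- config$genes$gene[config$genes$role == "nuclear"]
  sm <- apply_missingness(aln, coverage,
                          scaffold_fraction = config$scaffold_fraction,
                          min_total_bp = config$min_total_bp,
                          seed = derive_seed(config$seed, 3),
                          scaffold_genes = scaffold_genes,
                          fragment_range = config$fragment_range)
  kept <- rownames(sm$seq)
  tree_kept <- if (length(kept) < config$n_taxa) ape::keep.tip(tree, kept) else tree
  if (is.null(genera_sizes)) {
    n_gen <- max(1L, length(kept) %/% 4L)
    base <- length(kept) %/% n_gen
    genera_sizes <- rep(base, n_gen)
    rem <- length(kept) - sum(genera_sizes)
    if (rem > 0) genera_sizes[seq_len(rem)] <- genera_sizes[seq_len(rem)] + 1L
  }
  taxonomy <- suppressWarnings(
    plant_taxonomy(tree_kept, genera_sizes, violations))
  list(tree = tree_kept, matrix = sm, alignments = aln, taxonomy = taxonomy,
       model = config$models, config = config)
}
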