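test_that("simulated Yule trees are binary, ultrametric and reproducible", {
  tr <- simulate_tree(16, seed = 171)
  expect_equal(ape::Ntip(tr) + tr$Nnode, 2L * 16L - 1L)
  depths <- ape::node.depth.edgelength(tr)[1:16]
  expect_lt(diff(range(depths)), 1e-8)
  expect_identical(write_newick(simulate_tree(16, seed = 171)), write_newick(tr))
  expect_error(simulate_tree(2, seed = 1), ">= 3")
  tr2 <- simulate_tree(16, seed = 171, depth = 0.5)
  expect_equal(max(ape::node.depth.edgelength(tr2)), 0.5)
})

test_that("sequence simulation honors the model", {
  # zero-length tree: everything identical
  tr <- simulate_tree(5, seed = 181)
  tr$edge.length <- rep(0, nrow(tr$edge))
  aln <- simulate_alignment(tr, gtr_model(), c(g = 100L), seed = 182)
  expect_equal(nrow(unique(aln$g)), 1L)

  # long branches: empirical frequencies converge to pi
  mod <- gtr_model(pi = c(0.4, 0.3, 0.2, 0.1), rates = c(1, 5, 1, 1, 5, 1),
                   alpha = Inf, k = 1)
  tr2 <- read_newick("(A:8,B:8);")
  big <- simulate_alignment(tr2, mod, c(g = 100000L), seed = 183)
  freq <- prop.table(table(factor(big$g, levels = c("A", "C", "G", "T"))))
  expect_lt(max(abs(freq - mod$pi)), 0.02)
})

test_that("the truth model outscores a misspecified one on simulated data", {
  tree <- simulate_tree(8, seed = 191, depth = 0.5)
  truth <- gtr_model(pi = c(0.3, 0.25, 0.15, 0.3), rates = c(2, 8, 1.5, 1, 12, 1),
                     alpha = 0.5)
  wrong <- truth
  wrong$alpha <- 2 # shape off by a factor of four
  wins <- 0L
  for (s in 1:30) {
    aln <- simulate_alignment(tree, truth, c(g = 5000L), seed = 200 + s)
    sm <- concatenate_genes(aln)
    if (tree_log_likelihood(tree, sm, truth)$lnL >
        tree_log_likelihood(tree, sm, wrong)$lnL) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * 30))
})

test_that("gene-wise occupancy reproduces its target coverages", {
  ref <- squamate_gene_table()
  aln <- lapply(seq_len(nrow(ref)), function(i) {
    m <- matrix("A", 500, ref$length_bp[i])
    rownames(m) <- sprintf("sp%03d", 1:500)
    m
  })
  names(aln) <- ref$gene
  sm <- apply_missingness(aln, setNames(ref$coverage, ref$gene), seed = 211)
  st <- matrix_statistics(sm)
  # realized per-gene coverage within 3 binomial standard deviations
  for (i in seq_len(nrow(ref))) {
    p <- ref$coverage[i]
    sd3 <- 3 * sqrt(p * (1 - p) / 500)
    realized <- st$per_gene$n_covered[st$per_gene$gene == ref$gene[i]] / 500
    expect_lt(abs(realized - p), sd3 + 0.02) # +2% for the 250-bp redraws
  }
  # coverage probabilities of 1 leave nothing missing
  aln2 <- aln[1:2]
  sm2 <- apply_missingness(aln2, c(`12S` = 1, `16S` = 1), seed = 1,
                           scaffold_fraction = 0)
  expect_equal(matrix_statistics(sm2)$percent_missing, 0)
})

test_that("whole-gene occupancy matches its expectation; fragments reach ~81%", {
  ref <- squamate_gene_table()
  aln <- lapply(seq_len(nrow(ref)), function(i) {
    m <- matrix("A", 400, ref$length_bp[i])
    rownames(m) <- sprintf("sp%03d", 1:400)
    m
  })
  names(aln) <- ref$gene
  # expectation from the configuration itself
  expected_missing <- 1 - sum(ref$coverage * ref$length_bp) / sum(ref$length_bp)
  sm <- apply_missingness(aln, setNames(ref$coverage, ref$gene), seed = 221)
  expect_lt(abs(matrix_statistics(sm)$percent_missing / 100 - expected_missing),
            0.03)
  # contiguous-fragment emulation reproduces the reference matrix's ~81%
  smf <- apply_missingness(aln, setNames(ref$coverage, ref$gene), seed = 221,
                           fragment_range = c(0.26, 0.66))
  stf <- matrix_statistics(smf)
  expect_true(stf$percent_missing / 100 >= 0.79 &&
                stf$percent_missing / 100 <= 0.83)
  expect_equal(stf$mean_genes_per_taxon, 15595 / 4162, tolerance = 0.08)
})

test_that("planted taxonomies audit clean, and violations surface", {
  tree <- simulate_tree(36, seed = 231)
  tax0 <- suppressWarnings(plant_taxonomy(tree, rep(4L, 9), 0))
  aud0 <- audit_classification(tree, tax0)
  expect_true(all(aud0$status %in% c("monophyletic", "trivial")))

  # an explicit swap of one tip between two genera flags exactly those two
  gl <- unique(tax0$genus)
  sA <- tax0$species[tax0$genus == gl[1]][1]
  sB <- tax0$species[tax0$genus == gl[4]][1]
  taxs <- suppressWarnings(plant_taxonomy(
    tree, rep(4L, 9),
    data.frame(tip = c(sA, sB), genus = c(gl[4], gl[1]))))
  auds <- audit_classification(tree, taxs)
  gens <- auds[auds$rank == "genus", ]
  bads <- gens$taxon[!gens$status %in% c("monophyletic", "trivial")]
  expect_setequal(bads, c(gl[1], gl[4]))

  for (v in 2:3) {
    taxv <- suppressWarnings(plant_taxonomy(tree, rep(4L, 9), v))
    audv <- audit_classification(tree, taxv)
    genv <- audv[audv$rank == "genus", ]
    expect_gte(sum(!genv$status %in% c("monophyletic", "trivial")), v)
  }
  expect_error(suppressWarnings(plant_taxonomy(tree, rep(4L, 8), 0)), "sum")
})

test_that("generators are byte-reproducible under a fixed seed", {
  cfg <- simulation_config(n_taxa = 10, seed = 241, length_scale = 0.05)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$matrix$seq, s2$matrix$seq)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
  expect_identical(s1$taxonomy$genus, s2$taxonomy$genus)
})
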