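test_that("Fitch scores match direct expectations and brute force", {
  tr <- read_newick("((A,B),(C,D));")
  expect_equal(fitch_score(tr, c(A = "A", B = "A", C = "A", D = "A")), 0L)
  expect_equal(fitch_score(tr, c(A = "A", B = "A", C = "T", D = "T")), 1L)
  expect_equal(fitch_score(tr, c(A = "A", B = "T", C = "A", D = "T")), 2L)
  # missing data are wildcards
  expect_equal(fitch_score(tr, c(A = "A", B = "?", C = "T", D = "T")), 1L)

  set.seed(13)
  for (i in 1:8) {
    tr6 <- random_resolved_tree(6, seed = 100 + i)
    col <- setNames(sample(c("A", "C", "G", "T"), 6, TRUE), tr6$tip.label)
    expect_equal(fitch_score(tr6, col), brute_force_fitch(tr6, col))
  }
})

test_that("Fitch agrees with an independent implementation on a matrix", {
  skip_if_not_installed("phangorn")
  tree <- simulate_tree(9, seed = 31, depth = 0.5)
  aln <- simulate_alignment(tree, gtr_model(alpha = 0.5), c(g = 200L), seed = 32)
  sm <- concatenate_genes(aln)
  expect_equal(fitch_score(tree, sm),
               as.integer(phangorn::fitch(tree, phangorn::phyDat(aln$g))))
})

test_that("stepwise addition is deterministic and beats random topologies", {
  cfg <- simulation_config(n_taxa = 9, seed = 41, length_scale = 0.05,
                           fragment_range = c(1, 1))
  sim <- simulate_dataset(cfg)

  t3 <- stepwise_addition_tree(make_sm(c(A = "ACGT", B = "AGGT", C = "ACTT")), 1)
  expect_equal(ape::Ntip(t3), 3L)

  s1 <- stepwise_addition_tree(sim$matrix, seed = 7)
  s2 <- stepwise_addition_tree(sim$matrix, seed = 7)
  expect_identical(canonical_newick(s1), canonical_newick(s2))
  expect_error(stepwise_addition_tree(make_sm(c(A = "A", B = "A")), 1), ">= 3")

  sw_score <- fitch_score(s1, sim$matrix)
  rand_scores <- vapply(1:20, function(i) {
    set.seed(i)
    rt <- ape::rtree(nrow(sim$matrix$seq), tip.label = sample(rownames(sim$matrix$seq)))
    fitch_score(rt, sim$matrix)
  }, 0L)
  expect_lte(sw_score, stats::median(rand_scores))
})

test_that("branch-length optimization hits the JC closed form and never degrades", {
  jc <- gtr_model(alpha = Inf, k = 1)
  sm <- make_sm(c(A = paste(c(rep("A", 90), rep("C", 10)), collapse = ""),
                  B = strrep("A", 100)))
  tr <- read_newick("(A:0.2,B:0.2);")
  before <- tree_log_likelihood(tr, sm, jc)$lnL
  opt <- optimize_branch_lengths(tr, sm, jc)
  expect_equal(sum(opt$edge.length), -3 / 4 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-3)
  expect_gte(attr(opt, "lnL"), before)
})

test_that("branch lengths are recovered within 5% at large site counts", {
  tree <- simulate_tree(8, seed = 51, depth = 0.4)
  mod <- gtr_model(pi = c(0.3, 0.25, 0.15, 0.3), rates = c(2, 8, 1.5, 1, 12, 1),
                   alpha = 0.5)
  aln <- simulate_alignment(tree, mod, c(g = 50000L), seed = 52)
  sm <- concatenate_genes(aln)
  # compare on the unrooted tree in one fixed edge order (the two root-side
  # lengths of a rooted tree are not separately identifiable)
  truth <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  start <- truth
  start$edge.length <- rep(0.1, nrow(truth$edge))
  fit <- suppressWarnings(optimize_branch_lengths(start, sm, mod, tol = 0.001))
  stopifnot(identical(fit$edge, truth$edge))
  rel_err <- abs(fit$edge.length - truth$edge.length) /
    pmax(truth$edge.length, 0.01)
  expect_lt(stats::median(rel_err), 0.05)
})

test_that("model optimization recovers the gamma shape within 10%", {
  tree <- simulate_tree(6, seed = 61, depth = 0.5)
  truth <- gtr_model(pi = c(0.3, 0.25, 0.15, 0.3), rates = c(2, 8, 1.5, 1, 12, 1),
                     alpha = 0.5)
  aln <- simulate_alignment(tree, truth, c(g = 100000L), seed = 62)
  sm <- concatenate_genes(aln)
  before <- tree_log_likelihood(tree, sm, gtr_model(alpha = 1))$lnL
  out <- suppressWarnings(optimize_model(tree, sm, gtr_model(alpha = 1)))
  expect_gte(out$lnL, before)
  expect_lt(abs(out$model$g$alpha - 0.5) / 0.5, 0.10)
})

test_that("degenerate and rate-homogeneous partitions are handled", {
  # a single-pattern partition keeps its model, with a warning
  sm <- make_sm(setNames(rep(strrep("A", 12), 4), paste0("t", 1:4)))
  tr <- random_resolved_tree(4, seed = 4)
  tr$tip.label <- paste0("t", 1:4)
  expect_warning(optimize_model(tr, sm, gtr_model(alpha = 1)),
                 "single site pattern")

  # data without rate heterogeneity drive the shape toward its upper bound
  tree <- simulate_tree(6, seed = 71, depth = 0.5)
  flat <- gtr_model(alpha = Inf, k = 1)
  aln <- simulate_alignment(tree, flat, c(g = 20000L), seed = 72)
  smh <- concatenate_genes(aln)
  out <- suppressWarnings(optimize_model(tree, smh, gtr_model(alpha = 1)))
  expect_gt(out$model$g$alpha, 5)
})
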