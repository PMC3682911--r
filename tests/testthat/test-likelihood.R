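test_that("two-taxon single-site likelihood equals the hand formula", {
  jc <- gtr_model(alpha = Inf, k = 1)
  sm <- make_sm(c(A = "A", B = "A"))
  tr <- read_newick("(A:0.06,B:0.04);")
  ll <- tree_log_likelihood(tr, sm, jc)
  expect_equal(ll$lnL, log(0.25 * (1 / 4 + 3 / 4 * exp(-4 * 0.1 / 3))),
               tolerance = 1e-10)
})

test_that("pruning equals brute-force state enumeration on small trees", {
  set.seed(5)
  for (i in 1:6) {
    n <- sample(3:5, 1)
    tr <- random_resolved_tree(n, seed = i)
    tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.6)
    chars <- sample(c("A", "C", "G", "T", "?", "-"), 3 * n, TRUE,
                    prob = c(rep(0.22, 4), 0.06, 0.06))
    rows <- apply(matrix(chars, nrow = n), 1, paste, collapse = "")
    names(rows) <- tr$tip.label
    sm <- make_sm(rows)
    mod <- gtr_model(pi = prop.table(runif(4, 0.5, 1)),
                     rates = runif(6, 0.5, 2), alpha = 0.7, k = 2)
    ours <- tree_log_likelihood(tr, sm, mod)$lnL
    oracle <- brute_force_lnl(tr, sm, mod)
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
})

test_that("all-missing columns contribute nothing", {
  jc <- gtr_model()
  tr <- random_resolved_tree(4, seed = 2)
  sm1 <- make_sm(setNames(c("ACG", "ACT", "GCG", "ACG"), tr$tip.label))
  sm2 <- make_sm(setNames(c("ACG?", "ACT?", "GCG-", "ACGN"), tr$tip.label))
  expect_equal(tree_log_likelihood(tr, sm2, jc)$lnL,
               tree_log_likelihood(tr, sm1, jc)$lnL)
})

test_that("likelihood is invariant to root placement, taxon order and site order", {
  set.seed(9)
  tr <- random_resolved_tree(7, seed = 3)
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.4)
  rows <- setNames(vapply(1:7, function(i)
    paste(sample(c("A", "C", "G", "T", "?"), 40, TRUE), collapse = ""), ""),
    tr$tip.label)
  sm <- make_sm(rows)
  mod <- gtr_model(pi = c(0.3, 0.2, 0.2, 0.3), rates = c(1, 3, 1, 1, 3, 1),
                   alpha = 0.5)
  base <- tree_log_likelihood(tr, sm, mod)$lnL

  # pulley principle: rerooting an unrooted tree leaves lnL unchanged
  un <- ape::unroot(tr)
  expect_equal(tree_log_likelihood(un, sm, mod)$lnL, base, tolerance = 1e-8)
  for (og in c(2, 5)) {
    rr <- ape::root(un, outgroup = un$tip.label[og], resolve.root = TRUE)
    expect_equal(tree_log_likelihood(rr, sm, mod)$lnL, base, tolerance = 1e-8)
  }

  # taxon order
  sm_perm <- sm
  perm <- sample(7)
  sm_perm$seq <- sm_perm$seq[perm, , drop = FALSE]
  expect_equal(tree_log_likelihood(tr, sm_perm, mod)$lnL, base)

  # site order (pattern compression correctness)
  sm_sites <- sm
  sm_sites$seq <- sm_sites$seq[, sample(40), drop = FALSE]
  expect_equal(tree_log_likelihood(tr, sm_sites, mod)$lnL, base)
})

test_that("partitioned GTR+Gamma matches an independent implementation", {
  skip_if_not_installed("phangorn")
  tree <- simulate_tree(10, seed = 21, depth = 0.5)
  mod <- gtr_model(pi = c(0.35, 0.25, 0.1, 0.3), rates = c(2, 6, 1.4, 0.9, 9, 1),
                   alpha = 0.4)
  aln <- simulate_alignment(tree, mod, c(locus = 400L), seed = 22)
  sm <- concatenate_genes(aln)
  ours <- tree_log_likelihood(tree, sm, mod)$lnL
  fit <- phangorn::pml(tree, phangorn::phyDat(aln$locus), bf = mod$pi,
                       Q = mod$rates, shape = mod$alpha, k = 4)
  expect_equal(ours, fit$logLik, tolerance = 1e-6)

  # two partitions with rate multipliers: sums of per-partition evaluations
  pm <- partitioned_model(list(a = gtr_model(alpha = 0.5, rate_mult = 2),
                               b = gtr_model(alpha = 0.5, rate_mult = 1)),
                          c("a", "b"))
  aln2 <- simulate_alignment(tree, pm, c(a = 150L, b = 250L), seed = 23)
  sm2 <- concatenate_genes(aln2)
  ll <- tree_log_likelihood(tree, sm2, pm)
  expect_equal(ll$lnL, sum(ll$per_partition))
  expect_equal(length(ll$site_lnl$a), 150L)
})

test_that("leaves absent from the matrix are rejected", {
  sm <- make_sm(c(A = "ACG", B = "ACG", C = "ACG"))
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(tree_log_likelihood(tr, sm, gtr_model()), "absent")
})
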