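test_that("completeness is the present-bp quotient", {
  sm <- make_sm(c(A = strrep("A", 8), B = paste0(strrep("A", 2), strrep("?", 6))))
  comp <- completeness(sm)
  expect_equal(unname(comp["A"]), 1.0)
  expect_equal(unname(comp["B"]), 0.25)
  # the published mean: 2497 of 12896 bp
  expect_equal(round(2497 / 12896, 4), 0.1936)
  # conservation: completeness times columns sums to total present cells
  expect_equal(sum(comp * ncol(sm$seq)), sum(present_bp(sm)))
})

test_that("the completeness regression matches textbook closed forms", {
  tree <- simulate_tree(30, seed = 131, depth = 0.5)
  set.seed(132)
  comp <- setNames(runif(30, 0.05, 0.95), tree$tip.label)
  reg <- completeness_regression(tree, comp)

  ntip <- ape::Ntip(tree)
  term <- tree$edge[, 2] <= ntip
  y <- tree$edge.length[term]
  x <- unname(comp[tree$tip.label[tree$edge[term, 2]]])
  n <- length(x)
  r_direct <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  tstat <- r_direct * sqrt((n - 2) / (1 - r_direct^2))
  p_direct <- 2 * stats::pt(-abs(tstat), df = n - 2)
  slope_direct <- r_direct * stats::sd(y) / stats::sd(x)
  expect_equal(reg$r, r_direct, tolerance = 1e-10)
  expect_equal(reg$p_value, p_direct, tolerance = 1e-10)
  expect_equal(reg$slope, slope_direct, tolerance = 1e-10)

  # perfectly linear data
  tree2 <- tree
  term_rows <- which(term)
  tree2$edge.length[term_rows] <- 0.01 + 0.5 * x
  reg2 <- completeness_regression(tree2, comp)
  expect_equal(reg2$r, 1, tolerance = 1e-12)
  expect_lt(reg2$p_value, 1e-20)

  expect_error(completeness_regression(tree, setNames(rep(0.5, 30), tree$tip.label)),
               "degenerate")
})

test_that("support summaries count strict exceedance and survive rerooting", {
  tr <- read_newick("(((A:1,B:1)100:1,(C:1,D:1)90:1):1,(E:1,F:1)50:1);")
  s <- support_summary(tr, threshold = 85)
  expect_equal(s$n_with_support, 3L)
  expect_equal(s$fraction_above, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(support_summary(tr, threshold = 90)$n_above, 1L) # strict >
  expect_equal(support_summary(tr, threshold = 90, strict = FALSE)$n_above, 2L)

  rr <- ape::root(ape::unroot(tr), outgroup = "A", resolve.root = TRUE)
  expect_equal(support_summary(rr, 85)$fraction_above, s$fraction_above)

  tr2 <- tr
  tr2$node.label <- NULL
  expect_error(support_summary(tr2), "support")
})

test_that("MCAR completeness induces no correlation and nominal type-I error", {
  null100 <- regression_null_study(n_seeds = 100, n_taxa = 100, seed = 17)
  expect_gte(mean(abs(null100$r) < 0.2), 0.90)
  reject <- mean(null100$p_value < 0.05)
  expect_true(reject >= 0 && reject <= 0.15)
})

test_that("rogue flagging finds planted misplaced weakly-supported tips", {
  # concordant tree: two families of 5, high supports everywhere
  nw <- "(((a1:1,a2:1)99:1,(a3:1,(a4:1,a5:1)98:1)97:1)96:1,((b1:1,b2:1)95:1,(b3:1,(b4:1,b5:1)94:1)93:1)92:1);"
  tr <- read_newick(nw)
  tax <- validate_taxonomy(data.frame(
    species = c(paste0("a", 1:5), paste0("b", 1:5)),
    genus = rep(c("Aus", "Bus"), each = 5),
    family = rep(c("Aidae", "Bidae"), each = 5)))
  expect_equal(nrow(flag_rogues(tr, tax)), 0L)

  # plant a rogue: an Aidae tip deep inside the Bidae clade, weak support
  nw2 <- "(((a1:1,a2:1)99:1,(a3:1,a4:1)97:1)96:1,((b1:1,(a5:1,b2:1)20:1)95:1,(b3:1,(b4:1,b5:1)94:1)93:1)92:1);"
  fl <- flag_rogues(read_newick(nw2), tax)
  expect_equal(fl$taxon, "a5")
  expect_equal(fl$neighborhood_family, "Bidae")

  # planted-rogue screen: 3 terminals carrying a foreign family label while
  # sitting (weakly supported) deep inside another family's clade, in
  # 100-tip simulations over 20 seeds
  n <- 100L
  stats_per_seed <- vapply(1:20, function(r) {
    tree <- simulate_tree(n, seed = 150 + r)
    tax2 <- suppressWarnings(plant_taxonomy(tree, rep(5L, 20), 0,
                                            n_families = 5))
    fam <- setNames(tax2$family, tax2$species)
    parent_of <- integer(n + tree$Nnode)
    parent_of[tree$edge[, 2]] <- tree$edge[, 1]
    sets <- sparsephy:::node_tip_sets(tree)
    # a tip is plantable if its >= 5-tip neighborhood is solidly one family
    neighborhood_fam <- function(tip) {
      node <- parent_of[tip]
      repeat {
        labs <- fam[tree$tip.label[setdiff(sets[[node]], tip)]]
        if (length(labs) >= 5 || parent_of[node] == 0) break
        node <- parent_of[node]
      }
      tt <- sort(table(labs), decreasing = TRUE)
      if (tt[1] > length(labs) * 0.7) names(tt)[1] else NA_character_
    }
    nb <- vapply(seq_len(n), neighborhood_fam, "")
    plantable <- which(!is.na(nb) & nb == fam[tree$tip.label])
    set.seed(1000 + r)
    rogues_idx <- sample(plantable, 3)
    rogues <- tree$tip.label[rogues_idx]
    other_fams <- unique(tax2$family)
    for (i in 1:3) {
      home <- fam[rogues[i]]
      tax2$family[tax2$species == rogues[i]] <-
        setdiff(other_fams, home)[1]
    }
    tree$node.label <- rep("99", tree$Nnode)
    for (rg in rogues_idx) {
      anc <- parent_of[rg]
      if (anc > n) tree$node.label[anc - n] <- "15"
    }
    fl2 <- flag_rogues(tree, tax2)
    c(found = sum(rogues %in% fl2$taxon),
      fp = sum(!fl2$taxon %in% rogues))
  }, c(found = 0, fp = 0))
  expect_gte(stats::median(stats_per_seed["found", ]), 3)
  expect_lte(stats::median(stats_per_seed["fp", ]), 1)
})
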