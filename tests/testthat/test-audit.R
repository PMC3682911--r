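test_that("taxon classification distinguishes mono-, para- and polyphyly", {
  t1 <- read_newick("((A1,A2),(B1,B2));")
  r1 <- classify_taxon(t1, c("A1", "A2"))
  expect_equal(r1$status, "monophyletic")
  expect_equal(r1$k_maximal_clades, 1L)
  expect_length(r1$intruders, 0L)

  t2 <- read_newick("((A1,B1),(A2,B2));")
  r2 <- classify_taxon(t2, c("A1", "A2"))
  expect_equal(r2$status, "polyphyletic")
  expect_setequal(r2$intruders, c("B1", "B2"))

  t3 <- read_newick("(O,(A1,(B1,(A2,A3))));")
  r3 <- classify_taxon(t3, c("A1", "A2", "A3"))
  expect_equal(r3$status, "paraphyletic")
  expect_equal(r3$intruders, "B1")
  expect_equal(r3$k_maximal_clades, 2L)

  expect_equal(classify_taxon(t1, "A1")$status, "trivial")
  expect_error(classify_taxon(t1, c("A1", "ZZ")), "unknown")
})

test_that("paraphyly implies a monophyletic intruder set, invariant to rotation", {
  set.seed(33)
  for (i in 1:20) {
    tr <- ape::rtree(10)
    tips <- sample(tr$tip.label, sample(3:6, 1))
    rep1 <- classify_taxon(tr, tips)
    if (rep1$status == "paraphyletic" && length(rep1$intruders) > 1) {
      expect_equal(classify_taxon(tr, rep1$intruders)$status, "monophyletic")
    }
    rot <- ape::rotate(tr, node = 10 + sample(2:tr$Nnode, 1))
    rep2 <- classify_taxon(rot, tips)
    expect_equal(rep2$status, rep1$status)
    expect_equal(rep2$k_maximal_clades, rep1$k_maximal_clades)
    expect_setequal(rep2$intruders, rep1$intruders)
  }
})

test_that("conflict support equals an exhaustive bipartition scan", {
  # independent scan built on ape's clade enumeration
  oracle_conflict <- function(tree, tips) {
    sup <- branch_supports(tree)
    ntip <- ape::Ntip(tree)
    best <- NA_real_
    pp <- ape::prop.part(tree)
    labs <- attr(pp, "labels")
    for (k in seq_along(pp)) {
      side <- labs[pp[[k]]]
      in_s <- sum(tips %in% side)
      if (in_s > 0 && in_s < length(tips) && length(side) > in_s) {
        s <- sup[k]
        if (!is.na(s) && (is.na(best) || s > best)) best <- s
      }
    }
    best
  }
  set.seed(44)
  checked <- 0L
  for (i in 1:40) {
    tr <- ape::rtree(12)
    tr$node.label <- c("", sample(0:100, tr$Nnode - 1, TRUE))
    tips <- sample(tr$tip.label, sample(3:7, 1))
    st <- classify_taxon(tr, tips)$status
    if (st %in% c("paraphyletic", "polyphyletic")) {
      expect_equal(conflict_support(tr, tips), oracle_conflict(tr, tips))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)

  t1 <- read_newick("((A1,A2),(B1,B2));")
  expect_error(conflict_support(t1, c("A1", "A2")), "monophyletic")
  # single conflicting edge, support 99
  t2 <- read_newick("(O,(A1,(B1,(A2,A3))99)80);")
  expect_equal(conflict_support(t2, c("A1", "A2", "A3")), 99)
  t3 <- read_newick("(O,(A1,(B1,(A2,A3))));")
  expect_true(is.na(conflict_support(t3, c("A1", "A2", "A3"))))
})

test_that("classification audits report planted structure exactly", {
  tree <- simulate_tree(40, seed = 161)
  tax <- suppressWarnings(plant_taxonomy(tree, rep(4L, 10), 0))
  aud <- audit_classification(tree, tax)
  gen <- aud[aud$rank == "genus", ]
  expect_true(all(gen$status %in% c("monophyletic", "trivial")))
  expect_true(all(aud$status %in% c("monophyletic", "trivial")))
  expect_false(any(aud$strongly_supported_conflict))
  # sum of maximal clades equals the number of audited taxa iff all mono
  expect_equal(sum(gen$k_clades), nrow(gen))

  # swap two tips across genera: exactly those two genera become non-mono
  tax2 <- tax
  g1 <- unique(tax2$genus)[1]; g2 <- unique(tax2$genus)[5]
  s1 <- tax2$species[tax2$genus == g1][1]
  s2 <- tax2$species[tax2$genus == g2][1]
  tax2$genus[tax2$species == s1] <- g2
  tax2$genus[tax2$species == s2] <- g1
  aud2 <- audit_classification(tree, tax2)
  bad <- aud2$taxon[aud2$rank == "genus" &
                      !aud2$status %in% c("monophyletic", "trivial")]
  expect_setequal(bad, c(g1, g2))
  expect_gte(sum(aud2$k_clades[aud2$rank == "genus"]),
             sum(aud2$rank == "genus"))
})

test_that("a genus nested inside another is called paraphyletic (skink case)", {
  # two tips of one genus nested within four of another, as in scincine
  # lizards where Scincus and Scincopus render Eumeces paraphyletic
  nw <- paste0("(Outgroup,((Eumeces_schneideri,(Eumeces_algeriensis,",
               "((Scincus_scincus,Scincopus_fasciatus)95,Eumeces_sp)90)85)80,",
               "Plestiodon_fasciatus));")
  tr <- read_newick(nw)
  eum <- grep("^Eumeces", tr$tip.label, value = TRUE)
  rep <- classify_taxon(tr, eum)
  expect_equal(rep$status, "paraphyletic")
  expect_setequal(rep$intruders, c("Scincus_scincus", "Scincopus_fasciatus"))
  expect_gte(conflict_support(tr, eum), 85)
})
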