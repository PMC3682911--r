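test_that("longest-per-species selection keeps the maximal record, ties to first", {
  rec <- make_records(c(X = "ACGTA", Y = "ACG"), "g")
  rec <- rbind(rec, make_records(c(X = "ACG", Y = "ACGTT", X = "ACGTA"), "g"))
  out <- select_longest_per_species(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$length_bp[out$taxon == "X"], 5L)
  # tie between two 5-bp X records: the first encountered wins
  expect_equal(out$sequence[out$taxon == "X"], "ACGTA")
  expect_equal(out$length_bp[out$taxon == "Y"], 5L)
  expect_equal(nrow(select_longest_per_species(rec[0, ])), 0L)
})

test_that("concatenation lays out partitions and fills absent genes", {
  sm <- concatenate_genes(tiny_gene_set())
  expect_equal(dim(sm$seq), c(3L, 12L))
  expect_equal(sm$partitions$start, c(1L, 9L))
  expect_equal(sm$partitions$end, c(8L, 12L))
  # Aus_cus lacks gB: all-missing cells there
  expect_true(all(partition_columns(sm, "gB")["Aus_cus", ] == "?"))

  lens <- c(714L, 903L)
  aln <- list(g1 = matrix("A", 1, lens[1], dimnames = list("t", NULL)),
              g2 = matrix("C", 1, lens[2], dimnames = list("t", NULL)))
  sm2 <- concatenate_genes(aln)
  expect_equal(sm2$partitions$end, c(714L, 1617L))

  dup <- list(g1 = make_records(c(A = "AC", A = "AG"), "g1"))
  expect_error(concatenate_genes(dup), "select_longest")
})

test_that("the 12 published gene lengths concatenate to 12896 bp", {
  ref <- squamate_gene_table()
  aln <- lapply(ref$length_bp, function(L)
    matrix("A", 1, L, dimnames = list("t", NULL)))
  names(aln) <- ref$gene
  sm <- concatenate_genes(aln)
  expect_equal(ncol(sm$seq), 12896L)
  expect_equal(nrow(sm$partitions), 12L)
})

test_that("minimum-data filter drops strictly-below-threshold taxa", {
  rows <- c(keep250 = paste(rep("A", 250), collapse = ""),
            drop249 = paste(c(rep("A", 249), "?"), collapse = ""),
            full = paste(rep("G", 250), collapse = ""))
  rows["drop249"] <- paste0(strrep("A", 249), "?")
  rows["keep250"] <- strrep("A", 250)
  rows["full"] <- strrep("G", 250)
  sm <- make_sm(rows)
  out <- filter_min_total(sm, 250)
  expect_setequal(rownames(out$seq), c("keep250", "full"))
  expect_equal(attr(out, "removed")$taxon, "drop249")
  expect_error(filter_min_total(sm, -1), ">= 0")
})

test_that("deduplication keeps the alphabetically first of identical rows", {
  sm <- make_sm(c(`Aus cus` = "ACGT??", `Aus bus` = "ACGT??",
                  `Bus dus` = "ACGTAA"))
  out <- deduplicate_identical(sm)
  expect_setequal(rownames(out$seq), c("Aus bus", "Bus dus"))
  expect_equal(attr(out, "removed")$taxon, "Aus cus")

  # same present cells but different missingness footprint: both kept
  sm2 <- make_sm(c(A = "ACGT??", B = "ACGTA?"))
  expect_equal(nrow(deduplicate_identical(sm2)$seq), 2L)

  # idempotent
  out2 <- deduplicate_identical(out)
  expect_identical(out2$seq, out$seq)
})

test_that("matrix statistics report completeness and coverage with rounding", {
  sm <- make_sm(c(A = strrep("A", 100), B = strrep("C", 100),
                  C = strrep("G", 100)))
  st <- matrix_statistics(sm)
  expect_equal(st$percent_missing, 0)
  expect_equal(st$mean_present_bp, 100)
  expect_equal(unname(st$completeness_range), c(100L, 100L))

  # the published 12S coverage: 2335 of 4162 taxa -> 56% rounded
  expect_equal(round(100 * 2335 / 4162), 56)
  # the published mean completeness: 2497 of 12896 -> 19% present, 81% missing
  expect_equal(round(100 * 2497 / 12896), 19)
  expect_equal(round(100 * (1 - 2497 / 12896)), 81)
})

test_that("present-bp total is conserved under taxon and gene reordering", {
  sm <- concatenate_genes(tiny_gene_set())
  tot <- sum(present_bp(sm))
  perm <- sm
  perm$seq <- perm$seq[c(3, 1, 2), ]
  expect_equal(sum(present_bp(perm)), tot)
  sm_rev <- concatenate_genes(tiny_gene_set(), gene_order = c("gB", "gA"))
  expect_equal(sum(present_bp(sm_rev)), tot)
})

test_that("split and re-concatenate round-trips the matrix", {
  sm <- concatenate_genes(tiny_gene_set())
  parts <- split_supermatrix(sm, keep_empty = TRUE)
  back <- concatenate_genes(parts, gene_order = sm$partitions$gene)
  expect_equal(back$seq, sm$seq)
  expect_equal(back$partitions, sm$partitions)
})

test_that("filter and dedup commute when no duplicate group straddles the cutoff", {
  sm <- make_sm(c(B = "ACGTAAAA", A = "ACGTAAAA", C = "AC??????"))
  a <- deduplicate_identical(filter_min_total(sm, 4))
  b <- filter_min_total(deduplicate_identical(sm), 4)
  expect_equal(a$seq, b$seq)
})
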