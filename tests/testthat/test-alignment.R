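test_that("identical protein sequences align gap-free at the BLOSUM62 diagonal sum", {
  sch <- scoring_scheme("protein")
  out <- pairwise_affine_align("ACDE", "ACDE", sch)
  expect_equal(out$a, "ACDE")
  expect_equal(out$b, "ACDE")
  diag_sum <- sum(diag(sch$matrix[c("A", "C", "D", "E"), c("A", "C", "D", "E")]))
  expect_equal(out$score, diag_sum)
})

test_that("aligning against an empty sequence costs one affine gap", {
  sch <- scoring_scheme("protein", gap_open = 12, gap_extend = 3)
  out <- pairwise_affine_align("A", "", sch)
  expect_equal(out$score, -(12 + 1 * 3))
  expect_equal(out$a, "A")
  expect_equal(out$b, "-")
})

test_that("DP scores equal brute-force enumeration on random short pairs", {
  sch <- scoring_scheme("dna", gap_open = 5, gap_extend = 2)
  set.seed(42)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE), collapse = "")
    dp <- pairwise_affine_align(a, b, sch)$score
    bf <- brute_force_align_score(a, b, sch)
    expect_equal(dp, bf, info = paste(a, b))
    # symmetry
    expect_equal(pairwise_affine_align(b, a, sch)$score, dp)
  }
})

test_that("translation alignment expands aa gaps to codon gaps and round-trips", {
  rec <- make_records(c(t1 = "ATGAAA", t2 = "ATGAAA"), "cds")
  out <- translation_align(rec)
  expect_equal(out$sequence, rec$sequence) # identity, no gaps

  rec2 <- make_records(c(t1 = "ATGAAACCC", t2 = "ATGCCC"), "cds")
  out2 <- translation_align(rec2)
  expect_equal(unique(nchar(out2$sequence)), 9L)
  gapped <- out2$sequence[out2$taxon == "t2"]
  expect_match(gapped, "---")
  # degapping recovers every input exactly
  for (i in seq_len(nrow(out2))) {
    expect_equal(gsub("-", "", out2$sequence[i]),
                 rec2$sequence[match(out2$taxon[i], rec2$taxon)])
  }

  # internal stops in every frame: record rejected with a report
  bad <- make_records(c(ok = "ATGAAA", bad = "TAGATAGATAGATAGG"), "cds")
  expect_warning(out3 <- translation_align(bad), "rejected")
  expect_false("bad" %in% out3$taxon)
})

test_that("profile merging preserves member columns and matches pairwise on singletons", {
  sch <- scoring_scheme("dna")
  p1 <- alignment_profile(c(x = "ACGT"))
  p2 <- alignment_profile(c(y = "AGT"))
  merged <- profile_merge(p1, p2, sch)
  pw <- pairwise_affine_align("ACGT", "AGT", sch)
  expect_equal(attr(merged, "score"), pw$score)
  expect_equal(paste(merged$members["x", ], collapse = ""), pw$a)
  expect_equal(paste(merged$members["y", ], collapse = ""), pw$b)

  expect_error(profile_merge(p1, list(members = NULL), sch), "empty profile")

  # within-profile identity is untouched by a merge (columns only inserted)
  pa <- alignment_profile(c(a1 = "ACGTT", a2 = "ACCTT"))
  pb <- alignment_profile(c(b1 = "ACG"))
  m2 <- profile_merge(pa, pb, sch)
  a1 <- m2$members["a1", ]; a2 <- m2$members["a2", ]
  both <- a1 != "-" | a2 != "-"
  expect_equal(paste(a1[a1 != "-"], collapse = ""), "ACGTT")
  expect_equal(sum(a1[both] == a2[both]), 4L) # 4 of 5 identical, as input
})

test_that("progressive alignment of identical sequences introduces no gaps", {
  seqs <- setNames(rep("ACGTACGT", 4), paste0("s", 1:4))
  prof <- progressive_align(seqs, scoring_scheme("dna"))
  expect_equal(ncol(prof$members), 8L)
  expect_false(any(prof$members == "-"))
})

test_that("end trimming removes only low-occupancy margins and is idempotent", {
  m <- rbind(a = strsplit("--ACGTAC--", "")[[1]],
             b = strsplit("--ACGTACGT", "")[[1]],
             c = strsplit("GGACGTACGT", "")[[1]],
             d = strsplit("--ACGTACGT", "")[[1]],
             e = strsplit("--ACGTACGT", "")[[1]],
             f = strsplit("--ACGTACGT", "")[[1]],
             g = strsplit("--ACGTACGT", "")[[1]],
             h = strsplit("--ACGTACGT", "")[[1]],
             i = strsplit("--ACGTACGT", "")[[1]],
             j = strsplit("--ACGTACGT", "")[[1]])
  out <- trim_ends(m, 0.5)
  expect_equal(ncol(out), 8L) # first two columns at 10% occupancy dropped
  expect_identical(trim_ends(out, 0.5), out)

  full <- matrix("A", 3, 5)
  expect_identical(trim_ends(full, 0.5), full)
  allgap <- matrix("-", 3, 4)
  expect_error(trim_ends(allgap, 0.5), "every column")
})
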