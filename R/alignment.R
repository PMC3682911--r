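#' Scoring scheme for affine-gap alignment
#'
#' A substitution matrix plus affine gap penalties. A gap of length L costs
#' `gap_open + L * gap_extend` (the first gap position pays both). Protein
#' scoring defaults to BLOSUM62 with open 12 / extension 3 — the
#' translation-alignment convention for coding genes; nucleotide scoring
#' defaults to match +5 / mismatch -4 with the same gap scheme.
#'
#' @param type `"protein"` or `"dna"`.
#' @param gap_open positive gap-opening cost (default 12).
#' @param gap_extend positive per-residue gap-extension cost (default 3).
#' @param matrix optional substitution matrix (symmetric, dimnames =
#'   alphabet); defaults to BLOSUM62 for protein.
#' @param match,mismatch nucleotide scores used when `type = "dna"` and no
#'   matrix is given.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(type = c("protein", "dna"), gap_open = 12,
                           gap_extend = 3, matrix = NULL, match = 5,
                           mismatch = -4) {
  type <- match.arg(type)
  if (gap_open <= 0 || gap_extend <= 0) stop("gap costs must be positive")
  if (is.null(matrix)) {
    if (type == "protein") {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      matrix <- e$BLOSUM62
    } else {
      ab <- DNA_STATES
      matrix <- matrix(mismatch, 4, 4, dimnames = list(ab, ab))
      diag(matrix) <- match
    }
  }
  if (!isTRUE(all.equal(matrix, t(matrix)))) stop("substitution matrix must be symmetric")
  structure(list(type = type, matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, alphabet = rownames(matrix)),
            class = "scoring_scheme")
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch / Gotoh three-state dynamic programming maximizing the
#' total substitution score minus affine gap costs. Traceback ties are
#' broken deterministically (diagonal, then gap-in-second, then
#' gap-in-first).
#'
#' @param a,b non-empty sequences over the scheme's alphabet.
#' @param scheme a [scoring_scheme()].
#' @return list: `a`, `b` (aligned strings with `-`), `score`.
#' @export
pairwise_affine_align <- function(a, b, scheme = scoring_scheme("protein")) {
  pa <- alignment_profile(setNames(c(a), "a"))
  pb <- alignment_profile(setNames(c(b), "b"))
  merged <- profile_align(pa, pb, scheme)
  list(a = paste(merged$profile$members[1, ], collapse = ""),
       b = paste(merged$profile$members[2, ], collapse = ""),
       score = merged$score)
}

#' Build an alignment profile
#'
#' @param seqs named character vector of (aligned or single) sequences; all
#'   must share one length when more than one is given.
#' @return list of class `alignment_profile` with a members matrix (rows =
#'   sequences, single characters).
#' @export
alignment_profile <- function(seqs) {
  if (length(seqs) == 0) stop("empty profile")
  if (is.matrix(seqs)) {
    members <- seqs
  } else {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) stop("profile members must share one length")
    members <- do.call(rbind, strsplit(unname(toupper(seqs)), ""))
    rownames(members) <- names(seqs)
  }
  structure(list(members = members), class = "alignment_profile")
}

#' Per-column state frequencies of a profile
#'
#' @param profile an [alignment_profile()].
#' @param alphabet residue alphabet (gap frequency is appended as `-`).
#' @return (|alphabet| + 1) x L matrix of frequencies summing to 1 per
#'   column.
#' @export
column_frequencies <- function(profile, alphabet = DNA_STATES) {
  m <- profile$members
  out <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    c(vapply(alphabet, function(s) mean(col == s), 0), `-` = mean(!col %in% alphabet))
  }, numeric(length(alphabet) + 1))
  rownames(out) <- c(alphabet, "-")
  out
}

# Core profile-profile Gotoh alignment; returns merged profile + score.
profile_align <- function(pa, pb, scheme) {
  A <- pa$members; B <- pb$members
  la <- ncol(A); lb <- ncol(B)
  S <- scheme$matrix
  ab <- rownames(S)
  # expected substitution score between columns, weighted by occupancy
  colstats <- function(M) {
    lapply(seq_len(ncol(M)), function(j) {
      col <- M[, j]
      res <- col[col %in% ab]
      list(f = if (length(res)) table(factor(res, levels = ab)) / length(res)
           else table(factor(character(), levels = ab)),
           occ = length(res) / length(col))
    })
  }
  sa <- colstats(A); sb <- colstats(B)
  colscore <- matrix(0, la, lb)
  for (i in seq_len(la)) {
    fi <- as.numeric(sa[[i]]$f)
    for (j in seq_len(lb)) {
      colscore[i, j] <- sa[[i]]$occ * sb[[j]]$occ *
        sum(outer(fi, as.numeric(sb[[j]]$f)) * S)
    }
  }
  go <- scheme$gap_open + scheme$gap_extend # first gap position
  ge <- scheme$gap_extend
  NEG <- -1e18
  M <- matrix(NEG, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1) # gap in B (consumes A columns)
  Y <- matrix(NEG, la + 1, lb + 1) # gap in A
  M[1, 1] <- 0
  for (i in seq_len(la)) X[i + 1, 1] <- -(scheme$gap_open + i * ge)
  for (j in seq_len(lb)) Y[1, j + 1] <- -(scheme$gap_open + j * ge)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + colscore[i, j]
      X[i + 1, j + 1] <- max(M[i, j + 1] - go, X[i, j + 1] - ge,
                             Y[i, j + 1] - go)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go, Y[i + 1, j] - ge,
                             X[i + 1, j] - go)
    }
  }
  score <- max(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
  # traceback, diagonal > up (X) > left (Y)
  ops <- character(0)
  i <- la; j <- lb
  state <- which.max(c(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1]))
  while (i > 0 || j > 0) {
    if (state == 1 && i > 0 && j > 0) {
      ops <- c("M", ops)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1; j <- j - 1
      state <- which.max(prev)
    } else if (state == 2 && i > 0) {
      ops <- c("X", ops)
      prev <- c(M[i, j + 1] - go, X[i, j + 1] - ge, Y[i, j + 1] - go)
      i <- i - 1
      state <- which.max(prev)
    } else if (state == 3 && j > 0) {
      ops <- c("Y", ops)
      prev <- c(M[i + 1, j] - go, Y[i + 1, j] - ge, X[i + 1, j] - go)
      j <- j - 1
      state <- c(1, 3, 2)[which.max(prev)]
    } else if (i > 0) {
      ops <- c("X", ops); i <- i - 1
    } else {
      ops <- c("Y", ops); j <- j - 1
    }
  }
  na <- nrow(A); nb <- nrow(B)
  newA <- matrix("-", na, length(ops))
  newB <- matrix("-", nb, length(ops))
  ia <- 0; ib <- 0
  for (k in seq_along(ops)) {
    if (ops[k] %in% c("M", "X")) { ia <- ia + 1; newA[, k] <- A[, ia] }
    if (ops[k] %in% c("M", "Y")) { ib <- ib + 1; newB[, k] <- B[, ib] }
  }
  members <- rbind(newA, newB)
  rownames(members) <- c(rownames(A), rownames(B))
  list(profile = structure(list(members = members),
                           class = "alignment_profile"),
       score = score)
}

#' Merge two alignment profiles
#'
#' Profile-profile global alignment with affine gaps, maximizing the
#' expected (occupancy-weighted) sum-of-pairs column score. Columns are only
#' ever inserted, never reordered, so within-profile alignments are
#' preserved; merging two singleton profiles is exactly
#' [pairwise_affine_align()].
#'
#' @param p1,p2 [alignment_profile()] objects over the same alphabet.
#' @param scheme a [scoring_scheme()].
#' @return the merged `alignment_profile` (score in `attr(, "score")`).
#' @export
profile_merge <- function(p1, p2, scheme = scoring_scheme("dna")) {
  if (is.null(p1$members) || nrow(p1$members) == 0 ||
      is.null(p2$members) || nrow(p2$members) == 0) stop("empty profile")
  res <- profile_align(p1, p2, scheme)
  out <- res$profile
  attr(out, "score") <- res$score
  out
}

#' Progressive multiple alignment
#'
#' Aligns sequences progressively along a UPGMA guide tree built from
#' k-mer distances (deterministic), merging profiles with
#' [profile_merge()].
#'
#' @param seqs named character vector of unaligned sequences.
#' @param scheme a [scoring_scheme()].
#' @param kmer k-mer length for the guide-tree distance (default 6,
#'   shortened automatically for short inputs).
#' @return an `alignment_profile` over all sequences.
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme("dna"), kmer = 6) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (length(seqs) == 1) return(alignment_profile(seqs))
  k <- max(1, min(kmer, min(nchar(seqs))))
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s) - k + 1
    unique(substring(s, 1:n, k:(n + k - 1)))
  })
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- length(intersect(kmers[[i]], kmers[[j]]))
      D[i, j] <- D[j, i] <- 1 - shared / min(length(kmers[[i]]),
                                             length(kmers[[j]]))
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  profs <- lapply(seq_len(n), function(i) alignment_profile(seqs[i]))
  merged <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    get_prof <- function(id) if (id < 0) profs[[-id]] else merged[[id]]
    merged[[step]] <- profile_merge(get_prof(hc$merge[step, 1]),
                                    get_prof(hc$merge[step, 2]), scheme)
  }
  out <- merged[[n - 1]]
  out$members <- out$members[names(seqs), , drop = FALSE]
  attr(out, "score") <- NULL
  out
}

#' Translation-guided alignment of coding nucleotide sequences
#'
#' Translates each coding sequence in its best reading frame (the frame
#' without internal stop codons; ties prefer frame 1), progressively aligns
#' the amino-acid sequences under BLOSUM62 with affine gaps, then expands
#' every amino-acid gap into three nucleotide gaps. Removing gaps from the
#' output recovers each input exactly; sequences with internal stops in all
#' frames are rejected and reported.
#'
#' @param records a `sequence_records` data.frame of coding nucleotide
#'   sequences.
#' @param scheme protein [scoring_scheme()] (default BLOSUM62, open 12 /
#'   extend 3).
#' @param kmer guide-tree k-mer length on the amino-acid sequences.
#' @return aligned `sequence_records` (equal-length sequences with `-`);
#'   rejected records in `attr(, "rejected")`.
#' @export
translation_align <- function(records, scheme = scoring_scheme("protein"),
                              kmer = 6) {
  frames <- lapply(records$sequence, choose_frame)
  ok <- !vapply(frames, is.null, TRUE)
  rejected <- records$taxon[!ok]
  if (length(rejected)) {
    warning("internal stop codons in all frames; rejected: ",
            paste(rejected, collapse = ", "))
  }
  rec <- records[ok, , drop = FALSE]
  frames <- frames[ok]
  if (nrow(rec) == 0) stop("no translatable sequences")
  aas <- setNames(vapply(frames, `[[`, "", "aa"), rec$taxon)
  prof <- progressive_align(aas, scheme, kmer = min(kmer, 3))
  aligned_aa <- prof$members[rec$taxon, , drop = FALSE]
  out_seq <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    codons <- frames[[i]]$codons
    ci <- 0L
    parts <- vapply(aligned_aa[i, ], function(a) {
      if (a == "-") "---" else { ci <<- ci + 1L; codons[ci] }
    }, "")
    core <- paste(parts, collapse = "")
    out_seq[i] <- core
  }
  # re-attach out-of-frame leading/trailing bases, padded with gaps
  pre <- vapply(frames, `[[`, "", "prefix")
  suf <- vapply(frames, `[[`, "", "suffix")
  wpre <- max(nchar(pre)); wsuf <- max(nchar(suf))
  pad <- function(x, w, left) {
    fill <- strrep("-", w - nchar(x))
    if (left) paste0(fill, x) else paste0(x, fill)
  }
  out_seq <- paste0(vapply(pre, pad, "", w = wpre, left = TRUE), out_seq,
                    vapply(suf, pad, "", w = wsuf, left = FALSE))
  out <- sequence_records(rec$taxon, out_seq, rec$gene[1])
  attr(out, "rejected") <- rejected
  out
}

# Pick the reading frame with no internal stops; ties prefer frame 1.
choose_frame <- function(seq) {
  s <- toupper(seq)
  for (off in 0:2) {
    body_len <- ((nchar(s) - off) %/% 3) * 3
    if (body_len < 3) next
    body <- substr(s, off + 1, off + body_len)
    codons <- substring(body, seq(1, body_len, 3), seq(3, body_len, 3))
    aa <- toupper(seqinr::translate(strsplit(body, "")[[1]]))
    internal <- aa[-length(aa)]
    if (!any(internal == "*")) {
      aa_str <- paste(aa, collapse = "")
      # a terminal stop stays with the suffix, not the alignment
      if (aa[length(aa)] == "*") {
        codons <- codons[-length(codons)]
        aa_str <- substr(aa_str, 1, nchar(aa_str) - 1)
        body_len <- body_len - 3
      }
      if (!nchar(aa_str)) next
      return(list(frame = off + 1, aa = aa_str, codons = codons,
                  prefix = substr(s, 1, off),
                  suffix = substr(s, off + body_len + 1, nchar(s))))
    }
  }
  NULL
}

#' Trim low-occupancy alignment ends
#'
#' Removes leading and trailing columns whose non-gap occupancy falls below
#' `min_occupancy`; internal columns are never touched. Idempotent.
#'
#' @param aln an [alignment_profile()], a character matrix, or aligned
#'   `sequence_records`.
#' @param min_occupancy minimum fraction of non-gap residues (default 0.5).
#' @return the trimmed object, same type as the input.
#' @export
trim_ends <- function(aln, min_occupancy = 0.5) {
  if (inherits(aln, "alignment_profile")) {
    m <- aln$members
  } else if (is.matrix(aln)) {
    m <- aln
  } else {
    m <- do.call(rbind, strsplit(aln$sequence, ""))
    rownames(m) <- aln$taxon
  }
  occ <- colMeans(matrix(!(m %in% c("-", "?")), nrow = nrow(m)))
  good <- occ >= min_occupancy
  if (!any(good)) stop("trimming would remove every column")
  keep <- min(which(good)):max(which(good))
  m2 <- m[, keep, drop = FALSE]
  if (inherits(aln, "alignment_profile")) {
    aln$members <- m2
    return(aln)
  }
  if (is.matrix(aln)) return(m2)
  sequence_records(aln$taxon, apply(m2, 1, paste, collapse = ""), aln$gene[1])
}
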