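#' Concatenate per-gene alignments into a sparse supermatrix
#'
#' Builds the concatenated character matrix underlying supermatrix
#' phylogenetics: the taxon set is the union of species across genes, and a
#' taxon absent from a gene receives `?` (fully missing) for all of that
#' gene's columns. Merging records for one species label across genes is what
#' produces composite ("chimeric") terminals, each species being represented
#' by a single terminal taxon.
#'
#' @param alignments named list, one element per gene, each either a
#'   `sequence_records` data.frame of aligned (equal-length) sequences or a
#'   character matrix of single characters with taxon rownames.
#' @param gene_order optional character vector giving partition order
#'   (default: the list's names in order).
#' @return a `supermatrix`: list with `seq` (taxa x sites single-character
#'   matrix), `partitions` (data.frame `gene`, `start`, `end`, 1-based
#'   inclusive).
#' @export
concatenate_genes <- function(alignments, gene_order = names(alignments)) {
  stopifnot(length(alignments) > 0, !is.null(names(alignments)),
            all(gene_order %in% names(alignments)))
  mats <- lapply(alignments[gene_order], as_gene_matrix)
  taxa <- sort(unique(unlist(lapply(mats, rownames))), method = "radix")
  lens <- vapply(mats, ncol, 0L)
  total <- sum(lens)
  seq <- matrix("?", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  offset <- 0L
  parts <- data.frame(gene = gene_order, start = NA_integer_, end = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(mats)) {
    cols <- (offset + 1L):(offset + lens[i])
    seq[rownames(mats[[i]]), cols] <- mats[[i]]
    parts$start[i] <- offset + 1L
    parts$end[i] <- offset + lens[i]
    offset <- offset + lens[i]
  }
  new_supermatrix(seq, parts)
}

as_gene_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)))
    if (anyDuplicated(rownames(x))) {
      stop("two records for one species within one gene: ",
           rownames(x)[duplicated(rownames(x))][1],
           " (run select_longest_per_species first)")
    }
    return(x)
  }
  taxa <- trimws(gsub("\\s+", " ", x$taxon))
  if (anyDuplicated(taxa)) {
    stop("two records for one species within one gene: ",
         taxa[duplicated(taxa)][1], " (run select_longest_per_species first)")
  }
  lens <- nchar(x$sequence)
  if (length(unique(lens)) > 1) stop("gene alignment is not rectangular")
  m <- do.call(rbind, strsplit(toupper(x$sequence), ""))
  rownames(m) <- taxa
  m
}

new_supermatrix <- function(seq, partitions) {
  stopifnot(is.matrix(seq), sum(partitions$end - partitions$start + 1) == ncol(seq))
  structure(list(seq = seq, partitions = partitions), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  st <- matrix_statistics(x)
  cat(sprintf("supermatrix: %d taxa x %d bp, %d partitions, %.1f%% missing\n",
              st$n_taxa, st$total_bp, nrow(x$partitions), st$percent_missing))
  invisible(x)
}

#' @export
dim.supermatrix <- function(x) dim(x$seq)

#' Per-taxon count of non-missing sites
#'
#' @param m a `supermatrix`.
#' @return named integer vector of present base pairs per taxon.
#' @export
present_bp <- function(m) {
  pres <- matrix(is_present(m$seq), nrow = nrow(m$seq))
  setNames(as.integer(rowSums(pres)), rownames(m$seq))
}

#' Extract one partition's columns
#'
#' @param m a `supermatrix`.
#' @param gene gene name present in `m$partitions`.
#' @return character matrix of the partition's columns.
#' @export
partition_columns <- function(m, gene) {
  i <- match(gene, m$partitions$gene)
  if (is.na(i)) stop("unknown partition: ", gene)
  m$seq[, m$partitions$start[i]:m$partitions$end[i], drop = FALSE]
}

#' Keep the longest sequence per species
#'
#' Within one gene pool, keeps for every species the record maximizing the
#' count of non-missing residues; ties are broken by earliest input order.
#'
#' @param records a `sequence_records` data.frame for a single gene.
#' @return the filtered records, one row per species, original order of first
#'   appearance preserved.
#' @export
select_longest_per_species <- function(records) {
  if (nrow(records) == 0) return(records)
  stopifnot(length(unique(records$gene)) == 1)
  taxa <- trimws(gsub("\\s+", " ", records$taxon))
  keep <- vapply(split(seq_len(nrow(records)), factor(taxa, levels = unique(taxa))),
                 function(idx) idx[which.max(records$length_bp[idx])], 0L)
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop taxa with too little total data
#'
#' Removes every taxon whose total non-missing length across all genes is
#' strictly below `threshold_bp` (default 250 bp). A per-gene variant removes
#' individual gene fragments below the threshold instead of whole taxa.
#'
#' @param m a `supermatrix`.
#' @param threshold_bp minimum total non-missing bp (default 250).
#' @param per_gene if `TRUE`, blank out sub-threshold gene fragments instead
#'   of dropping taxa (then re-apply the taxon rule to what remains).
#' @return the filtered `supermatrix`, with the removal log in
#'   `attr(, "removed")`.
#' @export
filter_min_total <- function(m, threshold_bp = 250, per_gene = FALSE) {
  if (threshold_bp < 0) stop("threshold_bp must be >= 0")
  if (per_gene) {
    for (g in m$partitions$gene) {
      cols <- partition_range(m, g)
      frag <- rowSums(matrix(is_present(m$seq[, cols, drop = FALSE]),
                             nrow = nrow(m$seq)))
      bad <- frag > 0 & frag < threshold_bp
      m$seq[bad, cols] <- "?"
    }
  }
  bp <- present_bp(m)
  drop <- bp < threshold_bp
  removed <- data.frame(taxon = names(bp)[drop], present_bp = unname(bp[drop]))
  m$seq <- m$seq[!drop, , drop = FALSE]
  attr(m, "removed") <- removed
  m
}

partition_range <- function(m, gene) {
  i <- match(gene, m$partitions$gene)
  m$partitions$start[i]:m$partitions$end[i]
}

#' Collapse taxa with identical sequences across all genes
#'
#' Taxa whose rows are identical cell-for-cell — same states where present
#' and the same missingness footprint — are collapsed to a single terminal,
#' keeping the first label in case-insensitive alphabetical order.
#'
#' @param m a `supermatrix`.
#' @return the deduplicated `supermatrix`; removed labels (with the label kept
#'   in their place) in `attr(, "removed")`.
#' @export
deduplicate_identical <- function(m) {
  key <- apply(m$seq, 1, paste, collapse = "")
  taxa <- rownames(m$seq)
  ord <- order(tolower(taxa), method = "radix")
  first <- !duplicated(key[ord])
  keep_labels <- taxa[ord][first]
  kept_for <- keep_labels[match(key, key[ord][first])]
  drop <- !(taxa %in% keep_labels)
  attr_removed <- data.frame(taxon = taxa[drop], kept = kept_for[drop])
  m$seq <- m$seq[sort(match(keep_labels, taxa)), , drop = FALSE]
  attr(m, "removed") <- attr_removed
  m
}

#' Summary statistics of a supermatrix
#'
#' Computes the bookkeeping statistics conventionally reported for sparse
#' supermatrices: total length, per-taxon completeness, per-gene coverage
#' counts and percentages (raw and rounded to the nearest integer), overall
#' percent missing, and the completeness range.
#'
#' @param m a `supermatrix`.
#' @return a list of class `matrix_stats`: `total_bp`, `n_taxa`,
#'   `mean_present_bp`, `mean_genes_per_taxon`, `percent_missing`,
#'   `percent_present`, `completeness_range`, and `per_gene` (data.frame with
#'   `gene`, `length_bp`, `n_covered`, `coverage_pct`, `coverage_pct_rounded`).
#' @export
matrix_statistics <- function(m) {
  stopifnot(nrow(m$seq) > 0)
  bp <- present_bp(m)
  total <- ncol(m$seq)
  ngene <- nrow(m$partitions)
  cover <- integer(ngene)
  genes_per_taxon <- numeric(nrow(m$seq))
  for (i in seq_len(ngene)) {
    cols <- m$partitions$start[i]:m$partitions$end[i]
    has <- rowSums(matrix(is_present(m$seq[, cols, drop = FALSE]),
                          nrow = nrow(m$seq))) > 0
    cover[i] <- sum(has)
    genes_per_taxon <- genes_per_taxon + has
  }
  per_gene <- data.frame(
    gene = m$partitions$gene,
    length_bp = m$partitions$end - m$partitions$start + 1L,
    n_covered = cover,
    coverage_pct = 100 * cover / nrow(m$seq))
  per_gene$coverage_pct_rounded <- round(per_gene$coverage_pct)
  structure(list(
    total_bp = total,
    n_taxa = nrow(m$seq),
    mean_present_bp = mean(bp),
    mean_genes_per_taxon = mean(genes_per_taxon),
    percent_present = 100 * mean(bp) / total,
    percent_missing = 100 * (1 - mean(bp) / total),
    completeness_range = c(min = min(bp), max = max(bp)),
    per_gene = per_gene), class = "matrix_stats")
}

#' @export
print.matrix_stats <- function(x, ...) {
  cat(sprintf("%d taxa x %d bp; mean %.0f bp (%.1f genes) per taxon; %.0f%% missing\n",
              x$n_taxa, x$total_bp, x$mean_present_bp, x$mean_genes_per_taxon,
              x$percent_missing))
  print(x$per_gene, row.names = FALSE)
  invisible(x)
}

#' Split a supermatrix back into per-gene alignments
#'
#' Inverse of [concatenate_genes()] (up to taxa that are entirely missing for
#' a gene, which are dropped from that gene's alignment).
#'
#' @param m a `supermatrix`.
#' @param keep_empty keep all-missing rows in each gene (default `FALSE`).
#' @return named list of character matrices.
#' @export
split_supermatrix <- function(m, keep_empty = FALSE) {
  out <- list()
  for (g in m$partitions$gene) {
    sub <- partition_columns(m, g)
    if (!keep_empty) {
      has <- rowSums(matrix(is_present(sub), nrow = nrow(sub))) > 0
      sub <- sub[has, , drop = FALSE]
    }
    out[[g]] <- sub
  }
  out
}
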