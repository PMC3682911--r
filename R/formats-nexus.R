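#' Write a supermatrix as a NEXUS DATA + SETS file
#'
#' Emits a `DATA` block (interleave off, missing `?`, gap `-`) and a `SETS`
#' block with one `charset` per partition, so the matrix round-trips
#' cell-for-cell and the partition map survives.
#'
#' @param m a `supermatrix` (non-empty).
#' @param path output path.
#' @export
write_nexus_matrix <- function(m, path) {
  if (nrow(m$seq) == 0 || ncol(m$seq) == 0) stop("empty matrix")
  # spaces become underscores (the NEXUS token convention); anything else
  # illegal is quoted
  taxa <- gsub(" ", "_", rownames(m$seq))
  quoted <- vapply(taxa, function(x) {
    if (grepl("[^A-Za-z0-9_.]", x)) paste0("'", gsub("'", "''", x), "'") else x
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m$seq), ncol(m$seq)), con)
  writeLines("  FORMAT DATATYPE=DNA MISSING=? GAP=-;", con)
  writeLines("  MATRIX", con)
  rows <- apply(m$seq, 1, paste, collapse = "")
  pad <- max(nchar(quoted)) + 2L
  writeLines(paste0("    ", formatC(quoted, width = -pad), rows), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  writeLines("BEGIN SETS;", con)
  writeLines(sprintf("  charset %s = %d-%d;", m$partitions$gene,
                     m$partitions$start, m$partitions$end), con)
  writeLines("END;", con)
  invisible(path)
}

#' Read a NEXUS DATA (+ SETS) file back into a supermatrix
#'
#' @param path path written by [write_nexus_matrix()] (or any simple
#'   non-interleaved NEXUS DNA matrix with an optional charset block).
#' @return a `supermatrix`.
#' @export
read_nexus_matrix <- function(path) {
  dat <- ape::read.nexus.data(path)
  seq <- do.call(rbind, lapply(dat, toupper))
  rownames(seq) <- names(dat)
  lines <- readLines(path, warn = FALSE)
  cs <- grep("^\\s*charset", lines, ignore.case = TRUE, value = TRUE)
  if (length(cs)) {
    gene <- sub("^\\s*charset\\s+(\\S+)\\s*=.*$", "\\1", cs, ignore.case = TRUE)
    rng <- regmatches(cs, regexpr("[0-9]+\\s*-\\s*[0-9]+", cs))
    start <- as.integer(sub("-.*", "", gsub("\\s", "", rng)))
    end <- as.integer(sub(".*-", "", gsub("\\s", "", rng)))
    parts <- data.frame(gene = gene, start = start, end = end,
                        stringsAsFactors = FALSE)
  } else {
    parts <- data.frame(gene = "all", start = 1L, end = ncol(seq),
                        stringsAsFactors = FALSE)
  }
  new_supermatrix(seq, parts)
}

#' Write a RAxML-style partition file
#'
#' One line per partition, `DNA, name = start-end`; codon subsets use the
#' `start-end\3` stride syntax with an offset per position.
#'
#' @param partitions a partition data.frame (`gene`, `start`, `end`) or a
#'   `supermatrix`; an optional `codon` column with value `"by_position"`
#'   expands a coding gene into three codon-position subsets.
#' @param path output path.
#' @export
write_partition_file <- function(partitions, path) {
  if (inherits(partitions, "supermatrix")) partitions <- partitions$partitions
  lines <- character(0)
  for (i in seq_len(nrow(partitions))) {
    g <- partitions$gene[i]; s <- partitions$start[i]; e <- partitions$end[i]
    codon <- if ("codon" %in% names(partitions)) partitions$codon[i] else "none"
    if (identical(codon, "by_position")) {
      lines <- c(lines, sprintf("DNA, %s_pos%d = %d-%d\\3", g, 1:3, s + 0:2, e))
    } else {
      lines <- c(lines, sprintf("DNA, %s = %d-%d", g, s, e))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
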