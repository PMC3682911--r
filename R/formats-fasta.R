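#' Read one gene's sequences from a FASTA file
#'
#' Reads a per-gene FASTA pool into a sequence-record table. Residues are
#' upper-cased; gap (`-`) and missing (`?`, `N`) characters are preserved as
#' given. `length_bp` counts non-gap, non-missing residues only, which is the
#' quantity used by the minimum-data filter during supermatrix assembly.
#'
#' @param path path to a FASTA file.
#' @param gene gene name to attach to every record.
#' @return a data.frame with columns `taxon`, `gene`, `sequence`, `length_bp`,
#'   one row per FASTA entry, in file order.
#' @export
read_gene_fasta <- function(path, gene) {
  stopifnot(file.exists(path))
  if (!any(startsWith(readLines(path, warn = FALSE), ">"))) {
    warning("empty FASTA file: ", path)
    return(sequence_records(character(), character(), gene))
  }
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  labels <- trimws(gsub("\\s+", " ", names(seqs)))
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    stop("duplicate taxon label(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  sequence_records(labels, toupper(vapply(seqs, as.character, "")), gene)
}

#' Build a sequence-record table
#'
#' @param taxon character vector of taxon labels.
#' @param sequence character vector of residue strings.
#' @param gene gene name (recycled).
#' @return data.frame of class `sequence_records`.
#' @export
sequence_records <- function(taxon, sequence, gene) {
  stopifnot(length(taxon) == length(sequence))
  if (length(taxon) && any(!nzchar(taxon))) stop("empty taxon label")
  df <- data.frame(taxon = as.character(taxon),
                   gene = rep_len(gene, length(taxon)),
                   sequence = toupper(as.character(sequence)),
                   stringsAsFactors = FALSE)
  df$length_bp <- count_present(df$sequence)
  class(df) <- c("sequence_records", "data.frame")
  df
}

count_present <- function(sequence) {
  vapply(strsplit(sequence, ""), function(s) sum(is_present(s)), 0L)
}

#' Write sequence records to FASTA
#'
#' @param records a `sequence_records` data.frame (or any data.frame with
#'   `taxon` and `sequence` columns).
#' @param path output path.
#' @export
write_gene_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(c(paste0(">", records$taxon[i]), records$sequence[i]), con)
  }
  invisible(path)
}
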