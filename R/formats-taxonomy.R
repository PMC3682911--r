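#' Read a ranked taxonomy table
#'
#' Reads a TSV mapping species to genus / subfamily / family (plus optional
#' `higher_taxon` and `incertae_sedis` columns). Every non-incertae-sedis row
#' must carry a family; species must be unique.
#'
#' @param path path to a tab-separated file with a header containing at least
#'   `species`, `genus`, `family` (and optionally `subfamily`,
#'   `higher_taxon`, `incertae_sedis`).
#' @return a data.frame of class `taxonomy_table`.
#' @export
read_taxonomy <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = character(0))
  validate_taxonomy(tab)
}

#' Validate (and normalize) a taxonomy data.frame
#'
#' @param tab data.frame with taxonomy columns as in [read_taxonomy()].
#' @return the normalized `taxonomy_table`.
#' @export
validate_taxonomy <- function(tab) {
  need <- c("species", "genus", "family")
  if (!all(need %in% names(tab))) {
    stop("taxonomy must have columns: ", paste(need, collapse = ", "))
  }
  if (!"subfamily" %in% names(tab)) tab$subfamily <- ""
  if (!"higher_taxon" %in% names(tab)) tab$higher_taxon <- ""
  if (!"incertae_sedis" %in% names(tab)) tab$incertae_sedis <- FALSE
  tab$incertae_sedis <- as.logical(tab$incertae_sedis)
  tab$incertae_sedis[is.na(tab$incertae_sedis)] <- FALSE
  for (col in c("species", "genus", "subfamily", "family", "higher_taxon")) {
    tab[[col]] <- trimws(as.character(tab[[col]]))
    tab[[col]][is.na(tab[[col]])] <- ""
  }
  dup <- tab$species[duplicated(tab$species)]
  if (length(dup)) stop("duplicate species: ", paste(unique(dup), collapse = ", "))
  bad <- !tab$incertae_sedis & !nzchar(tab$family)
  if (any(bad)) {
    stop("missing family for non-incertae-sedis species: ",
         paste(tab$species[bad], collapse = ", "))
  }
  class(tab) <- c("taxonomy_table", "data.frame")
  tab
}

#' Write a taxonomy table to TSV
#'
#' @param tab a `taxonomy_table`.
#' @param path output path.
#' @export
write_taxonomy <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
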