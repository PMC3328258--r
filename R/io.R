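#' Read a FASTA file into a tibble
#'
#' @param path FASTA file (plain text).
#' @return Tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq` (uppercase).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path, call. = FALSE)
  tibble(id = ids, seq = toupper(as.character(x)))
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param seqs Named character vector, or tibble with `id` and `seq`.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' @param path TSV with header columns `gene_id`, `term` and optionally
#'   `description`.
#' @return Tibble with one row per (gene, term).
#' @export
read_annotation_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "term")
  if (!all(need %in% names(x))) {
    stop("annotation table must have columns gene_id and term", call. = FALSE)
  }
  x
}

#' Read an externally supplied 1:1 orthologue list
#'
#' Stand-in for orthologue sets retrieved from comparative-genomics
#' databases: a TSV with header columns `id_a` and `id_b`, one row per
#' 1:1 pair.
#'
#' @param path TSV file.
#' @return Tibble with `id_a`, `id_b`.
#' @export
read_ortholog_list <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("id_a", "id_b") %in% names(x))) {
    stop("orthologue list must have columns id_a and id_b", call. = FALSE)
  }
  if (anyDuplicated(x$id_a) || anyDuplicated(x$id_b)) {
    stop("orthologue list is not 1:1 (duplicated ids)", call. = FALSE)
  }
  dplyr::select(x, "id_a", "id_b")
}
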