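#' Protein-guided pairwise codon alignment
#'
#' Translates both open reading frames, aligns the proteins by global
#' affine-gap dynamic programming (BLOSUM62, Needleman-Wunsch) and back-maps
#' the protein alignment onto codons, so gaps occur only in whole-codon
#' units. A terminal stop codon on either ORF is stripped before
#' alignment; an internal stop codon is an error (it would be a
#' frame-shift or misannotation upstream).
#'
#' @param orf_a,orf_b In-frame nucleotide strings (lengths multiples of 3).
#' @param pair_id Identifier carried into downstream tables.
#' @param gap_open,gap_extend Affine gap penalties for the protein
#'   alignment.
#' @return Object of class `codon_alignment`: gapped codon strings
#'   `aligned_a`, `aligned_b` (gap codon `"---"`), a per-column mask
#'   tibble, `kept_codons`, and a `discarded` flag (set by
#'   [filter_columns()]).
#' @export
align_codons <- function(orf_a, orf_b, pair_id = "pair", gap_open = 11,
                         gap_extend = 1) {
  a <- strip_terminal_stop(orf_a, "orf_a")
  b <- strip_terminal_stop(orf_b, "orf_b")
  pa <- translate_codons(a)
  pb <- translate_codons(b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    type = "global", substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  ga <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  cod_a <- split_codons(a)
  cod_b <- split_codons(b)
  ia <- ib <- 0L
  out_a <- out_b <- character(length(ga))
  for (k in seq_along(ga)) {
    if (ga[k] == "-") {
      out_a[k] <- "---"
    } else {
      ia <- ia + 1L
      out_a[k] <- cod_a[ia]
    }
    if (gb[k] == "-") {
      out_b[k] <- "---"
    } else {
      ib <- ib + 1L
      out_b[k] <- cod_b[ib]
    }
  }
  new_codon_alignment(pair_id, out_a, out_b)
}

strip_terminal_stop <- function(seq, what) {
  validate_nucleotides(seq, what)
  cods <- split_codons(seq)
  if (length(cods) > 1 && cods[length(cods)] %in% stop_codons()) {
    cods <- cods[-length(cods)]
  }
  internal <- which(cods %in% stop_codons())
  if (length(internal) > 0) {
    stop(what, ": internal stop codon at codon position ", internal[1], call. = FALSE)
  }
  if (length(cods) < 1) stop(what, ": no codons left", call. = FALSE)
  paste(cods, collapse = "")
}

new_codon_alignment <- function(pair_id, codons_a, codons_b,
                                keep = NULL, reason = NULL, discarded = FALSE) {
  stopifnot(length(codons_a) == length(codons_b))
  if (is.null(keep)) keep <- rep(TRUE, length(codons_a))
  if (is.null(reason)) reason <- rep(NA_character_, length(codons_a))
  structure(
    list(
      pair_id = pair_id,
      aligned_a = paste(codons_a, collapse = ""),
      aligned_b = paste(codons_b, collapse = ""),
      column_mask = tibble(
        column = seq_along(codons_a), codon_a = codons_a, codon_b = codons_b,
        keep = keep, reason = reason
      ),
      kept_codons = sum(keep),
      discarded = discarded
    ),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(
    "<codon_alignment> ", x$pair_id, ": ", nrow(x$column_mask),
    " columns, ", x$kept_codons, " kept",
    if (x$discarded) " (DISCARDED)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Filter codon-alignment columns
#'
#' Drops every gap column, then drops gap-free runs of at most
#' `min_run_codons` kept columns flanked by gaps or alignment ends (short
#' aligned islands between gaps are unreliable, the codon-level reading of
#' a 7 bp nucleotide rule). If fewer than `min_alignment_codons` columns
#' survive, the whole alignment is marked discarded. Filtering is
#' idempotent.
#'
#' @param alignment A [align_codons()] result.
#' @param min_run_codons Maximum length of a dropped short run (default 3
#'   codons).
#' @param min_alignment_codons Minimum surviving length (default 30 codons,
#'   i.e. 30 amino acids).
#' @return The alignment with an updated column mask, `kept_codons` and
#'   `discarded` flag.
#' @export
filter_columns <- function(alignment, min_run_codons = 3,
                           min_alignment_codons = 30) {
  stopifnot(inherits(alignment, "codon_alignment"))
  m <- alignment$column_mask
  keep <- m$keep
  reason <- m$reason
  is_gap <- m$codon_a == "---" | m$codon_b == "---"
  keep[is_gap] <- FALSE
  reason[is_gap] <- "gap"
  # maximal runs of currently kept columns
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] <= min_run_codons) {
      idx <- starts[k]:ends[k]
      keep[idx] <- FALSE
      reason[idx] <- "short_run"
    }
  }
  out <- new_codon_alignment(
    alignment$pair_id, m$codon_a, m$codon_b,
    keep = keep, reason = reason
  )
  out$discarded <- out$kept_codons < min_alignment_codons
  out
}

# 2 x kept-columns character matrix of codons
kept_codon_matrix <- function(alignment) {
  m <- alignment$column_mask[alignment$column_mask$keep, , drop = FALSE]
  rbind(a = m$codon_a, b = m$codon_b)
}

# accept a codon_alignment or two gap-free in-frame strings
as_codon_alignment <- function(x, y = NULL, pair_id = "pair") {
  if (inherits(x, "codon_alignment")) {
    return(x)
  }
  if (is.null(y)) stop("need a codon_alignment or two codon strings", call. = FALSE)
  a <- split_codons(x)
  b <- split_codons(y)
  if (length(a) != length(b)) stop("codon sequences differ in length", call. = FALSE)
  new_codon_alignment(pair_id, a, b)
}

#' Write a filter report TSV
#'
#' @param alignments List of filtered [codon_alignment] objects.
#' @param path Output TSV.
#' @export
write_filter_report <- function(alignments, path) {
  rep <- purrr::map(alignments, function(al) {
    m <- al$column_mask
    tibble(
      pair_id = al$pair_id, kept_codons = al$kept_codons,
      dropped_gap = sum(!m$keep & m$reason == "gap", na.rm = TRUE),
      dropped_short_run = sum(!m$keep & m$reason == "short_run", na.rm = TRUE),
      discarded_flag = al$discarded
    )
  }) |> dplyr::bind_rows()
  readr::write_tsv(rep, path)
  invisible(path)
}

#' Write an aligned codon pair as FASTA
#'
#' @param alignment A [codon_alignment].
#' @param path Output FASTA.
#' @export
write_alignment_fasta <- function(alignment, path) {
  write_fasta(setNames(
    c(alignment$aligned_a, alignment$aligned_b),
    paste0(alignment$pair_id, c("_a", "_b"))
  ), path)
}
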