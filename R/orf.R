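#' Find open reading frames
#'
#' Enumerates maximal ORFs in each input sequence. In the default
#' start-to-stop mode an ORF runs from the first ATG of a stop-free codon
#' run to the following stop codon (stop included). With
#' `open_ended = TRUE`, every maximal stop-free codon run is also reported
#' as an open-ended ORF that may lack the start and/or stop codon --
#' fragmented EST-cluster consensus sequences may contain only a truncated
#' portion of the true coding region, so the start-to-stop definition is
#' reserved for full-length cDNA inputs.
#'
#' @param seqs Tibble with columns `id` and `seq`, or a named character
#'   vector of nucleotide sequences (A, C, G, T, N).
#' @param min_codons Minimum ORF length in codons (stop codon included when
#'   present).
#' @param strands `"forward"` (default; cDNA and EST-cluster inputs are
#'   oriented) or `"both"`.
#' @param open_ended Also enumerate ORFs lacking start and/or stop at run
#'   boundaries.
#' @return Tibble with one row per ORF: `parent_id`, `orf_id`, `frame`
#'   (+1..+3, -1..-3), `start`/`end` (0-based half-open, forward strand),
#'   `codons` (in-frame nucleotide string, reverse-complemented for minus
#'   frames), `n_codons`, `has_start`, `has_stop`, `has_n` (any codon
#'   containing N, retained in coordinates but flagged for exclusion from
#'   substitution counting). Sorted by length descending, then smaller
#'   start, then frame.
#' @export
find_orfs <- function(seqs, min_codons = 1, strands = c("forward", "both"),
                      open_ended = FALSE) {
  strands <- match.arg(strands)
  if (min_codons < 1) stop("min_codons must be >= 1", call. = FALSE)
  seqs <- as_seq_tibble(seqs)
  out <- purrr::map(seq_len(nrow(seqs)), function(k) {
    id <- seqs$id[k]
    s <- toupper(seqs$seq[k])
    validate_nucleotides(s, paste0("sequence '", id, "'"))
    frames <- if (strands == "forward") 1:3 else c(1:3, -1:-3)
    purrr::map(frames, function(fr) orfs_in_frame(id, s, fr, open_ended))
  })
  out <- dplyr::bind_rows(purrr::flatten(out))
  if (nrow(out) == 0) {
    return(empty_orf_tibble())
  }
  out <- out[out$n_codons >= min_codons, , drop = FALSE]
  frame_rank <- match(out$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  out <- out[order(-out$n_codons, out$start, frame_rank), , drop = FALSE]
  out$orf_id <- paste(out$parent_id, out$frame, out$start, sep = ":")
  dplyr::select(
    out, "parent_id", "orf_id", "frame", "start", "end", "codons",
    "n_codons", "has_start", "has_stop", "has_n"
  )
}

empty_orf_tibble <- function() {
  tibble(
    parent_id = character(), orf_id = character(), frame = integer(),
    start = integer(), end = integer(), codons = character(),
    n_codons = integer(), has_start = logical(), has_stop = logical(),
    has_n = logical()
  )
}

as_seq_tibble <- function(seqs) {
  if (is.data.frame(seqs)) {
    stopifnot(all(c("id", "seq") %in% names(seqs)))
    out <- tibble(id = seqs$id, seq = seqs$seq)
  } else {
    if (is.null(names(seqs))) {
      names(seqs) <- if (length(seqs) == 1) "seq1" else paste0("seq", seq_along(seqs))
    }
    out <- tibble(id = names(seqs), seq = unname(seqs))
  }
  if (anyDuplicated(out$id)) stop("sequence ids must be unique", call. = FALSE)
  if (any(nchar(out$seq) == 0)) stop("empty sequence", call. = FALSE)
  out
}

# enumerate ORFs of one sequence in one frame; coordinates on the forward
# strand, 0-based half-open
orfs_in_frame <- function(id, s, frame, open_ended) {
  n <- nchar(s)
  if (frame > 0) {
    work <- s
    off <- frame - 1L
  } else {
    work <- revcomp(s)
    off <- -frame - 1L
  }
  usable <- n - off
  ncod <- usable %/% 3
  if (ncod < 1) {
    return(NULL)
  }
  starts <- off + 3 * (seq_len(ncod) - 1) + 1
  cods <- substring(work, starts, starts + 2)
  is_stop <- cods %in% stop_codons()
  runs <- split(seq_len(ncod), cumsum(c(0, head(is_stop, -1))))
  res <- list()
  for (r in runs) {
    r_clean <- r[!is_stop[r]]
    if (length(r_clean) == 0) next
    # a run carries its terminating stop as its last element when present
    stop_idx <- if (any(is_stop[r])) r[is_stop[r]][1] else NA_integer_
    atg <- r_clean[cods[r_clean] == "ATG"]
    emit <- list()
    if (!is.na(stop_idx) && length(atg) > 0) {
      emit[[length(emit) + 1L]] <- c(first = atg[1], last = stop_idx, hs = 1, he = 1)
    }
    if (open_ended) {
      first <- r_clean[1]
      last <- if (!is.na(stop_idx)) stop_idx else r_clean[length(r_clean)]
      hs <- length(atg) > 0 && atg[1] == first
      if (!(length(emit) > 0 && emit[[1]]["first"] == first)) {
        emit[[length(emit) + 1L]] <- c(first = first, last = last, hs = as.numeric(hs), he = as.numeric(!is.na(stop_idx)))
      }
    }
    for (e in emit) {
      w_start <- off + 3 * (e[["first"]] - 1)
      w_end <- off + 3 * e[["last"]]
      codstr <- substr(work, w_start + 1, w_end)
      if (frame > 0) {
        g_start <- w_start
        g_end <- w_end
      } else {
        g_start <- n - w_end
        g_end <- n - w_start
      }
      res[[length(res) + 1L]] <- tibble(
        parent_id = id, frame = as.integer(frame),
        start = as.integer(g_start), end = as.integer(g_end),
        codons = codstr, n_codons = as.integer((w_end - w_start) / 3),
        has_start = e[["hs"]] == 1, has_stop = e[["he"]] == 1,
        has_n = grepl("N", codstr, fixed = TRUE)
      )
    }
  }
  if (length(res)) dplyr::bind_rows(res) else NULL
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Select one ORF per transcript by homology evidence
#'
#' Implements the full-length-cDNA selection strategy: the ORF owning the
#' best similarity hit (lowest e-value, ties by higher bitscore, then
#' longer ORF, then smaller start) wins; transcripts whose ORFs have no hit
#' fall back to the longest ORF when `fallback_longest` is set.
#'
#' @param orfs [find_orfs()] output (may span many transcripts).
#' @param hits Tibble with columns `orf_id`, `evalue`, `bitscore` (may be
#'   empty or `NULL`).
#' @param fallback_longest Select the longest ORF for hit-less transcripts.
#' @return Tibble with one selected ORF per transcript plus a
#'   `selection_rule` column (`"homology"` or `"longest"`); transcripts
#'   with no hit are absent when `fallback_longest = FALSE`.
#' @export
select_orf_by_homology <- function(orfs, hits = NULL, fallback_longest = TRUE) {
  if (nrow(orfs) == 0) {
    stop("no ORF structure in input: transcript discarded upstream", call. = FALSE)
  }
  if (is.null(hits)) {
    hits <- tibble(orf_id = character(), evalue = numeric(), bitscore = numeric())
  }
  ranked <- dplyr::left_join(orfs, dplyr::select(hits, "orf_id", "evalue", "bitscore"),
    by = "orf_id"
  )
  picked <- ranked |>
    dplyr::group_by(.data$parent_id) |>
    dplyr::group_modify(function(d, key) {
      with_hit <- d[!is.na(d$evalue), , drop = FALSE]
      if (nrow(with_hit) > 0) {
        o <- order(with_hit$evalue, -with_hit$bitscore, -with_hit$n_codons, with_hit$start)
        out <- with_hit[o[1], , drop = FALSE]
        out$selection_rule <- "homology"
        return(out)
      }
      if (!fallback_longest) {
        return(d[0, , drop = FALSE])
      }
      o <- order(-d$n_codons, d$start)
      out <- d[o[1], , drop = FALSE]
      out$selection_rule <- "longest"
      out
    }) |>
    dplyr::ungroup()
  dplyr::select(picked, -"evalue", -"bitscore")
}

#' Select one ORF per fragment by reference reading frame
#'
#' Implements the EST-fragment selection strategy: among the fragment's
#' ORFs (including open-ended ones) in the same frame as the best-scoring
#' reference hit, the ORF with the longest overlap with the hit interval is
#' selected. Fragments with no ORF in the hit frame are reported with a
#' `"no_frame_match"` rule and NA coordinates, to be excluded downstream.
#'
#' @param orfs [find_orfs()] output (typically `open_ended = TRUE`).
#' @param reference_hits Tibble with one row per fragment: `parent_id`,
#'   `start`, `end` (0-based half-open aligned interval on the fragment),
#'   `frame` (frame of the reference hit on the fragment).
#' @param seq_lengths Optional named vector of fragment lengths used to
#'   validate hit intervals.
#' @return Tibble with one row per row of `reference_hits`: the selected
#'   ORF columns (NA when absent), `overlap` (nt) and `selection_rule`.
#' @export
select_orf_by_reference_frame <- function(orfs, reference_hits, seq_lengths = NULL) {
  stopifnot(all(c("parent_id", "start", "end", "frame") %in% names(reference_hits)))
  if (any(reference_hits$end <= reference_hits$start) || any(reference_hits$start < 0)) {
    stop("reference hit interval is empty or negative", call. = FALSE)
  }
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[reference_hits$parent_id]
    if (any(is.na(len)) || any(reference_hits$end > len)) {
      stop("reference hit interval outside the record", call. = FALSE)
    }
  }
  purrr::map(seq_len(nrow(reference_hits)), function(k) {
    h <- reference_hits[k, ]
    cand <- orfs[orfs$parent_id == h$parent_id & orfs$frame == h$frame, , drop = FALSE]
    if (nrow(cand) > 0) {
      cand$overlap <- pmax(0L, pmin(cand$end, h$end) - pmax(cand$start, h$start))
      cand <- cand[cand$overlap > 0, , drop = FALSE]
    }
    if (nrow(cand) == 0) {
      return(tibble(
        parent_id = h$parent_id, orf_id = NA_character_, frame = h$frame,
        start = NA_integer_, end = NA_integer_, codons = NA_character_,
        n_codons = NA_integer_, has_start = NA, has_stop = NA, has_n = NA,
        overlap = 0L, selection_rule = "no_frame_match"
      ))
    }
    # ties on overlap: prefer complete ORFs, then longer, then leftmost
    completeness <- cand$has_start + cand$has_stop
    o <- order(-cand$overlap, -completeness, -cand$n_codons, cand$start)
    out <- cand[o[1], , drop = FALSE]
    out$selection_rule <- "frame_match"
    out
  }) |> dplyr::bind_rows()
}

#' Write an ORF report TSV
#'
#' Coordinates are written 1-based inclusive (`start1`, `end1`); internal
#' coordinates stay 0-based half-open.
#'
#' @param orfs Tibble of ORFs (optionally with `selection_rule`).
#' @param path Output TSV.
#' @export
write_orf_report <- function(orfs, path) {
  rep <- tibble(
    parent_id = orfs$parent_id, frame = orfs$frame,
    start1 = orfs$start + 1L, end1 = orfs$end,
    n_codons = orfs$n_codons, has_start = orfs$has_start,
    has_stop = orfs$has_stop,
    selection_rule = if ("selection_rule" %in% names(orfs)) orfs$selection_rule else NA_character_
  )
  readr::write_tsv(rep, path)
  invisible(path)
}
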