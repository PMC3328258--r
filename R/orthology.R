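#' Read BLAST tabular (outfmt 6) hits
#'
#' Parses the 12-column tabular dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). File
#' coordinates are 1-based inclusive; they are converted to the package's
#' 0-based half-open convention. Subject coordinates given in reverse
#' (minus-strand translated hits) are normalised with `frame = -1`.
#'
#' @param path Tabular file without header.
#' @return Tibble of hit records: `query_id`, `subject_id`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`, `frame`.
#' @export
read_blast_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      query_id = character(), subject_id = character(), pident = numeric(),
      length = integer(), mismatch = integer(), gapopen = integer(),
      qstart = integer(), qend = integer(), sstart = integer(),
      send = integer(), evalue = numeric(), bitscore = numeric(),
      frame = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop("line ", bad, ": expected 12 tab-separated columns, found ", nf[bad],
      call. = FALSE
    )
  }
  m <- do.call(rbind, fields)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      stop("line ", which(is.na(v))[1], ": non-numeric ", what, call. = FALSE)
    }
    v
  }
  evalue <- num(11, "e-value")
  if (any(evalue < 0)) stop("negative e-value", call. = FALSE)
  sstart_raw <- num(9, "sstart")
  send_raw <- num(10, "send")
  rev_s <- sstart_raw > send_raw
  s_lo <- as.integer(pmin(sstart_raw, send_raw) - 1)
  s_hi <- as.integer(pmax(sstart_raw, send_raw))
  tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pident = num(3, "pident"), length = as.integer(num(4, "length")),
    mismatch = as.integer(num(5, "mismatch")), gapopen = as.integer(num(6, "gapopen")),
    qstart = as.integer(num(7, "qstart") - 1), qend = as.integer(num(8, "qend")),
    sstart = s_lo, send = s_hi,
    evalue = evalue, bitscore = num(12, "bitscore"),
    frame = ifelse(rev_s, -1L, 1L)
  )
}

# Karlin-Altschul constants for ungapped BLOSUM62 statistics; the built-in
# search reports approximate e-values -- ingested BLAST tabular files are
# authoritative when available.
ka_params <- function() list(lambda = 0.3176, K = 0.134)

ka_evalue <- function(score, m, n_db) {
  p <- ka_params()
  p$K * m * n_db * exp(-p$lambda * score)
}

ka_bitscore <- function(score) {
  p <- ka_params()
  (p$lambda * score - log(p$K)) / log(2)
}

#' Built-in exact local-alignment similarity search
#'
#' Smith-Waterman best local alignment of every query against every
#' subject (BLOSUM62, affine gaps), with bitscores and Karlin-Altschul
#' e-values from standard ungapped BLOSUM62 constants. A drop-in
#' replacement for an external search tool so the orthology stage needs no
#' external binary; e-values are approximate and documented as such.
#'
#' @param queries,subjects Protein sequences: tibble with `id`, `seq`, or a
#'   named character vector.
#' @param e_max Report only hits with e-value <= `e_max`.
#' @param gap_open,gap_extend Affine gap penalties.
#' @param with_intervals Compute aligned intervals (needs a second
#'   traceback pass per reported hit; scores-only is faster).
#' @return Tibble of hit records: `query_id`, `subject_id`, `score`,
#'   `bitscore`, `evalue`, and (with intervals) `qstart`, `qend`, `sstart`,
#'   `send` in 0-based half-open coordinates.
#' @export
local_align_search <- function(queries, subjects, e_max = 1e-20,
                               gap_open = 11, gap_extend = 1,
                               with_intervals = TRUE) {
  queries <- as_seq_tibble2(queries)
  subjects <- as_seq_tibble2(subjects)
  if (nrow(queries) == 0 || nrow(subjects) == 0) {
    return(empty_hit_tibble())
  }
  mat <- blosum62_matrix()
  subj_set <- Biostrings::AAStringSet(setNames(subjects$seq, subjects$id))
  n_db <- sum(nchar(subjects$seq))
  res <- list()
  for (k in seq_len(nrow(queries))) {
    sc <- Biostrings::pairwiseAlignment(subj_set, Biostrings::AAString(queries$seq[k]),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
    ev <- ka_evalue(sc, nchar(queries$seq[k]), n_db)
    keep <- which(ev <= e_max)
    for (j in keep) {
      row <- tibble(
        query_id = queries$id[k], subject_id = subjects$id[j],
        score = sc[j], bitscore = ka_bitscore(sc[j]), evalue = ev[j]
      )
      if (with_intervals) {
        al <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(subjects$seq[j]), Biostrings::AAString(queries$seq[k]),
          type = "local", substitutionMatrix = mat,
          gapOpening = gap_open, gapExtension = gap_extend
        )
        row$qstart <- Biostrings::start(Biostrings::subject(al)) - 1L
        row$qend <- Biostrings::end(Biostrings::subject(al))
        row$sstart <- Biostrings::start(Biostrings::pattern(al)) - 1L
        row$send <- Biostrings::end(Biostrings::pattern(al))
      }
      res[[length(res) + 1L]] <- row
    }
  }
  if (length(res) == 0) {
    return(empty_hit_tibble(with_intervals))
  }
  dplyr::bind_rows(res)
}

empty_hit_tibble <- function(with_intervals = TRUE) {
  out <- tibble(
    query_id = character(), subject_id = character(), score = numeric(),
    bitscore = numeric(), evalue = numeric()
  )
  if (with_intervals) {
    out$qstart <- integer()
    out$qend <- integer()
    out$sstart <- integer()
    out$send <- integer()
  }
  out
}

as_seq_tibble2 <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    tibble(id = x$id, seq = x$seq)
  } else {
    tibble(id = names(x), seq = unname(x))
  }
}

blosum62_matrix <- function() {
  if (is.null(.cr$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .cr$blosum62 <- e$BLOSUM62
  }
  .cr$blosum62
}

#' Reciprocal best hits
#'
#' Builds 1:1 orthologue pairs from two directed hit lists: (a, b) is a
#' pair iff b is a's unique best hit (lowest e-value, ties broken by higher
#' bitscore) in the A-to-B search and a is b's unique best hit in the
#' B-to-A search, both with e-value <= `e_max`. Remaining exact ties are
#' treated as ambiguous and the query is excluded (conservative 1:1).
#' Multiple HSPs between the same ordered pair are reduced to the
#' best-scoring one first.
#'
#' @param hits_ab,hits_ba Hit tibbles with `query_id`, `subject_id`,
#'   `evalue`, `bitscore` (from [local_align_search()] or
#'   [read_blast_tabular()]).
#' @param e_max E-value threshold applied to both directions.
#' @return Tibble of pairs: `id_a`, `id_b`, `evalue_ab`, `evalue_ba`,
#'   `bitscore_ab`, `bitscore_ba`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, e_max = 1e-20) {
  best_ab <- best_per_query(hits_ab, e_max)
  best_ba <- best_per_query(hits_ba, e_max)
  if (nrow(best_ab) == 0 || nrow(best_ba) == 0) {
    return(tibble(
      id_a = character(), id_b = character(), evalue_ab = numeric(),
      evalue_ba = numeric(), bitscore_ab = numeric(), bitscore_ba = numeric()
    ))
  }
  joined <- dplyr::inner_join(
    dplyr::rename(best_ab,
      id_a = "query_id", id_b = "subject_id",
      evalue_ab = "evalue", bitscore_ab = "bitscore"
    ),
    dplyr::rename(best_ba,
      id_b = "query_id", id_a = "subject_id",
      evalue_ba = "evalue", bitscore_ba = "bitscore"
    ),
    by = c("id_a", "id_b")
  )
  dplyr::arrange(
    dplyr::select(
      joined, "id_a", "id_b", "evalue_ab", "evalue_ba",
      "bitscore_ab", "bitscore_ba"
    ),
    .data$id_a
  )
}

# unique best hit per query: best HSP per ordered pair, then best subject;
# queries whose top two subjects tie exactly are dropped as ambiguous
best_per_query <- function(hits, e_max) {
  h <- hits[hits$evalue <= e_max, c("query_id", "subject_id", "evalue", "bitscore")]
  if (nrow(h) == 0) {
    return(h)
  }
  h <- h |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  h |>
    dplyr::group_by(.data$query_id) |>
    dplyr::group_modify(function(d, key) {
      o <- order(d$evalue, -d$bitscore)
      if (nrow(d) > 1 &&
        d$evalue[o[1]] == d$evalue[o[2]] &&
        d$bitscore[o[1]] == d$bitscore[o[2]]) {
        return(d[0, , drop = FALSE]) # ambiguous best: exclude
      }
      d[o[1], , drop = FALSE]
    }) |>
    dplyr::ungroup()
}

#' Write an orthologue-pair TSV
#'
#' @param pairs [reciprocal_best_hits()] output.
#' @param path Output TSV.
#' @export
write_ortholog_pairs <- function(pairs, path) {
  readr::write_tsv(
    dplyr::select(pairs, "id_a", "id_b", "evalue_ab", "evalue_ba"), path
  )
  invisible(path)
}

# score-matrix RBH between two small protein sets, exploiting the symmetry
# of the Smith-Waterman score so both directions come from one pass
rbh_search <- function(seqs_a, seqs_b, e_max = 1e-20, gap_open = 11, gap_extend = 1) {
  a <- as_seq_tibble2(seqs_a)
  b <- as_seq_tibble2(seqs_b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(reciprocal_best_hits(empty_hit_tibble(FALSE), empty_hit_tibble(FALSE), e_max))
  }
  mat <- blosum62_matrix()
  bset <- Biostrings::AAStringSet(setNames(b$seq, b$id))
  scores <- matrix(0, nrow(a), nrow(b))
  for (k in seq_len(nrow(a))) {
    scores[k, ] <- Biostrings::pairwiseAlignment(
      bset, Biostrings::AAString(a$seq[k]),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
  }
  grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  sc <- scores[cbind(grid$i, grid$j)]
  hits_ab <- tibble(
    query_id = a$id[grid$i], subject_id = b$id[grid$j], score = sc,
    bitscore = ka_bitscore(sc),
    evalue = ka_evalue(sc, nchar(a$seq)[grid$i], sum(nchar(b$seq)))
  )
  hits_ba <- tibble(
    query_id = b$id[grid$j], subject_id = a$id[grid$i], score = sc,
    bitscore = ka_bitscore(sc),
    evalue = ka_evalue(sc, nchar(b$seq)[grid$j], sum(nchar(a$seq)))
  )
  reciprocal_best_hits(hits_ab, hits_ba, e_max)
}
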