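#' Sense codons of the standard nuclear genetic code
#'
#' The 61 sense codons (stop codons TAA, TAG, TGA excluded), in the fixed
#' order used by every codon-indexed structure in the package.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  names(gc_tab)[gc_tab != "*"]
}

stop_codons <- function() c("TAA", "TAG", "TGA")

# Amino acid for each sense codon, in sense_codons() order.
sense_aa <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  unname(gc_tab[sense_codons()])
}

is_transition_nt <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

# 61 x 3 character matrix of codon nucleotides.
codon_matrix <- function() {
  if (is.null(.cr$codon_matrix)) {
    .cr$codon_matrix <- do.call(rbind, strsplit(sense_codons(), ""))
  }
  .cr$codon_matrix
}

#' Single-nucleotide neighbour structure of the sense-codon space
#'
#' All ordered pairs of sense codons that differ at exactly one position,
#' with transition/transversion and synonymous/non-synonymous labels. This
#' edge list parameterises the Goldman-Yang rate matrix and the
#' Nei-Gojobori site counts.
#'
#' @return Tibble with columns `i`, `j` (1-based indices into
#'   [sense_codons()]), `pos` (differing codon position, 1-3), `ts`
#'   (logical, transition), `syn` (logical, synonymous).
#' @export
codon_edges <- function() {
  if (!is.null(.cr$codon_edges)) {
    return(.cr$codon_edges)
  }
  cm <- codon_matrix()
  aa <- sense_aa()
  res <- list()
  for (pos in 1:3) {
    other <- setdiff(1:3, pos)
    key <- paste0(cm[, other[1]], cm[, other[2]])
    for (g in unique(key)) {
      idx <- which(key == g)
      if (length(idx) < 2) next
      pairs <- expand.grid(i = idx, j = idx)
      pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
      ts <- is_transition_nt(cm[pairs$i, pos], cm[pairs$j, pos])
      syn <- aa[pairs$i] == aa[pairs$j]
      res[[length(res) + 1L]] <- tibble(
        i = pairs$i, j = pairs$j, pos = pos, ts = ts, syn = syn
      )
    }
  }
  out <- dplyr::bind_rows(res)
  out <- dplyr::arrange(out, .data$i, .data$j)
  .cr$codon_edges <- out
  out
}

# Logical length-61 vector: codon belongs to a 4-fold degenerate family
# (all four third-position variants encode the same amino acid).
fourfold_flags <- function() {
  if (is.null(.cr$fourfold)) {
    gc_tab <- Biostrings::GENETIC_CODE
    cm <- codon_matrix()
    pre <- paste0(cm[, 1], cm[, 2])
    .cr$fourfold <- vapply(pre, function(p) {
      aas <- gc_tab[paste0(p, c("A", "C", "G", "T"))]
      all(aas == aas[1]) && aas[1] != "*"
    }, logical(1), USE.NAMES = FALSE)
  }
  .cr$fourfold
}

# --- Nei-Gojobori counting tables -------------------------------------------
#
# syn_sites: per-codon synonymous site count, f_pos = n_syn/n_valid summed
# over positions, where n_valid excludes changes to stop codons (mutations
# to stops do not occur along sense-codon histories; excluding them from
# both numerator and denominator keeps S + N = 3 per codon exact and the
# estimator centred at omega = 1 under neutral simulation).
#
# syn_diff/nonsyn_diff: 61 x 61 matrices of fractional synonymous and
# non-synonymous differences, averaged with equal weight over all shortest
# substitution pathways between the two codons; pathways through stop codons
# are excluded (all-blocked pairs fall back to the unrestricted pathway set).
ng86_tables <- function() {
  if (!is.null(.cr$ng86)) {
    return(.cr$ng86)
  }
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- sense_codons()
  cm <- codon_matrix()
  aa <- sense_aa()
  nt <- c("A", "C", "G", "T")

  # per-position synonymous fraction among non-stop changes, so that the
  # site budget matches the substitution process over sense codons and
  # S + N = 3 per codon holds exactly
  syn_sites <- numeric(61)
  for (i in 1:61) {
    s <- 0
    for (pos in 1:3) {
      n_syn <- 0
      n_valid <- 0
      for (b in setdiff(nt, cm[i, pos])) {
        mut <- cm[i, ]
        mut[pos] <- b
        mutc <- paste(mut, collapse = "")
        if (gc_tab[mutc] == "*") next
        n_valid <- n_valid + 1
        if (gc_tab[mutc] == aa[i]) n_syn <- n_syn + 1
      }
      if (n_valid > 0) s <- s + n_syn / n_valid
    }
    syn_sites[i] <- s
  }

  step_type <- function(c1, c2) {
    # returns c(syn, nonsyn) for a single-nt step between two sense codons
    if (gc_tab[c1] == gc_tab[c2]) c(1, 0) else c(0, 1)
  }
  syn_diff <- matrix(0, 61, 61)
  nonsyn_diff <- matrix(0, 61, 61)
  for (i in 1:61) {
    for (j in 1:61) {
      if (i == j) next
      dpos <- which(cm[i, ] != cm[j, ])
      k <- length(dpos)
      perms <- if (k == 1) list(dpos) else {
        if (k == 2) {
          list(dpos, rev(dpos))
        } else {
          idx <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
          idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 3), ]
          lapply(seq_len(nrow(idx)), function(r) dpos[unlist(idx[r, ])])
        }
      }
      path_counts <- function(order, allow_stops) {
        cur <- cm[i, ]
        tot <- c(0, 0)
        for (pos in order) {
          nxt <- cur
          nxt[pos] <- cm[j, pos]
          c1 <- paste(cur, collapse = "")
          c2 <- paste(nxt, collapse = "")
          if (gc_tab[c2] == "*" && !allow_stops) return(NULL)
          if (gc_tab[c1] != "*" && gc_tab[c2] != "*") {
            tot <- tot + step_type(c1, c2)
          } else {
            # stop intermediate on the unrestricted fallback: count the step
            # as non-synonymous
            tot <- tot + c(0, 1)
          }
          cur <- nxt
        }
        tot
      }
      counts <- Filter(Negate(is.null), lapply(perms, path_counts, allow_stops = FALSE))
      if (length(counts) == 0) {
        counts <- lapply(perms, path_counts, allow_stops = TRUE)
      }
      avg <- Reduce(`+`, counts) / length(counts)
      syn_diff[i, j] <- avg[1]
      nonsyn_diff[i, j] <- avg[2]
    }
  }
  .cr$ng86 <- list(syn_sites = syn_sites, syn_diff = syn_diff, nonsyn_diff = nonsyn_diff)
  .cr$ng86
}

# Split a nucleotide string into codons; error if length not divisible by 3.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) {
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  }
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

# Translate an in-frame nucleotide string; codons containing N become X.
translate_codons <- function(seq) {
  gc_tab <- Biostrings::GENETIC_CODE
  cods <- split_codons(seq)
  aa <- ifelse(grepl("N", cods, fixed = TRUE), "X", unname(gc_tab[cods]))
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

validate_nucleotides <- function(seq, id = "sequence") {
  if (grepl("[^ACGTN]", seq)) {
    bad <- regmatches(seq, regexpr("[^ACGTN]", seq))
    stop(id, " contains invalid character '", bad, "' (allowed: A, C, G, T, N)",
      call. = FALSE
    )
  }
  invisible(TRUE)
}
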