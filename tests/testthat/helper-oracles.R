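# Independent oracles used across tests. These deliberately reimplement
# textbook algorithms in the plainest possible way so they share no code
# with the package internals they check.

# exhaustive six-frame ORF scan: every maximal ATG..stop span
orf_oracle <- function(seq) {
  revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  n <- nchar(seq)
  for (strand in c(1, -1)) {
    s <- if (strand == 1) seq else revcomp(seq)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3
      if (ncod < 1) next
      cods <- substring(s, off + 3 * (seq_len(ncod) - 1) + 1, off + 3 * seq_len(ncod))
      open_at <- NA
      for (k in seq_len(ncod)) {
        if (is.na(open_at) && cods[k] == "ATG") open_at <- k
        if (!is.na(open_at) && cods[k] %in% stops) {
          w_start <- off + 3 * (open_at - 1)
          w_end <- off + 3 * k
          found[[length(found) + 1L]] <- data.frame(
            frame = strand * (off + 1),
            start = if (strand == 1) w_start else n - w_end,
            end = if (strand == 1) w_end else n - w_start
          )
          open_at <- NA
        }
      }
    }
  }
  do.call(rbind, found)
}

# plain Smith-Waterman best local score with affine gaps costing
# open + len * extend (the Biostrings convention)
sw_score_oracle <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0
  M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend, Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# exact Mann-Whitney U two-sided p by enumeration over all assignments of
# ranks to the first group (no ties assumed)
mw_exact_oracle <- function(x, y) {
  nx <- length(x)
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  u_of <- function(idx) {
    xx <- vals[idx]
    yy <- vals[-idx]
    sum(outer(xx, yy, ">"))
  }
  u_obs <- sum(outer(x, y, ">"))
  combos <- utils::combn(length(vals), nx)
  us <- apply(combos, 2, u_of)
  mu <- nx * (length(vals) - nx) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

quick_pair <- function(n = 200, t = 0.3, kappa = 2, omega = 0.3, seed = 1) {
  simulate_codon_pair(sim_regime(n, t, kappa, omega, seed = seed))
}

split_codons_for_test <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}
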