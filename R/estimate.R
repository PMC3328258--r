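#' Nei-Gojobori counting estimate of dN and dS
#'
#' Per-codon synonymous site fractions are obtained by enumerating the
#' three single-nucleotide neighbours of each position (changes to stop
#' codons are excluded from both numerator and denominator, so S + N = 3
#' per codon holds exactly); synonymous and
#' non-synonymous differences between codons are averaged with equal
#' weight over all shortest substitution pathways through sense codons;
#' both proportions are corrected with the Jukes-Cantor formula
#' d = -(3/4) log(1 - 4p/3). Codons containing N are skipped pairwise and
#' tallied.
#'
#' @param x A [codon_alignment] (only kept columns are used) or an
#'   in-frame gap-free codon string.
#' @param y Second codon string when `x` is a string.
#' @param pair_id Identifier for the output row.
#' @return One-row tibble with the standard per-pair estimate columns:
#'   `pair_id`, `method`, `t`, `kappa`, `omega`, `dN`, `dS`, `d4`, `n4D`,
#'   `S_sites`, `N_sites`, `lnL`, `n_codons`, `n_skipped`, `status`
#'   (`"ok"`, `"undefined_ratio"` when dS = 0, `"failed"` when a
#'   proportion reaches the Jukes-Cantor ceiling p >= 3/4).
#' @export
ng86_estimate <- function(x, y = NULL, pair_id = NULL) {
  aln <- as_codon_alignment(x, y, pair_id %||% "pair")
  pid <- pair_id %||% aln$pair_id
  cm <- kept_codon_matrix(aln)
  idx <- codon_indices(cm)
  n_skip <- idx$n_skipped
  ia <- idx$ia
  ib <- idx$ib
  if (length(ia) < 1) stop("no usable codon columns", call. = FALSE)
  tabs <- ng86_tables()
  S_sites <- sum((tabs$syn_sites[ia] + tabs$syn_sites[ib]) / 2)
  N_sites <- 3 * length(ia) - S_sites
  Sd <- sum(tabs$syn_diff[cbind(ia, ib)])
  Nd <- sum(tabs$nonsyn_diff[cbind(ia, ib)])
  pS <- if (S_sites > 0) Sd / S_sites else 0
  pN <- if (N_sites > 0) Nd / N_sites else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  dS <- jc(pS)
  dN <- jc(pN)
  status <- if (is.na(dS) || is.na(dN)) {
    "failed"
  } else if (dS == 0) "undefined_ratio" else "ok"
  omega <- if (identical(status, "ok")) dN / dS else NA_real_
  t_hat <- if (!is.na(dS) && !is.na(dN)) {
    (dS * S_sites + dN * N_sites) / length(ia)
  } else {
    NA_real_
  }
  estimate_row(
    pair_id = pid, method = "NG86", t = t_hat, kappa = NA_real_,
    omega = omega, dN = dN, dS = dS, S_sites = S_sites, N_sites = N_sites,
    lnL = NA_real_, n_codons = length(ia), n_skipped = n_skip, status = status
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

estimate_row <- function(pair_id, method, t, kappa, omega, dN, dS,
                         S_sites, N_sites, lnL, n_codons, n_skipped, status,
                         d4 = NA_real_, n4D = NA_integer_) {
  tibble(
    pair_id = pair_id, method = method, t = t, kappa = kappa, omega = omega,
    dN = dN, dS = dS, d4 = d4, n4D = n4D, S_sites = S_sites,
    N_sites = N_sites, lnL = lnL, n_codons = n_codons,
    n_skipped = n_skipped, status = status
  )
}

# map codon columns to sense-codon indices, dropping N-containing columns
# (tallied) and rejecting stop codons
codon_indices <- function(cm) {
  has_n <- grepl("N", cm[1, ], fixed = TRUE) | grepl("N", cm[2, ], fixed = TRUE)
  a <- cm[1, !has_n]
  b <- cm[2, !has_n]
  codons <- sense_codons()
  ia <- match(a, codons)
  ib <- match(b, codons)
  if (anyNA(ia) || anyNA(ib)) {
    stop("stop codon or invalid codon in alignment column", call. = FALSE)
  }
  list(ia = ia, ib = ib, n_skipped = sum(has_n))
}

#' F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies are estimated from both
#' sequences pooled; sense-codon frequencies are the products over the
#' three positions, renormalised to sum to one (stop codons carry no
#' mass). A nucleotide unobserved at some position gives zero frequency to
#' the codons requiring it.
#'
#' @inheritParams ng86_estimate
#' @return Length-61 numeric vector over [sense_codons()].
#' @export
f3x4_frequencies <- function(x, y = NULL) {
  aln <- as_codon_alignment(x, y)
  cm <- kept_codon_matrix(aln)
  if (ncol(cm) < 1) stop("need at least one codon column", call. = FALSE)
  nt <- c("A", "C", "G", "T")
  posfreq <- matrix(0, 4, 3, dimnames = list(nt, NULL))
  for (pos in 1:3) {
    chars <- c(substr(cm[1, ], pos, pos), substr(cm[2, ], pos, pos))
    chars <- chars[chars %in% nt]
    tab <- table(factor(chars, levels = nt))
    posfreq[, pos] <- as.numeric(tab) / sum(tab)
  }
  f3x4_from_position_freqs(posfreq)
}

#' Distance at 4-fold degenerate sites
#'
#' A column's third position qualifies iff the two codons share their
#' first two positions and that prefix defines a 4-fold degenerate family
#' (any third-position nucleotide encodes the same amino acid). The
#' p-distance over qualifying third positions is corrected with the
#' Kimura 2-parameter formula using the transition/transversion partition
#' (Jukes-Cantor available as an option).
#'
#' @inheritParams ng86_estimate
#' @param correction `"K2P"` (default) or `"JC"`.
#' @return One-row tibble: `pair_id`, `d4`, `n4D`, `n_diff`, `status`
#'   (`"ok"`, `"no_sites"` when no column qualifies -- `d4` is NA, not 0 --
#'   or `"failed"` when the correction is undefined).
#' @export
d4_distance <- function(x, y = NULL, pair_id = NULL, correction = c("K2P", "JC")) {
  correction <- match.arg(correction)
  aln <- as_codon_alignment(x, y, pair_id %||% "pair")
  pid <- pair_id %||% aln$pair_id
  cm <- kept_codon_matrix(aln)
  idx <- codon_indices(cm)
  ff <- fourfold_flags()
  cmat <- codon_matrix()
  pre_a <- paste0(cmat[idx$ia, 1], cmat[idx$ia, 2])
  pre_b <- paste0(cmat[idx$ib, 1], cmat[idx$ib, 2])
  qual <- pre_a == pre_b & ff[idx$ia]
  n4D <- sum(qual)
  if (n4D == 0) {
    return(tibble(
      pair_id = pid, d4 = NA_real_, n4D = 0L, n_diff = 0L,
      status = "no_sites"
    ))
  }
  a3 <- cmat[idx$ia[qual], 3]
  b3 <- cmat[idx$ib[qual], 3]
  diff <- a3 != b3
  ts <- diff & is_transition_nt(a3, b3)
  P <- sum(ts) / n4D
  Q <- sum(diff & !ts) / n4D
  d4 <- if (correction == "K2P") {
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  } else {
    p <- P + Q
    if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  }
  tibble(
    pair_id = pid, d4 = d4, n4D = as.integer(n4D),
    n_diff = as.integer(sum(diff)), status = if (is.na(d4)) "failed" else "ok"
  )
}

#' Maximum-likelihood estimate under the Goldman-Yang codon model
#'
#' Maximises the pairwise likelihood L(t, kappa, omega) = sum over codon
#' columns of log(pi_i P_ij(t)) under the reversible Goldman-Yang rate
#' matrix with F3x4 frequencies estimated from the data, the matrix scaled
#' to one expected substitution per codon per unit t. Transition
#' probabilities come from an eigendecomposition of the symmetrised rate
#' matrix, recomputed per (kappa, omega) evaluation; the optimiser is
#' bounded quasi-Newton (L-BFGS-B in log-parameter space), with two
#' further dispersed starts if the first fails to converge or ends on a
#' bound. dN and dS follow the mutational-opportunity site definition (see
#' [gy94_dn_ds()]); omega = dN/dS.
#'
#' @inheritParams ng86_estimate
#' @param init Optional named list with starting values `t`, `kappa`,
#'   `omega`; by default t starts from the Nei-Gojobori total, kappa at 2,
#'   omega at 0.4.
#' @param codon_freqs Optional length-61 frequency vector overriding the
#'   F3x4 estimate.
#' @return Object of class `gy94_fit`; use [generics::tidy()] for the
#'   standard per-pair estimate row and [generics::glance()] for the fit
#'   summary.
#' @export
gy94_ml_estimate <- function(x, y = NULL, pair_id = NULL, init = NULL,
                             codon_freqs = NULL) {
  aln <- as_codon_alignment(x, y, pair_id %||% "pair")
  pid <- pair_id %||% aln$pair_id
  cm <- kept_codon_matrix(aln)
  idx <- codon_indices(cm)
  if (length(idx$ia) < 1) stop("no usable codon columns", call. = FALSE)
  pi <- codon_freqs %||% f3x4_frequencies(aln)
  pat <- pattern_counts(idx$ia, idx$ib)
  ed <- codon_edges()

  identical_seqs <- all(idx$ia == idx$ib)
  if (identical_seqs) {
    lnL0 <- sum(pat$n * log(pi[pat$i]))
    est <- estimate_row(
      pair_id = pid, method = "GY94-ML", t = 0, kappa = NA_real_,
      omega = NA_real_, dN = 0, dS = 0, S_sites = NA_real_, N_sites = NA_real_,
      lnL = lnL0, n_codons = length(idx$ia), n_skipped = idx$n_skipped,
      status = "undefined_ratio"
    )
    return(new_gy94_fit(est, c(t = 0, kappa = NA, omega = NA), lnL0, 0L, pi, pat))
  }

  nll <- function(logpar) {
    p <- exp(logpar)
    -gy94_loglik_cpp(
      p[1], p[2], p[3], pi,
      ed$i, ed$j, as.integer(ed$ts), as.integer(ed$syn),
      pat$i, pat$j, pat$n
    )
  }
  ng <- tryCatch(ng86_estimate(aln, pair_id = pid), error = function(e) NULL)
  t0 <- if (!is.null(ng) && is.finite(ng$t) && ng$t > 0) ng$t else 0.3
  starts <- list(
    c(t = t0, kappa = init$kappa %||% 2, omega = init$omega %||% 0.4),
    c(t = t0 * 2 + 0.1, kappa = 1, omega = 0.1),
    c(t = max(t0 * 0.5, 0.02), kappa = 4, omega = 1)
  )
  if (!is.null(init$t)) starts[[1]]["t"] <- init$t
  lower <- log(c(1e-6, 0.05, 1e-4))
  upper <- log(c(30, 50, 20))
  best <- NULL
  n_starts <- 0L
  for (s in starts) {
    n_starts <- n_starts + 1L
    fit <- tryCatch(
      optim(log(pmin(pmax(s, exp(lower)), exp(upper))), nll,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(factr = 1e7, maxit = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    ok <- fit$convergence == 0 && !any(on_bound(fit$par, lower, upper))
    if (ok) break
  }
  if (is.null(best)) {
    est <- estimate_row(
      pair_id = pid, method = "GY94-ML", t = NA_real_, kappa = NA_real_,
      omega = NA_real_, dN = NA_real_, dS = NA_real_, S_sites = NA_real_,
      N_sites = NA_real_, lnL = NA_real_, n_codons = length(idx$ia),
      n_skipped = idx$n_skipped, status = "failed"
    )
    return(new_gy94_fit(est, c(t = NA, kappa = NA, omega = NA), NA_real_, n_starts, pi, pat))
  }
  par <- exp(best$par)
  names(par) <- c("t", "kappa", "omega")
  lnL <- -best$value
  dd <- gy94_dn_ds(par["t"], par["kappa"], par["omega"], pi)
  rhoS1 <- dd$rhoS1
  S_sites <- 3 * length(idx$ia) * rhoS1
  N_sites <- 3 * length(idx$ia) * (1 - rhoS1)
  pinned <- on_bound(best$par, lower, upper)
  status <- if (best$convergence != 0 || pinned[2] || (pinned[1] && par["t"] > 1)) {
    # non-convergence, a kappa bound, or t at the saturation ceiling
    "failed"
  } else if (dd$dS <= 0 || par["omega"] >= exp(upper[3]) * (1 - 1e-6) ||
    (pinned[1] && par["t"] <= 1)) {
    # no usable synonymous signal: the pairwise analogue of the dN/dS
    # sentinel class that saturation filtering discards
    "undefined_ratio"
  } else {
    "ok"
  }
  est <- estimate_row(
    pair_id = pid, method = "GY94-ML", t = unname(par["t"]),
    kappa = unname(par["kappa"]),
    omega = if (identical(status, "ok")) dd$dN / dd$dS else NA_real_,
    dN = dd$dN, dS = dd$dS, S_sites = S_sites, N_sites = N_sites,
    lnL = lnL, n_codons = length(idx$ia), n_skipped = idx$n_skipped,
    status = status
  )
  new_gy94_fit(est, par, lnL, n_starts, pi, pat)
}

on_bound <- function(par, lower, upper, tol = 1e-6) {
  (par - lower < tol) | (upper - par < tol)
}

pattern_counts <- function(ia, ib) {
  key <- (ia - 1L) * 61L + ib
  tab <- table(key)
  k <- as.integer(names(tab))
  tibble(
    i = (k - 1L) %/% 61L + 1L,
    j = (k - 1L) %% 61L + 1L,
    n = as.numeric(tab)
  )
}

new_gy94_fit <- function(estimate, par, lnL, n_starts, pi, patterns) {
  structure(
    list(
      estimate = estimate, par = par, lnL = lnL, n_starts = n_starts,
      pi = pi, patterns = patterns
    ),
    class = "gy94_fit"
  )
}

#' @export
print.gy94_fit <- function(x, ...) {
  e <- x$estimate
  cat("<gy94_fit> ", e$pair_id, ": t=", signif(e$t, 4), " kappa=",
    signif(e$kappa, 4), " dN=", signif(e$dN, 4), " dS=", signif(e$dS, 4),
    " lnL=", signif(e$lnL, 6), " [", e$status, "]\n",
    sep = ""
  )
  invisible(x)
}

#' Per-pair evolutionary estimates for a set of aligned pairs
#'
#' Applies the chosen dN/dS estimator and the 4-fold degenerate site
#' distance to each pair and returns the combined per-gene estimates
#' table, one row per pair.
#'
#' @param pairs Tibble with `pair_id` and either a list-column `alignment`
#'   of [codon_alignment] objects or character columns `codon_a`,
#'   `codon_b` holding equal-length in-frame gap-free sequences.
#' @param method `"GY94-ML"` (default, matching a codeml pairwise run with
#'   F3x4 frequencies and kappa estimated from the data) or `"NG86"`.
#' @param d4_correction Passed to [d4_distance()].
#' @return Tibble of per-pair estimates (the per-gene analogue of a
#'   supplementary dN/dS table), including `d4` and `n4D`.
#' @export
estimate_pairs <- function(pairs, method = c("GY94-ML", "NG86"),
                           d4_correction = "K2P") {
  method <- match.arg(method)
  get_aln <- function(k) {
    if ("alignment" %in% names(pairs)) {
      pairs$alignment[[k]]
    } else {
      as_codon_alignment(pairs$codon_a[k], pairs$codon_b[k], pairs$pair_id[k])
    }
  }
  purrr::map(seq_len(nrow(pairs)), function(k) {
    aln <- get_aln(k)
    pid <- pairs$pair_id[k]
    est <- tryCatch(
      {
        if (method == "NG86") {
          ng86_estimate(aln, pair_id = pid)
        } else {
          generics::tidy(gy94_ml_estimate(aln, pair_id = pid))
        }
      },
      error = function(e) {
        estimate_row(
          pair_id = pid, method = method, t = NA_real_, kappa = NA_real_,
          omega = NA_real_, dN = NA_real_, dS = NA_real_, S_sites = NA_real_,
          N_sites = NA_real_, lnL = NA_real_, n_codons = NA_integer_,
          n_skipped = NA_integer_, status = "failed"
        )
      }
    )
    d4 <- tryCatch(
      d4_distance(aln, pair_id = pid, correction = d4_correction),
      error = function(e) tibble(d4 = NA_real_, n4D = NA_integer_)
    )
    est$d4 <- d4$d4
    est$n4D <- as.integer(d4$n4D)
    est
  }) |> dplyr::bind_rows()
}

#' Write the per-pair estimates TSV
#'
#' @param estimates [estimate_pairs()] output.
#' @param path Output TSV.
#' @param sentinel_undefined Write the codeml-style 98.99 sentinel in the
#'   omega column for pairs with an undefined ratio instead of NA
#'   (compatibility shim; the in-memory representation stays a typed
#'   status).
#' @export
write_estimates_tsv <- function(estimates, path, sentinel_undefined = FALSE) {
  out <- estimates
  if (sentinel_undefined) {
    out$omega[out$status == "undefined_ratio"] <- 98.99
  }
  readr::write_tsv(out, path)
  invisible(path)
}
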