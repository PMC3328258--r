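#' Goldman-Yang codon rate matrix
#'
#' Builds the 61x61 reversible codon substitution rate matrix with
#' off-diagonal entries pi_j, kappa*pi_j, omega*pi_j, omega*kappa*pi_j for
#' synonymous/non-synonymous transversions/transitions between codons one
#' nucleotide apart (zero for multi-nucleotide changes), scaled so that the
#' expected number of substitutions per codon per unit time is 1.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS rate ratio (>= 0).
#' @param pi Length-61 stationary codon frequency vector over
#'   [sense_codons()]; must sum to 1.
#' @return 61x61 numeric matrix with rows summing to zero.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi = rep(1 / 61, 61)) {
  check_gy94_params(kappa, omega, pi)
  ed <- codon_edges()
  Q <- matrix(0, 61, 61)
  w <- pi[ed$j] * ifelse(ed$ts, kappa, 1) * ifelse(ed$syn, 1, omega)
  Q[cbind(ed$i, ed$j)] <- w
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix: total flow is zero", call. = FALSE)
  Q / scale
}

check_gy94_params <- function(kappa, omega, pi) {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be finite and > 0", call. = FALSE)
  if (!is.finite(omega) || omega < 0) stop("omega must be finite and >= 0", call. = FALSE)
  if (length(pi) != 61 || any(!is.finite(pi)) || any(pi < 0)) {
    stop("pi must be a finite non-negative vector of length 61", call. = FALSE)
  }
  if (abs(sum(pi) - 1) > 1e-8) stop("codon frequencies must sum to 1", call. = FALSE)
  invisible(TRUE)
}

# Synonymous fraction of substitution flow sum_i pi_i q_ij for a GY94 model.
# Computed directly from the edge list (no matrix build needed).
synonymous_flow_fraction <- function(kappa, omega, pi = rep(1 / 61, 61)) {
  ed <- codon_edges()
  w <- pi[ed$i] * pi[ed$j] * ifelse(ed$ts, kappa, 1) * ifelse(ed$syn, 1, omega)
  sum(w[ed$syn]) / sum(w)
}

#' Convert codon-model parameters to per-site dN and dS
#'
#' Under the mutational-opportunity site definition, dS = t * rhoS /
#' (3 * rhoS1) and dN = t * (1 - rhoS) / (3 * (1 - rhoS1)), where rhoS is
#' the synonymous fraction of substitution flow at (kappa, omega) and rhoS1
#' the same fraction recomputed at omega = 1 (kappa held fixed).
#'
#' @param t Expected substitutions per codon (>= 0).
#' @inheritParams gy94_rate_matrix
#' @return Named list with `dN`, `dS`, `rhoS`, `rhoS1`.
#' @export
gy94_dn_ds <- function(t, kappa, omega, pi = rep(1 / 61, 61)) {
  rhoS <- synonymous_flow_fraction(kappa, omega, pi)
  rhoS1 <- synonymous_flow_fraction(kappa, 1, pi)
  list(
    dS = t * rhoS / (3 * rhoS1),
    dN = t * (1 - rhoS) / (3 * (1 - rhoS1)),
    rhoS = rhoS, rhoS1 = rhoS1
  )
}

#' Codon transition probability matrix
#'
#' P(t) = exp(Qt) computed by eigendecomposition of the reversible rate
#' matrix (symmetrised in the pi^(1/2) inner product).
#'
#' @inheritParams gy94_dn_ds
#' @return 61x61 stochastic matrix.
#' @export
gy94_pmatrix <- function(t, kappa, omega, pi = rep(1 / 61, 61)) {
  if (!is.finite(t) || t < 0) stop("t must be finite and >= 0", call. = FALSE)
  Q <- gy94_rate_matrix(kappa, omega, pi)
  # guard zero-frequency codons: they receive and emit no flow
  pos <- pi > 0
  sp <- sqrt(pi[pos])
  S <- Q[pos, pos] * outer(sp, 1 / sp)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  Ppos <- (e$vectors %*% (exp(e$values * t) * t(e$vectors))) * outer(1 / sp, sp)
  Ppos[Ppos < 0] <- 0
  P <- matrix(0, 61, 61)
  diag(P) <- 1
  P[pos, pos] <- Ppos
  P
}
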