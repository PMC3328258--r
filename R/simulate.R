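#' Simulation regime for an orthologous codon-sequence pair
#'
#' Bundles the generative parameters of the Goldman-Yang codon model under
#' which a pair of orthologues is simulated: sequence length, total expected
#' divergence t (substitutions per codon across both lineages), kappa,
#' omega, and the stationary codon frequencies.
#'
#' @param n_codons Number of codons (>= 1).
#' @param t_codon Expected substitutions per codon between the pair (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS rate ratio (>= 0).
#' @param codon_freqs Either a length-61 frequency vector over
#'   [sense_codons()] (summing to 1, no stop-codon mass by construction), or
#'   a 4x3 matrix of nucleotide-by-position frequencies (rows A, C, G, T)
#'   from which F3x4 codon frequencies are built, or `NULL` for uniform.
#' @param seed Integer seed; every stochastic operation in the package takes
#'   an explicit seed and leaves the global random state untouched.
#' @return Object of class `sim_regime`.
#' @export
sim_regime <- function(n_codons, t_codon, kappa, omega, codon_freqs = NULL,
                       seed = 1L) {
  if (!is.finite(n_codons) || n_codons < 1) stop("n_codons must be >= 1", call. = FALSE)
  if (!is.finite(t_codon) || t_codon < 0) stop("t_codon must be finite and >= 0", call. = FALSE)
  pi <- resolve_codon_freqs(codon_freqs)
  check_gy94_params(kappa, omega, pi)
  structure(
    list(
      n_codons = as.integer(n_codons), t_codon = t_codon, kappa = kappa,
      omega = omega, codon_freqs = pi, seed = as.integer(seed)
    ),
    class = "sim_regime"
  )
}

resolve_codon_freqs <- function(codon_freqs) {
  if (is.null(codon_freqs)) {
    return(rep(1 / 61, 61))
  }
  if (is.matrix(codon_freqs)) {
    if (!all(dim(codon_freqs) == c(4, 3))) {
      stop("nucleotide-by-position frequencies must be a 4x3 matrix (rows A,C,G,T)",
        call. = FALSE
      )
    }
    return(f3x4_from_position_freqs(codon_freqs))
  }
  if (length(codon_freqs) != 61) {
    stop("codon_freqs must have length 61 (sense codons only; stop codons carry no mass)",
      call. = FALSE
    )
  }
  if (any(!is.finite(codon_freqs)) || any(codon_freqs < 0)) {
    stop("codon frequencies must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(codon_freqs) - 1) > 1e-8) {
    stop("codon frequencies must sum to 1", call. = FALSE)
  }
  codon_freqs
}

# product of position-specific nucleotide frequencies over sense codons,
# renormalised (the F3x4 construction)
f3x4_from_position_freqs <- function(posfreq) {
  nt <- c("A", "C", "G", "T")
  rownames(posfreq) <- nt
  cm <- codon_matrix()
  w <- posfreq[cm[, 1], 1] * posfreq[cm[, 2], 2] * posfreq[cm[, 3], 3]
  if (sum(w) <= 0) stop("all-zero codon frequency vector", call. = FALSE)
  unname(w / sum(w))
}

#' Simulate one orthologous codon-sequence pair
#'
#' Draws an ancestral sequence from the stationary codon distribution and
#' evolves two independent lineages, each for `t_codon / 2`, using exact
#' matrix-exponential transition probabilities of the Goldman-Yang rate
#' matrix (scaled to one expected substitution per codon per unit time).
#' Both emitted sequences are gap-free, stop-free and of equal length.
#'
#' @param regime A [sim_regime()].
#' @return List with `a`, `b` (nucleotide strings of length `3 * n_codons`)
#'   and `truth`, a one-row tibble recording the generative parameters and
#'   the true per-site `dN_true`, `dS_true` implied by the rate matrix.
#' @export
simulate_codon_pair <- function(regime) {
  stopifnot(inherits(regime, "sim_regime"))
  pi <- regime$codon_freqs
  P <- gy94_pmatrix(regime$t_codon / 2, regime$kappa, regime$omega, pi)
  codons <- sense_codons()
  seqs <- withr::with_seed(regime$seed, {
    anc <- sample.int(61, regime$n_codons, replace = TRUE, prob = pi)
    list(a = evolve_from(anc, P), b = evolve_from(anc, P))
  })
  dd <- gy94_dn_ds(regime$t_codon, regime$kappa, regime$omega, pi)
  list(
    a = paste(codons[seqs$a], collapse = ""),
    b = paste(codons[seqs$b], collapse = ""),
    truth = tibble(
      t = regime$t_codon, kappa = regime$kappa, omega = regime$omega,
      dN_true = dd$dN, dS_true = dd$dS
    )
  )
}

# sample child codon states given ancestor states and a transition matrix
evolve_from <- function(anc, P) {
  out <- integer(length(anc))
  for (s in unique(anc)) {
    idx <- which(anc == s)
    out[idx] <- sample.int(61, length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Wrap a coding sequence as a cDNA-like transcript
#'
#' Adds a start codon, a stop codon and random UTRs around a codon body,
#' emulating a full-length cDNA; optionally truncates the transcript to
#' emulate a fragmented EST-cluster consensus whose coding region may lack
#' its start and/or stop codon. UTRs are generated free of ATG triplets so
#' the planted ORF is the longest ORF in the untruncated transcript.
#'
#' @param codon_seq In-frame codon body (no start/stop), length a multiple
#'   of 3, free of internal stop codons.
#' @param utr5_len,utr3_len UTR lengths in nucleotides (>= 0).
#' @param truncate_fraction Fraction of the full transcript removed
#'   (0 <= f < 1); 0 keeps the transcript full length.
#' @param truncate_end Which end to cut: `"5prime"`, `"3prime"` or `"both"`
#'   (split evenly).
#' @param seed Integer seed.
#' @return Nucleotide string with attributes `orf_start`, `orf_end`
#'   (0-based half-open coordinates of the surviving planted coding region,
#'   start/stop codons included when present) and `frame` (1-based frame
#'   offset of the ORF within the returned sequence).
#' @export
wrap_as_cdna <- function(codon_seq, utr5_len = 0, utr3_len = 0,
                         truncate_fraction = 0,
                         truncate_end = c("5prime", "3prime", "both"),
                         seed = 1L) {
  truncate_end <- match.arg(truncate_end)
  if (utr5_len < 0 || utr3_len < 0) stop("UTR lengths must be >= 0", call. = FALSE)
  if (truncate_fraction < 0 || truncate_fraction >= 1) {
    stop("truncate_fraction must be in [0, 1)", call. = FALSE)
  }
  validate_nucleotides(codon_seq, "codon body")
  if (nchar(codon_seq) %% 3 != 0) stop("codon body length must be a multiple of 3", call. = FALSE)
  orf <- paste0("ATG", codon_seq, "TAA")
  full <- withr::with_seed(seed, {
    paste0(random_utr(utr5_len), orf, random_utr(utr3_len))
  })
  orf_start <- utr5_len
  orf_end <- utr5_len + nchar(orf)
  n <- nchar(full)
  cut <- floor(truncate_fraction * n)
  cut5 <- switch(truncate_end,
    "5prime" = cut, "3prime" = 0L, "both" = floor(cut / 2)
  )
  cut3 <- cut - cut5
  out <- substr(full, cut5 + 1, n - cut3)
  # surviving coding region, snapped to the original codon frame
  usable_start <- if (cut5 <= orf_start) {
    orf_start - cut5
  } else {
    (3L - (cut5 - orf_start) %% 3L) %% 3L
  }
  end_raw <- min(orf_end, n - cut3) - cut5
  usable_end <- usable_start + max((end_raw - usable_start) %/% 3, 0) * 3
  if (usable_end - usable_start < 3) {
    stop("truncation would leave less than one codon of the coding region", call. = FALSE)
  }
  structure(out,
    orf_start = usable_start, orf_end = usable_end,
    frame = (usable_start %% 3) + 1L
  )
}

# random UTR with no ATG triplet at any offset (so no spurious long ORF can
# start upstream of or inside the UTR)
random_utr <- function(len) {
  if (len == 0) {
    return("")
  }
  nt <- c("A", "C", "G", "T")
  for (attempt in 1:100) {
    s <- paste(sample(nt, len, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    if (!grepl("ATG", s, fixed = TRUE)) {
      return(s)
    }
    s <- gsub("ATG", "ACG", s, fixed = TRUE)
    if (!grepl("ATG", s, fixed = TRUE)) {
      return(s)
    }
  }
  stop("failed to generate an ATG-free UTR", call. = FALSE)
}

#' Clade configuration for a synthetic two-clade study
#'
#' Describes how one clade's orthologous pairs are generated: gene count,
#' length, kappa, the per-gene omega distribution (gamma with given mean and
#' shape), and the per-gene synonymous divergence (dS) distribution, either
#' a plain gamma or a mixture with a saturated tail placed entirely above
#' `ds_tail_threshold` so the post-filter survivor fraction is known by
#' construction.
#'
#' @param n_pairs Number of orthologous pairs.
#' @param n_codons Codons per gene.
#' @param kappa Transition/transversion ratio shared by the clade.
#' @param omega_mean,omega_shape Mean and gamma shape of per-gene omega.
#' @param ds_mean,ds_shape Mean and gamma shape of per-gene dS. With a
#'   saturated tail configured, `ds_mean` is the mean of the estimable
#'   body below the threshold (clade mean dS is conventionally reported
#'   after saturation filtering). The default shape of 6 (CV about 0.41)
#'   matches the between-gene dS dispersion implied by gene-level
#'   bootstrap intervals of low-divergence clade studies of this size.
#' @param ds_tail_frac Fraction of genes in the saturated-dS tail (0 for
#'   none).
#' @param ds_tail_threshold dS value above which the tail lies.
#' @return List of class `clade_config`.
#' @export
clade_config <- function(n_pairs = 50, n_codons = 170, kappa = 2,
                         omega_mean = 0.31, omega_shape = 2,
                         ds_mean = 0.19, ds_shape = 6,
                         ds_tail_frac = 0, ds_tail_threshold = 4) {
  if (ds_tail_frac < 0 || ds_tail_frac >= 1) stop("ds_tail_frac must be in [0, 1)", call. = FALSE)
  if (ds_tail_frac > 0 && ds_mean <= ds_tail_frac * ds_tail_threshold) {
    stop("ds_mean too small for the requested saturated tail", call. = FALSE)
  }
  structure(as.list(environment()), class = "clade_config")
}

#' Configuration for a synthetic two-clade study
#'
#' Defaults emulate the study conditions of a conifer-like clade (low
#' divergence, elevated omega) against an angiosperm-like clade (high,
#' partly saturated divergence, low omega). Planted functional categories
#' multiply the omega of their member genes so enrichment tests have a
#' known signal.
#'
#' @param clades Named list of two [clade_config()] objects.
#' @param n_decoys Unpaired paralog-like decoy sequences added per clade.
#' @param planted_categories List of `list(term =, n_genes =,
#'   omega_multiplier =)` entries, planted in the first clade.
#' @param n_background_terms Number of background annotation terms.
#' @param utr5_len,utr3_len UTR lengths used when wrapping coding sequences
#'   as cDNA.
#' @param truncate_fraction Truncation applied to the second species'
#'   transcripts (EST-fragment emulation); 0 keeps them full length.
#' @return List of class `study_config`.
#' @export
study_config <- function(clades = list(
                           conifer = clade_config(
                             n_pairs = 50, n_codons = 170, omega_mean = 0.31,
                             ds_mean = 0.19
                           ),
                           angiosperm = clade_config(
                             n_pairs = 50, n_codons = 129, omega_mean = 0.09,
                             ds_mean = 2.2, ds_shape = 2,
                             ds_tail_frac = 0.25, ds_tail_threshold = 4
                           )
                         ),
                         n_decoys = 0, planted_categories = list(),
                         n_background_terms = 8,
                         utr5_len = 60, utr3_len = 40,
                         truncate_fraction = 0) {
  if (length(clades) != 2 || is.null(names(clades)) || any(names(clades) == "")) {
    stop("exactly two named clades are required", call. = FALSE)
  }
  structure(as.list(environment()), class = "study_config")
}

# draw per-gene dS values for a clade
#
# With a saturated tail configured, the distribution is a two-component
# mixture: with probability 1 - tail_frac a gamma truncated below the
# threshold whose scale is calibrated (deterministically, by root finding)
# so the *truncated* mean equals ds_mean -- clade mean dS in this kind of
# study is always reported after saturation filtering, so the target is
# the mean of the estimable body -- and with probability tail_frac a
# shifted exponential entirely above the threshold. The survivor fraction
# of an oracle dS filter is therefore exactly 1 - tail_frac.
draw_ds <- function(cc, n) {
  if (cc$ds_tail_frac == 0) {
    return(rgamma(n, shape = cc$ds_shape, scale = cc$ds_mean / cc$ds_shape))
  }
  thr <- cc$ds_tail_threshold
  body_scale <- calibrate_truncated_gamma(cc$ds_shape, cc$ds_mean, thr)
  in_tail <- runif(n) < cc$ds_tail_frac
  out <- numeric(n)
  nb <- sum(!in_tail)
  if (nb > 0) {
    draws <- rgamma(nb * 3 + 20, shape = cc$ds_shape, scale = body_scale)
    draws <- draws[draws < thr]
    while (length(draws) < nb) {
      draws <- c(draws, rgamma(nb, shape = cc$ds_shape, scale = body_scale))
      draws <- draws[draws < thr]
    }
    out[!in_tail] <- draws[seq_len(nb)]
  }
  # saturated genes: moderately beyond the threshold (excess mean ds_mean/2)
  out[in_tail] <- thr + stats::rexp(sum(in_tail), rate = 2 / cc$ds_mean)
  out
}

truncated_gamma_mean <- function(shape, scale, upper) {
  f <- function(x) x * stats::dgamma(x, shape = shape, scale = scale)
  stats::integrate(f, 0, upper)$value / stats::pgamma(upper, shape = shape, scale = scale)
}

# scale such that E[X | X < upper] = target for X ~ gamma(shape, scale)
calibrate_truncated_gamma <- function(shape, target, upper) {
  max_mean <- truncated_gamma_mean(shape, upper * 50, upper)
  if (target >= max_mean * 0.999) {
    stop("ds_mean too close to the saturation threshold to calibrate", call. = FALSE)
  }
  uniroot(
    function(s) truncated_gamma_mean(shape, s, upper) - target,
    lower = target / shape / 10, upper = upper * 50, tol = 1e-10
  )$root
}

#' Generate a complete synthetic two-clade study
#'
#' Produces every input the pipeline consumes: cDNA-wrapped FASTA-ready
#' sequences for both species of both clades, the true orthologue list, a
#' gene-to-term annotation table with planted categories, and a truth table
#' (per-pair t, kappa, omega and the implied true dN, dS) sufficient to
#' score orthology recall and estimator bias. Deterministic for a fixed
#' seed.
#'
#' @param config A [study_config()].
#' @param seed Integer seed governing all randomness.
#' @return List of class `study_bundle` with tibbles `sequences` (clade,
#'   species, id, seq, orf_start, orf_end), `codon_pairs` (clade, pair_id,
#'   codon_a, codon_b -- the unwrapped coding bodies), `pairs` (ortholog
#'   truth), `truth`, and `annotations`.
#' @export
generate_study <- function(config = study_config(), seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  withr::with_seed(seed, generate_study_impl(config))
}

generate_study_impl <- function(config) {
  clade_names <- names(config$clades)
  seqs <- list()
  codon_pairs <- list()
  pairs <- list()
  truth <- list()

  planted <- config$planted_categories
  n_planted <- if (length(planted)) sum(vapply(planted, `[[`, 0, "n_genes")) else 0L

  for (ci in seq_along(config$clades)) {
    clade <- clade_names[ci]
    cc <- config$clades[[ci]]
    n <- cc$n_pairs
    pi <- rep(1 / 61, 61)
    rhoS1 <- synonymous_flow_fraction(cc$kappa, 1, pi)

    omega_g <- rgamma(n, shape = cc$omega_shape, scale = cc$omega_mean / cc$omega_shape)
    omega_g <- pmax(omega_g, 1e-4)
    category <- rep(NA_character_, n)
    if (ci == 1 && length(planted)) {
      if (n_planted > n) stop("more planted genes than pairs in clade 1", call. = FALSE)
      slots <- sample.int(n, n_planted)
      off <- 0L
      for (pc in planted) {
        idx <- slots[(off + 1):(off + pc$n_genes)]
        category[idx] <- pc$term
        omega_g[idx] <- pmax(omega_g[idx] * pc$omega_multiplier, 1e-4)
        off <- off + pc$n_genes
      }
    }
    ds_g <- draw_ds(cc, n)
    # invert the mutational-opportunity dS definition to get branch lengths
    rhoS_g <- vapply(omega_g, function(w) synonymous_flow_fraction(cc$kappa, w, pi), 0)
    t_g <- ds_g * 3 * rhoS1 / rhoS_g
    gene_seeds <- sample.int(.Machine$integer.max - 1L, n + 2L)

    for (g in seq_len(n)) {
      pair_id <- sprintf("%s_%04d", clade, g)
      reg <- sim_regime(cc$n_codons, t_g[g], cc$kappa, omega_g[g],
        codon_freqs = pi, seed = gene_seeds[g]
      )
      sim <- simulate_codon_pair(reg)
      codon_pairs[[length(codon_pairs) + 1L]] <- tibble(
        clade = clade, pair_id = pair_id, codon_a = sim$a, codon_b = sim$b
      )
      id_a <- paste0(pair_id, "_s1")
      id_b <- paste0(pair_id, "_s2")
      w1 <- wrap_as_cdna(sim$a, config$utr5_len, config$utr3_len,
        seed = gene_seeds[g] + 1L
      )
      w2 <- wrap_as_cdna(sim$b, config$utr5_len, config$utr3_len,
        truncate_fraction = config$truncate_fraction,
        truncate_end = "5prime", seed = gene_seeds[g] + 2L
      )
      seqs[[length(seqs) + 1L]] <- tibble(
        clade = clade, species = c(1L, 2L), id = c(id_a, id_b),
        seq = c(as.character(w1), as.character(w2)),
        orf_start = c(attr(w1, "orf_start"), attr(w2, "orf_start")),
        orf_end = c(attr(w1, "orf_end"), attr(w2, "orf_end"))
      )
      pairs[[length(pairs) + 1L]] <- tibble(
        clade = clade, pair_id = pair_id, id_a = id_a, id_b = id_b
      )
      truth[[length(truth) + 1L]] <- dplyr::bind_cols(
        tibble(clade = clade, pair_id = pair_id), sim$truth,
        tibble(category = category[g])
      )
    }

    # paralog-like decoys: extra divergent copies without a true partner
    if (config$n_decoys > 0) {
      P_dec <- gy94_pmatrix(1.0, cc$kappa, 0.2, pi)
      codons <- sense_codons()
      for (d in seq_len(config$n_decoys)) {
        src <- codon_pairs[[length(codon_pairs) - n + ((d - 1L) %% n) + 1L]]
        anc <- match(split_codons(src$codon_a), codons)
        dec <- paste(codons[evolve_from(anc, P_dec)], collapse = "")
        did <- sprintf("%s_decoy%03d_s2", clade, d)
        wd <- wrap_as_cdna(dec, config$utr5_len, config$utr3_len,
          seed = gene_seeds[n + 1L] + d
        )
        seqs[[length(seqs) + 1L]] <- tibble(
          clade = clade, species = 2L, id = did,
          seq = as.character(wd),
          orf_start = attr(wd, "orf_start"), orf_end = attr(wd, "orf_end")
        )
      }
    }
  }

  truth <- dplyr::bind_rows(truth)
  annotations <- build_annotations(truth, config)
  structure(
    list(
      sequences = dplyr::bind_rows(seqs),
      codon_pairs = dplyr::bind_rows(codon_pairs),
      pairs = dplyr::bind_rows(pairs),
      truth = truth,
      annotations = annotations,
      config = config
    ),
    class = "study_bundle"
  )
}

build_annotations <- function(truth, config) {
  first_clade <- names(config$clades)[1]
  g1 <- truth[truth$clade == first_clade, ]
  bg_terms <- sprintf("background_%02d", seq_len(config$n_background_terms))
  term <- ifelse(is.na(g1$category),
    sample(bg_terms, nrow(g1), replace = TRUE), g1$category
  )
  tibble(
    gene_id = g1$pair_id, term = term,
    description = ifelse(is.na(g1$category), "background term", "planted category")
  )
}

#' Write a study bundle to disk
#'
#' Emits the file formats the pipeline reads: one FASTA per clade and
#' species (60-column wrapped), an orthologue truth TSV, a truth table TSV
#' and an annotation TSV.
#'
#' @param bundle A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (clade in unique(bundle$sequences$clade)) {
    for (sp in 1:2) {
      sub <- bundle$sequences[bundle$sequences$clade == clade & bundle$sequences$species == sp, ]
      p <- file.path(dir, sprintf("%s_species%d.fasta", clade, sp))
      write_fasta(setNames(sub$seq, sub$id), p)
      paths[[sprintf("%s_s%d", clade, sp)]] <- p
    }
  }
  paths$pairs <- file.path(dir, "ortholog_truth.tsv")
  readr::write_tsv(bundle$pairs, paths$pairs)
  paths$truth <- file.path(dir, "sim_truth.tsv")
  readr::write_tsv(bundle$truth, paths$truth)
  paths$annotations <- file.path(dir, "annotations.tsv")
  readr::write_tsv(bundle$annotations, paths$annotations)
  invisible(paths)
}
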