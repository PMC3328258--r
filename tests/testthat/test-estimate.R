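test_that("identical sequences give zero distances and an undefined ratio", {
  orf <- quick_pair(n = 50, t = 0, seed = 1)$a
  ng <- ng86_estimate(orf, orf)
  expect_equal(ng$dN, 0)
  expect_equal(ng$dS, 0)
  expect_true(is.na(ng$omega))
  expect_identical(ng$status, "undefined_ratio")
  ml <- tidy(gy94_ml_estimate(orf, orf))
  expect_equal(ml$t, 0)
  expect_equal(ml$dS, 0)
  expect_identical(ml$status, "undefined_ratio")
})

test_that("single synonymous difference follows the hand-enumerated site counts", {
  # TTT: of its 9 single-nt neighbours only TTC is synonymous -> S = 1/3
  e <- ng86_estimate(strrep("TTT", 30), paste0("TTC", strrep("TTT", 29)))
  expect_equal(e$S_sites, 30 * (1 / 3))
  expect_equal(e$N_sites, 90 - 10)
  # one synonymous difference on 10 synonymous sites, JC-corrected
  expect_equal(e$dS, -0.75 * log(1 - 4 * 0.1 / 3))
  expect_equal(e$dN, 0)
})

test_that("counting estimates match an independently computed reference", {
  # fixture with one synonymous, one nonsynonymous and one two-step codon
  # difference; expected values frozen from an independent implementation
  # of the Nei-Gojobori pathway counts
  a <- "ATGTTTGGACTTCCAGTCACCGGAGCAAAGGAC"
  b <- "ATGTTCGGACTTCTAGTCACCGGAGTTAAGGAC"
  e <- ng86_estimate(a, b)
  expect_equal(e$dN, 0.0851978833, tolerance = 1e-9)
  expect_equal(e$dS, 0.2964845525, tolerance = 1e-9)
})

test_that("F3x4 frequencies renormalise position products over sense codons", {
  # uniform nucleotide composition: every sense codon at 1/61 exactly
  # (1/64 per product, stop mass 3/64 renormalised away)
  pf <- codonrates:::f3x4_from_position_freqs(matrix(1 / 4, 4, 3))
  expect_equal(pf, rep(1 / 61, 61))
  # degenerate composition: repeated ATG puts all mass on ATG
  f <- f3x4_frequencies(strrep("ATG", 20), strrep("ATG", 20))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_equal(f[match("ATG", sense_codons())], 1)
  # frequencies from simulated data sum to 1 within 1e-12
  p <- quick_pair(n = 300, t = 0.4, seed = 2)
  expect_equal(sum(f3x4_frequencies(p$a, p$b)), 1, tolerance = 1e-12)
})

test_that("4-fold degenerate site qualification follows the family rule", {
  # GGA/GGC: glycine family, first two positions equal -> qualifies, one
  # transversion difference
  d <- d4_distance(paste0("GGA", strrep("GGG", 40)), paste0("GGC", strrep("GGG", 40)))
  expect_equal(d$n4D, 41L)
  expect_equal(d$n_diff, 1L)
  # TTA/CTA: both leucine but first positions differ -> not comparable
  d2 <- d4_distance(strrep("TTA", 10), strrep("CTA", 10))
  expect_equal(d2$n4D, 0L)
  expect_true(is.na(d2$d4))
  expect_identical(d2$status, "no_sites")
})

test_that("d4 with K2P matches the distance package on extracted third positions", {
  p <- quick_pair(n = 1200, t = 0.6, seed = 13)
  d <- d4_distance(p$a, p$b)
  # rebuild the qualifying third positions independently and hand them to
  # ape's K80 distance as an external oracle
  a <- split_codons_for_test(p$a)
  b <- split_codons_for_test(p$b)
  gc_tab <- Biostrings::GENETIC_CODE
  is4d <- function(cod) {
    pre <- substr(cod, 1, 2)
    aas <- gc_tab[paste0(pre, c("A", "C", "G", "T"))]
    all(aas == aas[1]) && aas[1] != "*"
  }
  qual <- substr(a, 1, 2) == substr(b, 1, 2) & vapply(a, is4d, TRUE)
  m <- rbind(strsplit(paste0(substr(a[qual], 3, 3), collapse = ""), "")[[1]],
             strsplit(paste0(substr(b[qual], 3, 3), collapse = ""), "")[[1]])
  bin <- ape::as.DNAbin(m)
  want <- as.numeric(ape::dist.dna(bin, model = "K80"))
  expect_equal(sum(qual), d$n4D)
  expect_equal(d$d4, want, tolerance = 1e-8)
})

test_that("d4 tracks dS on neutral data", {
  ratio <- vapply(1:60, function(s) {
    p <- simulate_codon_pair(sim_regime(2000, 0.3, kappa = 2, omega = 1, seed = s))
    d4 <- d4_distance(p$a, p$b)$d4
    ds <- tidy(gy94_ml_estimate(p$a, p$b))$dS
    d4 / ds
  }, 0)
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("the likelihood surface is locally optimal at the reported MLE", {
  p <- quick_pair(n = 300, t = 0.5, seed = 21)
  fit <- gy94_ml_estimate(p$a, p$b)
  est <- tidy(fit)
  ed <- codon_edges()
  ll <- function(t, k, w) {
    codonrates:::gy94_loglik_cpp(
      t, k, w, fit$pi, ed$i, ed$j,
      as.integer(ed$ts), as.integer(ed$syn),
      fit$patterns$i, fit$patterns$j, fit$patterns$n
    )
  }
  grid <- expand.grid(
    t = est$t * c(0.8, 0.9, 1, 1.1, 1.2),
    k = est$kappa * c(0.8, 0.9, 1, 1.1, 1.2),
    w = tidy(fit)$omega * c(0.8, 0.9, 1, 1.1, 1.2)
  )
  vals <- mapply(ll, grid$t, grid$k, grid$w)
  expect_gte(fit$lnL + 1e-6, max(vals))
})

test_that("omega is invariant to swapping the two sequences", {
  for (seed in c(2, 9)) {
    p <- quick_pair(n = 250, t = 0.6, seed = seed)
    f1 <- tidy(gy94_ml_estimate(p$a, p$b))
    f2 <- tidy(gy94_ml_estimate(p$b, p$a))
    expect_equal(f1$omega, f2$omega, tolerance = 1e-4)
    expect_equal(f1$t, f2$t, tolerance = 1e-4)
  }
})

test_that("median t-hat increases with simulated divergence", {
  med_t <- vapply(c(0.2, 0.5, 1.0, 2.0), function(tt) {
    stats::median(vapply(1:12, function(s) {
      p <- simulate_codon_pair(sim_regime(200, tt, 2, 0.3, seed = s * 7))
      tidy(gy94_ml_estimate(p$a, p$b))$t
    }, 0))
  }, 0)
  expect_true(all(diff(med_t) > 0))
})

test_that("codons containing N are excluded from counting but tallied", {
  orf <- quick_pair(n = 40, t = 0, seed = 3)$a
  withN <- paste0("ANG", substr(orf, 4, nchar(orf)))
  e <- ng86_estimate(withN, orf)
  expect_equal(e$n_skipped, 1L)
  expect_equal(e$n_codons, 39L)
})

test_that("estimate_pairs combines the estimator and d4 into one table", {
  pairs <- dplyr::bind_rows(lapply(1:3, function(s) {
    p <- quick_pair(n = 120, t = 0.3, seed = s)
    tibble::tibble(pair_id = paste0("g", s), codon_a = p$a, codon_b = p$b)
  }))
  est <- estimate_pairs(pairs, method = "NG86")
  expect_equal(nrow(est), 3)
  expect_true(all(!is.na(est$d4)))
  expect_true(all(est$method == "NG86"))
  f <- tempfile(fileext = ".tsv")
  est2 <- est
  est2$status[1] <- "undefined_ratio"
  write_estimates_tsv(est2, f, sentinel_undefined = TRUE)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$omega[1], 98.99)
})
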