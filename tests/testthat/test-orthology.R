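test_that("BLAST tabular rows round-trip field by field", {
  f <- tempfile(fileext = ".tsv")
  rows <- c(
    "geneA\tgeneX\t98.5\t120\t2\t0\t1\t120\t5\t124\t1e-50\t230.1",
    "geneB\tgeneY\t77.0\t90\t20\t1\t11\t100\t200\t111\t2.5e-21\t99.9",
    "geneC\tgeneZ\t50.0\t30\t15\t0\t1\t30\t1\t30\t0.001\t25.0"
  )
  writeLines(rows, f)
  h <- read_blast_tabular(f)
  expect_equal(nrow(h), 3)
  expect_identical(h$query_id, c("geneA", "geneB", "geneC"))
  # 1-based inclusive -> 0-based half-open
  expect_equal(h$qstart, c(0L, 10L, 0L))
  expect_equal(h$qend, c(120L, 100L, 30L))
  # reversed subject interval is normalised and flagged
  expect_equal(h$sstart[2], 110L)
  expect_equal(h$send[2], 200L)
  expect_equal(h$frame, c(1L, -1L, 1L))
  expect_equal(h$evalue, c(1e-50, 2.5e-21, 1e-3))
  expect_equal(h$bitscore, c(230.1, 99.9, 25.0))
})

test_that("malformed BLAST tabular input is rejected with the line number", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "a\tb\t90\t50\t5\t0\t1\t50\t1\t50\t1e-30\t100",
    "a\tb\t90\t50\t5\t0\t1\t50\t1\t50\t1e-30" # 11 columns
  ), f)
  expect_error(read_blast_tabular(f), "line 2")
  writeLines("a\tb\t90\t50\t5\t0\t1\t50\t1\t50\tnot_a_number\t100", f)
  expect_error(read_blast_tabular(f), "e-value")
  empty <- tempfile()
  writeLines(character(), empty)
  expect_equal(nrow(read_blast_tabular(empty)), 0)
})

test_that("built-in search scores equal a textbook Smith-Waterman oracle", {
  set.seed(99)
  aa <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
  )
  mk <- function(n) paste(sample(aa, n, TRUE), collapse = "")
  qs <- setNames(replicate(5, mk(25)), paste0("q", 1:5))
  ss <- setNames(replicate(5, mk(25)), paste0("s", 1:5))
  # make two related pairs so some hits clear the threshold
  ss["s1"] <- paste0(substr(qs["q1"], 1, 20), "AAAAA")
  ss["s2"] <- qs["q2"]
  hits <- local_align_search(qs, ss, e_max = Inf, with_intervals = FALSE)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  for (k in seq_len(nrow(hits))) {
    want <- sw_score_oracle(
      qs[[hits$query_id[k]]], ss[[hits$subject_id[k]]], mat
    )
    expect_equal(hits$score[k], want)
  }
})

test_that("identical sequences self-hit maximally; unrelated ones do not hit", {
  p <- c(x = "MSTNPKPQRKTKRNTNRRPQDVKFPGG")
  self <- local_align_search(p, setNames(p, "y"), e_max = 1)
  expect_equal(nrow(self), 1)
  expect_equal(self$qstart, 0L)
  expect_equal(self$qend, unname(nchar(p)))
  set.seed(7)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  r1 <- setNames(paste(sample(aa, 50, TRUE), collapse = ""), "r1")
  r2 <- setNames(paste(sample(aa, 50, TRUE), collapse = ""), "r2")
  none <- local_align_search(r1, r2, e_max = 1e-20, with_intervals = FALSE)
  expect_equal(nrow(none), 0)
  expect_equal(nrow(local_align_search(
    character(0), r2,
    e_max = 1
  )), 0)
})

test_that("reciprocal best hits require mutual uniqueness", {
  hit <- function(q, s, e, b = 100) {
    data.frame(query_id = q, subject_id = s, evalue = e, bitscore = b)
  }
  # mutual best: one pair
  ab <- rbind(hit("a1", "b1", 1e-50), hit("a1", "b2", 1e-30))
  ba <- rbind(hit("b1", "a1", 1e-50), hit("b2", "a1", 1e-28))
  pairs <- reciprocal_best_hits(ab, ba, e_max = 1e-20)
  expect_equal(nrow(pairs), 1)
  expect_identical(pairs$id_a, "a1")
  expect_identical(pairs$id_b, "b1")

  # a's best is b, but b's best is c: no pair
  ab2 <- hit("a1", "b1", 1e-50)
  ba2 <- rbind(hit("b1", "c9", 1e-60), hit("b1", "a1", 1e-50))
  expect_equal(nrow(reciprocal_best_hits(ab2, ba2, e_max = 1e-20)), 0)

  # exact tie for best: ambiguous, excluded
  ab3 <- rbind(hit("a1", "b1", 1e-50, 100), hit("a1", "b2", 1e-50, 100))
  ba3 <- rbind(hit("b1", "a1", 1e-50, 100), hit("b2", "a1", 1e-50, 100))
  expect_equal(nrow(reciprocal_best_hits(ab3, ba3, e_max = 1e-20)), 0)

  # multiple HSPs per ordered pair are reduced to the best before RBH
  ab4 <- rbind(hit("a1", "b1", 1e-50), hit("a1", "b1", 1e-10))
  ba4 <- hit("b1", "a1", 1e-45)
  expect_equal(nrow(reciprocal_best_hits(ab4, ba4, e_max = 1e-20)), 1)
})

test_that("RBH output is symmetric and monotone in the e-value threshold", {
  set.seed(12)
  n <- 6
  ab <- data.frame(
    query_id = paste0("a", rep(1:n, each = n)),
    subject_id = paste0("b", rep(1:n, times = n)),
    evalue = 10^-round(runif(n * n, 5, 60)),
    bitscore = round(runif(n * n, 30, 300))
  )
  ba <- data.frame(
    query_id = ab$subject_id, subject_id = ab$query_id,
    evalue = ab$evalue, bitscore = ab$bitscore
  )
  p1 <- reciprocal_best_hits(ab, ba, e_max = 1e-20)
  p2 <- reciprocal_best_hits(ba, ab, e_max = 1e-20)
  expect_identical(
    sort(paste(p1$id_a, p1$id_b)),
    sort(paste(p2$id_b, p2$id_a))
  )
  expect_lte(nrow(p1), n)
  expect_true(all(p1$evalue_ab <= 1e-20 & p1$evalue_ba <= 1e-20))
  # tightening the threshold never adds pairs
  p_tight <- reciprocal_best_hits(ab, ba, e_max = 1e-40)
  expect_true(all(paste(p_tight$id_a, p_tight$id_b) %in% paste(p1$id_a, p1$id_b)))
})

test_that("paralog decoys neither break recall nor precision on a known study", {
  cfg <- study_config(
    clades = list(
      a = clade_config(n_pairs = 15, n_codons = 90, ds_mean = 0.2),
      b = clade_config(n_pairs = 2, n_codons = 90, ds_mean = 0.2)
    ),
    n_decoys = 5
  )
  bundle <- generate_study(cfg, seed = 17)
  res <- run_pipeline(pipeline_config(
    study = cfg, n_boot = 50, seed = 17,
    filters = list(a = filter_policy(0.5), b = filter_policy(0.5)),
    scenarios = list(a = divergence_scenario(140), b = divergence_scenario(140))
  ))
  orth <- res$orthology[res$orthology$clade == "a", ]
  truth <- bundle$pairs[bundle$pairs$clade == "a", ]
  found <- paste(orth$id_a, orth$id_b)
  want <- paste(truth$id_a, truth$id_b)
  expect_true(all(found %in% want)) # precision 1: no decoy pairs
  expect_equal(sort(found), sort(want)) # recall 1
})
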