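test_that("annotation transfer honours the e-value threshold", {
  hits <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    ref_id = c("r1", "r1", "r9"),
    evalue = c(1e-10, 1e-3, 1e-30)
  )
  ref <- tibble::tibble(gene_id = c("r1", "r1"), term = c("kinase", "membrane"))
  expect_warning(out <- transfer_annotations(hits, ref), "absent")
  expect_setequal(out$term[out$gene_id == "g1"], c("kinase", "membrane"))
  expect_false("g2" %in% out$gene_id) # hit too weak to transfer
  expect_false("g3" %in% out$gene_id) # reference gene unannotated
  expect_error(
    transfer_annotations(hits[c(1, 1), ], ref),
    "at most one"
  )
})

test_that("annotation transfer recovers planted labels on exact self-matches", {
  cfg <- study_config(
    clades = list(
      a = clade_config(n_pairs = 20, n_codons = 60),
      b = clade_config(n_pairs = 2, n_codons = 60)
    ),
    planted_categories = list(list(term = "planted", n_genes = 6, omega_multiplier = 3))
  )
  bundle <- generate_study(cfg, seed = 8)
  self_hits <- tibble::tibble(
    gene_id = bundle$annotations$gene_id,
    ref_id = bundle$annotations$gene_id, evalue = 0
  )
  out <- transfer_annotations(self_hits, bundle$annotations)
  expect_identical(
    sort(out$gene_id[out$term == "planted"]),
    sort(bundle$annotations$gene_id[bundle$annotations$term == "planted"])
  )
})

test_that("between-clade category comparison finds a planted shift and not a null", {
  set.seed(5)
  mk_est <- function(om, pre) {
    tibble::tibble(pair_id = paste0(pre, seq_along(om)), omega = om)
  }
  ann <- tibble::tibble(
    gene_id = c(paste0("a", 1:50), paste0("b", 1:50)),
    term = "cat1"
  )
  ea <- mk_est(rgamma(50, 4, scale = 0.05) + 0.2, "a")
  eb <- mk_est(rgamma(50, 4, scale = 0.05), "b")
  res <- compare_categories_between_clades(ea, eb, ann)
  expect_equal(res$term, "cat1")
  expect_lt(res$p, 0.001)
  expect_identical(res$direction, "a_high")

  # same values in both clades: p = 1, no direction
  same <- rgamma(30, 4, scale = 0.05)
  r0 <- compare_categories_between_clades(
    mk_est(same, "a"), mk_est(same, "b"),
    tibble::tibble(gene_id = c(paste0("a", 1:30), paste0("b", 1:30)), term = "cat1")
  )
  expect_gt(r0$p, 0.99)
  expect_identical(r0$direction, "none")
})

test_that("exact Mann-Whitney p on a 4-vs-4 fixture matches full enumeration", {
  xa <- c(0.91, 0.52, 0.77, 0.34)
  xb <- c(0.12, 0.45, 0.28, 0.61)
  ann <- tibble::tibble(
    gene_id = c(paste0("a", 1:4), paste0("b", 1:4)), term = "t1"
  )
  res <- compare_categories_between_clades(
    tibble::tibble(pair_id = paste0("a", 1:4), omega = xa),
    tibble::tibble(pair_id = paste0("b", 1:4), omega = xb),
    ann
  )
  expect_equal(res$p, mw_exact_oracle(xa, xb))
  expect_equal(res$statistic, sum(outer(xa, xb, ">")))
})

test_that("Kruskal-Wallis heterogeneity behaves at the null and under a shift", {
  # identical value multisets in two categories: H = 0
  vals <- tibble::tibble(gene_id = paste0("g", 1:20), value = rep(1:10, 2))
  ann <- tibble::tibble(
    gene_id = paste0("g", 1:20),
    term = rep(c("u", "v"), each = 10)
  )
  h0 <- across_category_heterogeneity(vals, ann)
  expect_equal(h0$statistic, 0, tolerance = 1e-12)
  # one category shifted by 2 SD is detected
  set.seed(9)
  v <- c(rnorm(30), rnorm(30), rnorm(30, mean = 2))
  d <- tibble::tibble(gene_id = paste0("g", 1:90), value = v)
  a <- tibble::tibble(
    gene_id = paste0("g", 1:90),
    term = rep(c("c1", "c2", "c3"), each = 30)
  )
  hs <- across_category_heterogeneity(d, a)
  expect_lt(hs$p, 0.01)
  expect_equal(hs$df, 2)
  expect_error(
    across_category_heterogeneity(vals[1:10, ], ann[1:10, ]),
    "at least 2 categories"
  )
})

test_that("a single-partition Fisher table equals the hypergeometric oracle", {
  # 2x2 table (10,0 / 0,10): all members above the cut
  p_pkg <- stats::fisher.test(matrix(c(10, 0, 0, 10), 2, 2))$p.value
  expect_equal(p_pkg, fisher_oracle(10, 0, 0, 10), tolerance = 1e-10)
  # and a non-extreme table
  expect_equal(
    stats::fisher.test(matrix(c(7, 3, 4, 8), 2, 2))$p.value,
    fisher_oracle(7, 3, 4, 8),
    tolerance = 1e-10
  )
})

segmentation_fixture <- function(n = 200, top_members = 0, interleave = FALSE,
                                 seed = 1) {
  set.seed(seed)
  omega <- sort(runif(n, 0.01, 1.5), decreasing = TRUE)
  est <- tibble::tibble(
    pair_id = sprintf("g%03d", 1:n), omega = omega, dN = 0.05
  )
  if (interleave) {
    member <- seq_len(n) %% 10 == 0
  } else {
    member <- c(rep(TRUE, top_members), rep(FALSE, n - top_members))
  }
  ann <- tibble::tibble(
    gene_id = est$pair_id[member], term = "catX"
  )
  # background term so BH has >1 category
  ann2 <- tibble::tibble(
    gene_id = est$pair_id[seq(2, n, by = 7)], term = "bg"
  )
  list(est = est, ann = dplyr::bind_rows(ann, ann2))
}

test_that("an interleaved category is not called by the segmentation test", {
  fx <- segmentation_fixture(interleave = TRUE)
  res <- ranked_segmentation_test(fx$est, fx$ann)
  expect_gt(res$p_adj[res$term == "catX"], 0.5)
  expect_false(res$significant[res$term == "catX"])
})

test_that("a planted top-decile category is detected with direction high", {
  fx <- segmentation_fixture(n = 200, top_members = 20)
  res <- ranked_segmentation_test(fx$est, fx$ann)
  row <- res[res$term == "catX", ]
  expect_lt(row$p_adj, 0.05)
  expect_identical(row$direction, "high")
  expect_equal(row$n_in + row$n_out, 200)

  lg <- logistic_trend_test(fx$est, fx$ann)
  lrow <- lg[lg$term == "catX", ]
  expect_lt(lrow$p_adj, 0.05)
  expect_identical(lrow$direction, "high")
})

test_that("genes with no non-synonymous substitution are removed before ranking", {
  fx <- segmentation_fixture(n = 100, top_members = 10)
  fx$est$dN[1:5] <- 0
  res <- ranked_segmentation_test(fx$est, fx$ann)
  expect_equal(res$n_in[res$term == "catX"] + res$n_out[res$term == "catX"], 95)
})

test_that("the logistic trend test skips degenerate categories and is null-calm", {
  fx <- segmentation_fixture(n = 120, interleave = TRUE)
  all_genes <- tibble::tibble(gene_id = fx$est$pair_id, term = "everything")
  res <- logistic_trend_test(fx$est, dplyr::bind_rows(fx$ann, all_genes))
  expect_false("everything" %in% res$term)
  expect_gt(res$p[res$term == "catX"], 0.05)
})

test_that("segmentation and logistic directions agree on planted signals", {
  hits <- 0L
  agree <- 0L
  for (seed in 1:10) {
    fx <- segmentation_fixture(n = 150, top_members = 15, seed = seed)
    rs <- ranked_segmentation_test(fx$est, fx$ann)
    rl <- logistic_trend_test(fx$est, fx$ann)
    srow <- rs[rs$term == "catX", ]
    lrow <- rl[rl$term == "catX", ]
    if (srow$significant && lrow$significant) {
      hits <- hits + 1L
      if (identical(srow$direction, lrow$direction)) agree <- agree + 1L
    }
  }
  expect_gt(hits, 5)
  expect_gte(agree / hits, 0.95)
})
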