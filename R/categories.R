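#' Transfer annotations by best hit
#'
#' A gene inherits the full term set of its best reference hit iff the hit
#' e-value passes the transfer threshold; genes with no qualifying hit get
#' no terms and are thereby excluded from category tests. A reference gene
#' absent from the annotation table yields no terms and a warning.
#'
#' @param best_hits Tibble with one row per gene: `gene_id`, `ref_id`,
#'   `evalue`.
#' @param reference_annotations Tibble `gene_id`, `term` (reference
#'   vocabulary), optional `description`.
#' @param e_max Transfer threshold (default 1e-5).
#' @return Long tibble `gene_id`, `term` (plus `description` when the
#'   reference table carries one).
#' @export
transfer_annotations <- function(best_hits, reference_annotations, e_max = 1e-5) {
  stopifnot(all(c("gene_id", "ref_id", "evalue") %in% names(best_hits)))
  if (anyDuplicated(best_hits$gene_id)) {
    stop("best_hits must map each gene to at most one reference gene", call. = FALSE)
  }
  qual <- best_hits[best_hits$evalue <= e_max, , drop = FALSE]
  missing_ref <- setdiff(qual$ref_id, reference_annotations$gene_id)
  if (length(missing_ref) > 0) {
    warning(
      length(missing_ref),
      " reference gene(s) absent from the annotation table; affected genes get no terms"
    )
  }
  out <- dplyr::inner_join(
    dplyr::select(qual, "gene_id", "ref_id"),
    dplyr::rename(reference_annotations, ref_id = "gene_id"),
    by = "ref_id", relationship = "many-to-many"
  )
  dplyr::select(out, -"ref_id")
}

#' Per-category two-clade comparison (Mann-Whitney)
#'
#' For every term with at least `min_genes` genes in each clade, a
#' two-sided Mann-Whitney U test compares per-gene values (omega by
#' default) between the clades; small categories use the exact null
#' distribution, larger ones the normal approximation with tie
#' correction. The direction records which clade has the larger median.
#'
#' @param estimates_a,estimates_b Per-pair estimate tibbles for the two
#'   clades (`pair_id` joins to annotations' `gene_id`).
#' @param annotations Long tibble `gene_id`, `term` covering both clades.
#' @param value Column compared (default `"omega"`).
#' @param alpha Significance level used only to set `direction = "none"`
#'   for non-significant terms.
#' @param min_genes Minimum genes per clade per term (default 2).
#' @param exact_max Largest per-clade size for the exact test (default 20).
#' @return Tibble: `term`, `n_a`, `n_b`, `statistic` (U), `p`, `p_adj`
#'   (Benjamini-Hochberg), `direction` (`"a_high"`, `"b_high"`, `"none"`).
#' @export
compare_categories_between_clades <- function(estimates_a, estimates_b,
                                              annotations, value = "omega",
                                              alpha = 0.05, min_genes = 2,
                                              exact_max = 20) {
  va <- annotated_values(estimates_a, annotations, value)
  vb <- annotated_values(estimates_b, annotations, value)
  terms <- intersect(unique(va$term), unique(vb$term))
  res <- purrr::map(sort(terms), function(tm) {
    xa <- va$value[va$term == tm]
    xb <- vb$value[vb$term == tm]
    if (length(xa) < min_genes || length(xb) < min_genes) {
      return(NULL)
    }
    exact <- length(xa) <= exact_max && length(xb) <= exact_max
    wt <- suppressWarnings(wilcox.test(xa, xb, exact = exact, correct = TRUE))
    tibble(
      term = tm, n_a = length(xa), n_b = length(xb),
      statistic = unname(wt$statistic), p = wt$p.value,
      med_a = stats::median(xa), med_b = stats::median(xb)
    )
  }) |> dplyr::bind_rows()
  if (nrow(res) == 0) {
    return(tibble(
      term = character(), n_a = integer(), n_b = integer(),
      statistic = numeric(), p = numeric(), p_adj = numeric(),
      direction = character()
    ))
  }
  res$p_adj <- p.adjust(res$p, "BH")
  res$direction <- ifelse(res$p >= alpha | res$med_a == res$med_b, "none",
    ifelse(res$med_a > res$med_b, "a_high", "b_high")
  )
  dplyr::select(res, -"med_a", -"med_b")
}

annotated_values <- function(estimates, annotations, value) {
  stopifnot(value %in% names(estimates))
  dplyr::inner_join(
    tibble(gene_id = estimates$pair_id, value = estimates[[value]]),
    dplyr::select(annotations, "gene_id", "term"),
    by = "gene_id", relationship = "many-to-many"
  ) |> dplyr::filter(!is.na(.data$value))
}

#' Across-category heterogeneity (Kruskal-Wallis)
#'
#' Tests whether per-gene values (omega, or a per-gene rate such as the
#' 4-fold degenerate site rate) differ across functional categories. A
#' gene carrying k terms contributes one observation to each of its k
#' categories.
#'
#' @param values Tibble `gene_id`, `value`.
#' @param annotations Long tibble `gene_id`, `term`.
#' @param min_genes Minimum genes per category (default 2).
#' @return One-row tibble: `statistic` (tie-corrected H), `df`, `p`,
#'   `n_categories`, `n_obs`.
#' @export
across_category_heterogeneity <- function(values, annotations, min_genes = 2) {
  stopifnot(all(c("gene_id", "value") %in% names(values)))
  d <- dplyr::inner_join(values, dplyr::select(annotations, "gene_id", "term"),
    by = "gene_id", relationship = "many-to-many"
  )
  d <- d[!is.na(d$value), , drop = FALSE]
  sizes <- table(d$term)
  eligible <- names(sizes)[sizes >= min_genes]
  d <- d[d$term %in% eligible, , drop = FALSE]
  if (length(eligible) < 2) {
    stop("need at least 2 categories with >= ", min_genes, " genes", call. = FALSE)
  }
  kw <- kruskal.test(d$value, factor(d$term))
  tibble(
    statistic = unname(kw$statistic), df = unname(kw$parameter),
    p = kw$p.value, n_categories = length(eligible), n_obs = nrow(d)
  )
}

# deterministic ranked gene list: descending by value, ties by gene id;
# genes with no non-synonymous substitution are removed when dN is present
ranked_gene_list <- function(estimates, value = "omega") {
  d <- estimates[!is.na(estimates[[value]]), , drop = FALSE]
  if ("dN" %in% names(d)) d <- d[is.na(d$dN) | d$dN > 0, , drop = FALSE]
  d <- d[order(-d[[value]], d$pair_id), , drop = FALSE]
  tibble(gene_id = d$pair_id, value = d[[value]], rank = seq_len(nrow(d)))
}

#' Ranked segmentation test (Fisher exact over partitions)
#'
#' Genes are ranked by omega (descending, ties broken by gene id; genes
#' with no non-synonymous substitution are removed first). The ranked
#' list is cut at `n_partitions` equally spaced rank quantiles; at each
#' cut, a two-sided Fisher exact test on the 2x2 table (category
#' membership x above/below the cut) is computed per category.
#' Benjamini-Hochberg FDR is applied jointly across the whole collection
#' of category-by-partition tests (the search over partitions is part of
#' the multiplicity); each category then reports its best cut -- minimum
#' raw p, the matching adjusted p, and the direction of the imbalance
#' there. Under a full null this keeps the any-false-positive rate at the
#' nominal FDR level.
#'
#' @param estimates Per-pair estimate tibble (needs `pair_id`, `omega`,
#'   and `dN` for the zero-substitution removal).
#' @param annotations Long tibble `gene_id`, `term`.
#' @param n_partitions Number of cuts (default 30).
#' @param fdr_alpha FDR level used for the significance flag.
#' @param value Ranking column (default `"omega"`).
#' @return Tibble: `term`, `n_in`, `n_out`, `statistic` (odds ratio at
#'   the best cut), `p` (minimum across cuts), `p_adj`, `direction`
#'   (`"high"`/`"low"` end of the ranking), `significant`.
#' @export
ranked_segmentation_test <- function(estimates, annotations, n_partitions = 30,
                                     fdr_alpha = 0.05, value = "omega") {
  ranked <- ranked_gene_list(estimates, value)
  n <- nrow(ranked)
  if (n < 4) stop("ranked list too short", call. = FALSE)
  ann <- annotations[annotations$gene_id %in% ranked$gene_id, , drop = FALSE]
  terms <- sort(unique(ann$term))
  cuts <- unique(pmin(pmax(round(seq_len(n_partitions) / (n_partitions + 1) * n), 1), n - 1))
  nc <- length(cuts)
  cells <- purrr::map(terms, function(tm) {
    member <- ranked$gene_id %in% ann$gene_id[ann$term == tm]
    m <- sum(member)
    if (m == 0 || m == n) {
      return(NULL)
    }
    cum_m <- cumsum(member)
    a <- cum_m[cuts] # members above each cut
    p <- numeric(nc)
    or <- numeric(nc)
    for (k in seq_len(nc)) {
      ft <- fisher.test(matrix(
        c(a[k], m - a[k], cuts[k] - a[k], (n - cuts[k]) - (m - a[k])), 2, 2
      ))
      p[k] <- ft$p.value
      or[k] <- unname(ft$estimate)
    }
    tibble(
      term = tm, n_in = m, n_out = n - m, cut = cuts,
      statistic = or, p = p,
      direction = ifelse(a > m * cuts / n, "high", "low")
    )
  }) |> dplyr::bind_rows()
  if (is.null(cells) || nrow(cells) == 0) {
    return(tibble(
      term = character(), n_in = integer(), n_out = integer(),
      statistic = numeric(), p = numeric(), p_adj = numeric(),
      direction = character(), significant = logical()
    ))
  }
  # one BH family over every (category, partition) test
  cells$p_adj <- p.adjust(cells$p, "BH")
  res <- cells |>
    dplyr::group_by(.data$term) |>
    dplyr::arrange(.data$p, .data$cut, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"cut")
  res$significant <- res$p_adj < fdr_alpha
  res
}

#' Logistic trend test on a ranked gene list
#'
#' Fits category membership as a logistic function of rank percentile
#' (percentile 1 = top of the omega ranking) and tests the slope (Wald).
#' A positive slope means the category concentrates at high omega. Under
#' complete separation the Wald test degenerates; the score test for the
#' slope (well-defined under the null) is used instead and flagged.
#'
#' @inheritParams ranked_segmentation_test
#' @return Tibble: `term`, `n_in`, `n_out`, `statistic` (slope on the
#'   percentile scale, or the score z under the fallback), `p`, `p_adj`,
#'   `direction`, `significant`, `note`.
#' @export
logistic_trend_test <- function(estimates, annotations, fdr_alpha = 0.05,
                                value = "omega") {
  ranked <- ranked_gene_list(estimates, value)
  n <- nrow(ranked)
  if (n < 4) stop("ranked list too short", call. = FALSE)
  # percentile increases towards the top (high omega) of the ranking
  pct <- 1 - (ranked$rank - 0.5) / n
  ann <- annotations[annotations$gene_id %in% ranked$gene_id, , drop = FALSE]
  terms <- sort(unique(ann$term))
  res <- purrr::map(terms, function(tm) {
    y <- as.integer(ranked$gene_id %in% ann$gene_id[ann$term == tm])
    m <- sum(y)
    if (m == 0 || m == n) {
      return(NULL) # no variation in the response: skipped
    }
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ pct, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    slope <- unname(coef(fit)[2])
    if (sep || !fit$converged || abs(slope) > 15) {
      z <- logistic_score_z(y, pct)
      tibble(
        term = tm, n_in = m, n_out = n - m, statistic = z,
        p = 2 * pnorm(-abs(z)),
        direction = if (z > 0) "high" else "low", note = "score_fallback"
      )
    } else {
      se <- sqrt(diag(stats::vcov(fit)))[2]
      z <- slope / se
      tibble(
        term = tm, n_in = m, n_out = n - m, statistic = slope,
        p = 2 * pnorm(-abs(z)),
        direction = if (slope > 0) "high" else "low", note = NA_character_
      )
    }
  }) |> dplyr::bind_rows()
  if (nrow(res) == 0) {
    return(tibble(
      term = character(), n_in = integer(), n_out = integer(),
      statistic = numeric(), p = numeric(), p_adj = numeric(),
      direction = character(), significant = logical(), note = character()
    ))
  }
  res$p_adj <- p.adjust(res$p, "BH")
  res$significant <- res$p_adj < fdr_alpha
  dplyr::select(
    res, "term", "n_in", "n_out", "statistic", "p", "p_adj",
    "direction", "significant", "note"
  )
}

# score test for the logistic slope: U / sqrt(V) with U = sum (y - ybar) x,
# V = ybar (1 - ybar) sum (x - xbar)^2
logistic_score_z <- function(y, x) {
  yb <- mean(y)
  U <- sum((y - yb) * x)
  V <- yb * (1 - yb) * sum((x - mean(x))^2)
  U / sqrt(V)
}

#' Write a category test results TSV
#'
#' @param results A category test result tibble.
#' @param path Output TSV.
#' @export
write_category_results <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}
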