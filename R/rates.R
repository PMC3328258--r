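#' Saturation filter policy
#'
#' Thresholds for excluding gene pairs with saturated divergence:
#' a low-divergence clade default of dS > 0.5, and for a high-divergence
#' clade dS > 4 with an additional dN > 5 guard. Pairs whose dN/dS is
#' undefined (no synonymous substitutions, the codeml 98.99 sentinel
#' class) are dropped first.
#'
#' @param max_dS Drop pairs with dS above this (default 0.5).
#' @param max_dN Drop pairs with dN above this (default Inf).
#' @param drop_undefined_ratio Drop pairs whose status is not `"ok"`.
#' @return List of class `filter_policy`.
#' @export
filter_policy <- function(max_dS = 0.5, max_dN = Inf, drop_undefined_ratio = TRUE) {
  if (max_dS <= 0 || max_dN <= 0) stop("thresholds must be > 0", call. = FALSE)
  structure(
    list(
      max_dS = max_dS, max_dN = max_dN,
      drop_undefined_ratio = drop_undefined_ratio
    ),
    class = "filter_policy"
  )
}

#' Apply saturation filters to per-pair estimates
#'
#' Drops pairs in rule order -- undefined/failed ratio first, then
#' dS > max_dS, then dN > max_dN; the first matching rule is the recorded
#' reason.
#'
#' @param estimates [estimate_pairs()]-style tibble.
#' @param policy A [filter_policy()].
#' @return List with `kept` (tibble of surviving rows) and `discarded`
#'   (tibble `pair_id`, `reason`).
#' @export
apply_filters <- function(estimates, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  reason <- rep(NA_character_, nrow(estimates))
  if (policy$drop_undefined_ratio) {
    bad <- estimates$status != "ok"
    reason[bad] <- ifelse(estimates$status[bad] == "failed", "failed", "undefined_ratio")
  }
  over_s <- !is.na(estimates$dS) & estimates$dS > policy$max_dS
  reason[over_s & is.na(reason)] <- "max_dS"
  over_n <- !is.na(estimates$dN) & estimates$dN > policy$max_dN
  reason[over_n & is.na(reason)] <- "max_dN"
  list(
    kept = estimates[is.na(reason), , drop = FALSE],
    discarded = tibble(
      pair_id = estimates$pair_id[!is.na(reason)],
      reason = reason[!is.na(reason)]
    )
  )
}

#' Divergence-time calibration scenario
#'
#' @param T_mya Working divergence time, million years ago.
#' @param T_low_mya,T_high_mya Fossil-record range (defaults to the
#'   working value).
#' @param rho Between-lineage rate ratio (fast lineage / slow lineage;
#'   1 = rates equivalent along both lineages).
#' @return List of class `divergence_scenario` with times in years.
#' @export
divergence_scenario <- function(T_mya, T_low_mya = T_mya, T_high_mya = T_mya,
                                rho = 1) {
  if (!(T_low_mya > 0 && T_low_mya <= T_mya && T_mya <= T_high_mya)) {
    stop("need 0 < T_low <= T <= T_high", call. = FALSE)
  }
  if (rho < 1) stop("rho must be >= 1 (orient the pair fast/slow)", call. = FALSE)
  structure(
    list(
      T_years = T_mya * 1e6, T_low_years = T_low_mya * 1e6,
      T_high_years = T_high_mya * 1e6, rho = rho
    ),
    class = "divergence_scenario"
  )
}

#' Absolute substitution rate from a pairwise distance
#'
#' mu = d / (2T): the per-site per-year rate implied by a pairwise
#' distance d and a divergence time T, assuming equal rates along both
#' lineages. The rate range comes from the divergence-time range
#' (mu_low at T_high, mu_high at T_low).
#'
#' @param d Distance in substitutions per site (>= 0); vectorised.
#' @param scenario A [divergence_scenario()].
#' @param site_class Optional label (`"synonymous"`, `"nonsynonymous"`,
#'   `"fourfold"`).
#' @return Tibble with `site_class`, `d`, `mu`, `mu_low`, `mu_high`
#'   (per site per year).
#' @export
substitution_rate <- function(d, scenario, site_class = NA_character_) {
  stopifnot(inherits(scenario, "divergence_scenario"))
  if (any(d < 0, na.rm = TRUE)) stop("d must be >= 0", call. = FALSE)
  tibble(
    site_class = site_class, d = d,
    mu = d / (2 * scenario$T_years),
    mu_low = d / (2 * scenario$T_high_years),
    mu_high = d / (2 * scenario$T_low_years)
  )
}

#' Apportion a pairwise distance onto asymmetric lineages
#'
#' When one lineage evolves rho times faster than the other, the pairwise
#' distance d accumulated over time T on each side splits as
#' mu_slow = d / ((1 + rho) T) and mu_fast = rho d / ((1 + rho) T), so
#' that (mu_slow + mu_fast) T = d exactly.
#'
#' @inheritParams substitution_rate
#' @return Tibble with `d`, `mu_slow`, `mu_fast`.
#' @export
apportion_lineage_rates <- function(d, scenario) {
  stopifnot(inherits(scenario, "divergence_scenario"))
  if (scenario$rho < 1) stop("rho must be >= 1", call. = FALSE)
  tibble(
    d = d,
    mu_slow = d / ((1 + scenario$rho) * scenario$T_years),
    mu_fast = scenario$rho * d / ((1 + scenario$rho) * scenario$T_years)
  )
}

#' Clade-level summary of per-pair estimates
#'
#' Arithmetic means of dS, d4 and dN, the mean of per-gene dN/dS ratios
#' (not the ratio of mean dN over mean dS, which differs whenever omega
#' and dS covary across genes), and the fraction of genes with omega > 1.
#'
#' @param kept Tibble of filtered estimates (non-empty, status `"ok"`).
#' @param clade Optional clade label.
#' @return One-row tibble: `clade`, `n`, `mean_dS`, `mean_d4`, `mean_dN`,
#'   `mean_omega`, `frac_omega_gt1`, `n_d4` (genes with a defined d4).
#' @export
clade_summary <- function(kept, clade = NA_character_) {
  if (nrow(kept) == 0) stop("empty estimate set", call. = FALSE)
  tibble(
    clade = clade, n = nrow(kept),
    mean_dS = mean(kept$dS), mean_d4 = mean(kept$d4, na.rm = TRUE),
    mean_dN = mean(kept$dN), mean_omega = mean(kept$omega),
    frac_omega_gt1 = mean(kept$omega > 1),
    n_d4 = sum(!is.na(kept$d4))
  )
}

#' Fold-change table between two clade summaries
#'
#' Ratios of mean dS, d4, dN, the implied absolute rates muS, mu4D, muN
#' (each clade under its own divergence-time scenario) and mean dN/dS,
#' oriented numerator:denominator. Labels are rounded half-even to one
#' decimal and rendered `"x:1"`, or `"1:x"` when the numerator is the
#' smaller value.
#'
#' @param summary_num,summary_den [clade_summary()] rows; the numerator
#'   clade is conventionally the faster-evolving one.
#' @param scenario_num,scenario_den Their [divergence_scenario()]s.
#' @return Tibble: `quantity`, `value_num`, `value_den`, `fold`, `label`.
#' @export
fold_change_table <- function(summary_num, summary_den, scenario_num,
                              scenario_den) {
  q <- list(
    dS = c(summary_num$mean_dS, summary_den$mean_dS),
    d4 = c(summary_num$mean_d4, summary_den$mean_d4),
    dN = c(summary_num$mean_dN, summary_den$mean_dN),
    muS = c(
      substitution_rate(summary_num$mean_dS, scenario_num)$mu,
      substitution_rate(summary_den$mean_dS, scenario_den)$mu
    ),
    mu4D = c(
      substitution_rate(summary_num$mean_d4, scenario_num)$mu,
      substitution_rate(summary_den$mean_d4, scenario_den)$mu
    ),
    muN = c(
      substitution_rate(summary_num$mean_dN, scenario_num)$mu,
      substitution_rate(summary_den$mean_dN, scenario_den)$mu
    ),
    omega = c(summary_num$mean_omega, summary_den$mean_omega)
  )
  purrr::imap(q, function(v, nm) {
    if (!all(is.finite(v)) || v[2] == 0) {
      return(tibble(
        quantity = nm, value_num = v[1], value_den = v[2],
        fold = NA_real_, label = NA_character_
      ))
    }
    fold <- v[1] / v[2]
    label <- if (fold >= 1) {
      sprintf("%.1f:1", round(fold, 1))
    } else {
      sprintf("1:%.1f", round(1 / fold, 1))
    }
    tibble(
      quantity = nm, value_num = v[1], value_den = v[2],
      fold = fold, label = label
    )
  }) |> dplyr::bind_rows()
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the per-gene values with replacement `n_reps` times and
#' takes the percentile interval of the resampled means. Deterministic
#' for a fixed seed.
#'
#' @param values Numeric vector (length >= 2; NAs dropped).
#' @param n_reps Bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return One-row tibble: `mean`, `ci_low`, `ci_high`, `n`, `n_reps`.
#' @export
bootstrap_ci <- function(values, n_reps = 1000, level = 0.95, seed = 1L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  means <- withr::with_seed(seed, {
    idx <- sample.int(n, n * n_reps, replace = TRUE)
    colMeans(matrix(values[idx], nrow = n))
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(means, c(alpha, 1 - alpha), type = 7))
  tibble(
    mean = mean(values), ci_low = ci[1], ci_high = ci[2],
    n = n, n_reps = n_reps
  )
}
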