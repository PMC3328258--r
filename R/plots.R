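#' Density plots of per-gene dS and dN by clade
#'
#' Smoothed density plots of the synonymous and non-synonymous distance
#' distributions, one panel per distance class, coloured by clade --
#' the standard way to show a slow, unsaturated clade against a fast,
#' partly saturated one.
#'
#' @param estimates Per-pair estimate tibble with a `clade` column.
#' @param trim_quantile Upper quantile at which each panel's x axis is
#'   trimmed (long saturated tails otherwise flatten the plot).
#' @return A ggplot object.
#' @export
plot_rate_distributions <- function(estimates, trim_quantile = 0.99) {
  stopifnot("clade" %in% names(estimates))
  long <- tidyr::pivot_longer(
    dplyr::select(estimates, "clade", "dS", "dN"),
    cols = c("dS", "dN"), names_to = "distance", values_to = "value"
  )
  long <- long[!is.na(long$value), , drop = FALSE]
  long <- long |>
    dplyr::group_by(.data$distance) |>
    dplyr::filter(.data$value <= quantile(.data$value, trim_quantile)) |>
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, colour = .data$clade)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~distance, scales = "free") +
    ggplot2::labs(x = "substitutions per site", y = "density") +
    ggplot2::theme_minimal()
}

#' Histogram of per-gene dN/dS
#'
#' @param estimates Per-pair estimate tibble with a `clade` column.
#' @param max_omega Genes above this omega are not shown.
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_omega_histogram <- function(estimates, max_omega = 2, bins = 200) {
  stopifnot("clade" %in% names(estimates))
  d <- estimates[!is.na(estimates$omega) & estimates$omega <= max_omega, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$omega)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~clade, ncol = 1, scales = "free_y") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "dN/dS", y = "genes") +
    ggplot2::theme_minimal()
}

#' Mean dN/dS per functional category and clade
#'
#' Dot-and-error-bar plot of mean per-gene omega for each annotation term
#' in each clade (bars are standard errors of the mean).
#'
#' @param estimates_a,estimates_b Per-pair estimate tibbles for the two
#'   clades.
#' @param annotations Long tibble `gene_id`, `term`.
#' @param clade_names Length-2 labels.
#' @return A ggplot object.
#' @export
plot_omega_by_category <- function(estimates_a, estimates_b, annotations,
                                   clade_names = c("clade_a", "clade_b")) {
  d <- dplyr::bind_rows(
    dplyr::mutate(annotated_values(estimates_a, annotations, "omega"),
      clade = clade_names[1]
    ),
    dplyr::mutate(annotated_values(estimates_b, annotations, "omega"),
      clade = clade_names[2]
    )
  )
  s <- d |>
    dplyr::group_by(.data$term, .data$clade) |>
    dplyr::summarise(
      mean_omega = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(s, ggplot2::aes(
    x = .data$mean_omega, y = .data$term, colour = .data$clade
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(
        xmin = .data$mean_omega - .data$se,
        xmax = .data$mean_omega + .data$se
      ),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(x = "mean dN/dS", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.study_bundle <- function(object, ...) {
  d <- dplyr::left_join(object$truth,
    dplyr::select(object$codon_pairs, "pair_id", "clade"),
    by = c("pair_id", "clade")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dS_true, fill = .data$clade)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "true dS", y = "genes") +
    ggplot2::theme_minimal()
}
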