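#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Goldman-Yang fit into the standard per-pair estimate row
#'
#' @param x A [gy94_ml_estimate()] result.
#' @param ... Unused.
#' @return One-row tibble of per-pair estimates.
#' @export
tidy.gy94_fit <- function(x, ...) {
  x$estimate
}

#' One-row fit summary of a Goldman-Yang fit
#'
#' @param x A [gy94_ml_estimate()] result.
#' @param ... Unused.
#' @return One-row tibble: `lnL`, `n_codons`, `n_patterns`, `n_starts`,
#'   `status`.
#' @export
glance.gy94_fit <- function(x, ...) {
  tibble(
    lnL = x$lnL, n_codons = x$estimate$n_codons,
    n_patterns = nrow(x$patterns), n_starts = x$n_starts,
    status = x$estimate$status
  )
}

#' Tidy a codon alignment into its column mask
#'
#' @param x A [codon_alignment].
#' @param ... Unused.
#' @return Tibble with one row per codon column: `column`, `codon_a`,
#'   `codon_b`, `keep`, `reason`.
#' @export
tidy.codon_alignment <- function(x, ...) {
  x$column_mask
}
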