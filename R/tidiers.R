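#' Tidy a pair-report table into per-link records
#'
#' Unnests the per-link distance records of an `xlmap_reports` tibble into
#' one row per cross-link per PPI-structure pair.
#'
#' @param x An `xlmap_reports` tibble.
#' @param ... Unused.
#' @return A tibble of distance records: link sites, linker, entry, winning
#'   chains/residues, `distance`, `status`.
#' @exportS3Method generics::tidy
tidy.xlmap_reports <- function(x, ...) {
  records_table(x)
}

#' One-row summary of a mapping run
#'
#' @param x An `xlmap_reports` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `n_links`, `n_mapped`,
#'   `n_satisfied`, `n_over`, `mean_score`, `best_score`.
#' @exportS3Method generics::glance
glance.xlmap_reports <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_links = sum(x$n_total),
    n_mapped = sum(x$n_mapped),
    n_satisfied = sum(x$n_satisfied),
    n_over = sum(x$n_over),
    mean_score = if (nrow(x)) mean(x$score) else NA_real_,
    best_score = if (nrow(x)) max(x$score) else NA_real_)
}

#' Score-distribution plot for PPI-structure pairs
#'
#' Histogram of pair scores (bin width 5 on `[0, 100]`), the global
#' dynamism-distribution view: mass near 100 indicates cross-links
#' consistent with static deposited structures, mass at low scores flags
#' dynamic or mismatched pairs.
#'
#' @param object A scored `xlmap_reports` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.xlmap_reports <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(breaks = seq(0, 100, by = 5),
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "pair score", y = "PPI-structure pairs",
                  title = "Score distribution") +
    ggplot2::theme_minimal()
}

#' Distance-versus-threshold plot for mapped cross-links
#'
#' Dot plot of measured Ca-Ca distances per PPI-structure pair with the
#' linker maximum drawn as a dashed line; over-length links stand out above
#' it.
#'
#' @param reports A scored `xlmap_reports` tibble.
#' @return A ggplot object.
#' @export
plot_link_distances <- function(reports) {
  rec <- records_table(reports)
  rec <- rec[rec$status != "unmapped", , drop = FALSE]
  ggplot2::ggplot(rec, ggplot2::aes(
    x = paste(.data$protein_a, .data$protein_b, sep = "-"),
    y = .data$distance, colour = .data$status)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$max_ca_distance),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(satisfied = "forestgreen", over_length = "firebrick")) +
    ggplot2::labs(x = "PPI", y = "Ca-Ca distance (A)", colour = NULL) +
    ggplot2::theme_minimal()
}
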