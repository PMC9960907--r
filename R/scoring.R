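#' Score features for PPI-structure pairs
#'
#' Derives the per-pair feature set the dynamism score is built from:
#'
#' * `f_sat` — satisfaction fraction, `n_satisfied / n_mapped` (0 when
#'   nothing is mapped): the core agreement signal between the cross-links
#'   and the structure.
#' * `coverage` — `n_mapped / n_total`: how much of the PPI's evidence the
#'   structure can speak to at all.
#' * `violation` — mean relative excess of the over-length links,
#'   `mean((distance - max) / max)`, 0 when none are over-length: how badly,
#'   not just how often, the structure is contradicted.
#' * `evidence` — `n_mapped / (n_mapped + k)`: a pseudo-count damping so a
#'   pair supported by a single mapped link cannot look as convincing as one
#'   supported by dozens.
#'
#' @param reports An `xlmap_reports` tibble (see [evaluate_pair()]).
#' @param k Pseudo-count for the evidence feature; the default 3 means three
#'   mapped links reach half the asymptotic confidence.
#' @return `reports` with columns `f_sat`, `coverage`, `violation`,
#'   `evidence` added/replaced.
#' @export
compute_features <- function(reports, k = 3) {
  stopifnot(k >= 0)
  viol <- vapply(reports$records, function(r) {
    ov <- r[r$status == "over_length", , drop = FALSE]
    if (nrow(ov) == 0) 0
    else mean((ov$distance - ov$max_ca_distance) / ov$max_ca_distance)
  }, numeric(1))
  reports |>
    mutate(
      f_sat = ifelse(.data$n_mapped > 0,
                     .data$n_satisfied / .data$n_mapped, 0),
      coverage = ifelse(.data$n_total > 0,
                        .data$n_mapped / .data$n_total, 0),
      violation = viol,
      evidence = ifelse(.data$n_mapped + k > 0,
                        .data$n_mapped / (.data$n_mapped + k), 0))
}

#' Bounded structural-dynamism score
#'
#' Combines the features into a score in `[0, 100]`:
#'
#' `score = 100 * evidence * max(0, w_s * f_sat + w_c * coverage - w_v * min(violation, 1))`
#'
#' High scores flag PPI-structure pairs whose cross-links are consistent
#' with the deposited structure (relatively static interactions); low scores
#' flag dynamic or mismatched pairs. The score is monotone: non-decreasing
#' in `f_sat` and `coverage`, non-increasing in `violation`, and approaches
#' 100 as mapped evidence accumulates on a perfectly consistent pair.
#'
#' @param reports An `xlmap_reports` tibble with feature columns (see
#'   [compute_features()]).
#' @param weights Named numeric vector `c(w_s=, w_c=, w_v=)`; `w_s` and
#'   `w_c` must be non-negative and sum to 1, `w_v >= 0`.
#' @return `reports` with a `score` column added/replaced.
#' @export
compute_score <- function(reports,
                          weights = c(w_s = 0.7, w_c = 0.3, w_v = 0.2)) {
  w <- validate_weights(weights)
  raw <- 100 * reports$evidence *
    pmax(0, w[["w_s"]] * reports$f_sat + w[["w_c"]] * reports$coverage -
           w[["w_v"]] * pmin(reports$violation, 1))
  reports$score <- pmin(100, pmax(0, raw))
  attr(reports, "weights") <- w
  reports
}

validate_weights <- function(weights) {
  need <- c("w_s", "w_c", "w_v")
  if (!all(need %in% names(weights))) {
    abort("weights must be named c(w_s=, w_c=, w_v=)")
  }
  w <- weights[need]
  if (any(!is.finite(w)) || any(w < 0)) abort("score weights must be non-negative")
  if (abs(w[["w_s"]] + w[["w_c"]] - 1) > 1e-9) {
    abort("w_s + w_c must equal 1")
  }
  w
}

#' Ranked score table and score distribution
#'
#' Produces the per-pair score table, sorted by score (descending) with
#' deterministic tie-breaking by entry id and protein pair, plus the global
#' score histogram (bin width 5 over `[0, 100]`) used for the
#' dynamism-distribution view.
#'
#' @param reports A scored `xlmap_reports` tibble.
#' @return A tibble with columns `protein_a`, `protein_b`, `entry_id`,
#'   `n_total`, `n_mapped`, `n_satisfied`, `n_over`, `f_sat`, `coverage`,
#'   `violation`, `score`, carrying the histogram as attribute `histogram`
#'   (tibble: `bin_lo`, `bin_hi`, `count`).
#' @export
score_table <- function(reports) {
  cols <- c("protein_a", "protein_b", "entry_id", "n_total", "n_mapped",
            "n_satisfied", "n_over", "f_sat", "coverage", "violation",
            "score")
  tab <- as_tibble(reports)[, cols, drop = FALSE] |>
    arrange(dplyr::desc(.data$score), .data$entry_id, .data$protein_a,
            .data$protein_b)
  attr(tab, "histogram") <- score_histogram(tab$score)
  attr(tab, "weights") <- attr(reports, "weights")
  tab
}

# histogram of scores with fixed bin width 5 on [0,100]; scores of exactly
# 100 fall in the top bin
score_histogram <- function(scores, width = 5) {
  lo <- seq(0, 100 - width, by = width)
  counts <- vapply(lo, function(b) {
    hi <- b + width
    sum(scores >= b & (scores < hi | (hi == 100 & scores == 100)))
  }, integer(1))
  tibble(bin_lo = lo, bin_hi = lo + width, count = counts)
}
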