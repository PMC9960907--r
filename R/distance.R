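#' Euclidean distance between two residue coordinates
#'
#' @param a,b Numeric 3-vectors (Angstrom).
#' @return The Euclidean norm of `a - b`, in Angstrom.
#' @examples
#' residue_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
residue_distance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3, all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

#' Evaluate every cross-link of one PPI on one structure
#'
#' For each cross-link, all combinations of chain-copy hits for site A and
#' site B with a present Ca are enumerated (identical (chain, residue)
#' self-pairings are excluded for intra-protein links), the Ca-Ca distance is
#' the minimum over combinations — a cross-link is geometrically satisfied if
#' any copy pair can satisfy it — and the link is classified against its
#' linker's maximum distance: `satisfied` (distance <= max), `over_length`
#' (distance > max), or `unmapped` (no valid combination). The winning
#' combination's chains and author residue numbers are recorded, so
#' intra-chain and cross-chain satisfaction are distinguishable in the
#' output.
#'
#' @param links Cross-link tibble for one PPI (columns `protein_a`, `pos_a`,
#'   `protein_b`, `pos_b`, `linker`, `spectral_count`).
#' @param structure An `xlmap_structure` (used for its entry id), or an entry
#'   id string.
#' @param maps Residue-map tibble covering this structure's entry.
#' @param linkers Linker table (see [default_linkers()]); a linker name
#'   absent from the table is an error.
#' @return A one-row tibble of class `xlmap_reports`: `protein_a`,
#'   `protein_b`, `entry_id`, counts (`n_total`, `n_mapped`, `n_satisfied`,
#'   `n_over`, `n_unmapped`), and a `records` list-column holding the
#'   per-link distance records.
#' @export
evaluate_pair <- function(links, structure, maps, linkers = default_linkers()) {
  entry <- if (inherits(structure, "xlmap_structure")) structure$entry_id
           else as.character(structure)
  lk_max <- linker_max(links$linker, linkers)
  intra <- links$protein_a == links$protein_b

  recs <- vector("list", nrow(links))
  for (i in seq_len(nrow(links))) {
    hits_a <- map_site(links$protein_a[i], links$pos_a[i], maps, entry_id = entry)
    hits_b <- map_site(links$protein_b[i], links$pos_b[i], maps, entry_id = entry)
    rec <- tibble(
      protein_a = links$protein_a[i], pos_a = links$pos_a[i],
      protein_b = links$protein_b[i], pos_b = links$pos_b[i],
      linker = links$linker[i], spectral_count = links$spectral_count[i],
      entry_id = entry,
      chain_a = NA_character_, auth_res_a = NA_integer_, ins_a = NA_character_,
      chain_b = NA_character_, auth_res_b = NA_integer_, ins_b = NA_character_,
      distance = NA_real_, max_ca_distance = lk_max[i],
      status = "unmapped")
    if (nrow(hits_a) > 0 && nrow(hits_b) > 0) {
      combos <- cross_join(
        select(hits_a, chain_a = "chain_id", auth_res_a = "auth_seq_num",
               ins_a = "ins_code", xa = "x", ya = "y", za = "z"),
        select(hits_b, chain_b = "chain_id", auth_res_b = "auth_seq_num",
               ins_b = "ins_code", xb = "x", yb = "y", zb = "z"))
      if (intra[i]) {
        self <- combos$chain_a == combos$chain_b &
          combos$auth_res_a == combos$auth_res_b &
          combos$ins_a == combos$ins_b
        combos <- combos[!self, , drop = FALSE]
      }
      if (nrow(combos) > 0) {
        combos$distance <- sqrt((combos$xa - combos$xb)^2 +
                                (combos$ya - combos$yb)^2 +
                                (combos$za - combos$zb)^2)
        combos <- arrange(combos, .data$distance, .data$chain_a,
                          .data$auth_res_a, .data$chain_b, .data$auth_res_b)
        w <- combos[1, ]
        rec$chain_a <- w$chain_a; rec$auth_res_a <- w$auth_res_a
        rec$ins_a <- w$ins_a
        rec$chain_b <- w$chain_b; rec$auth_res_b <- w$auth_res_b
        rec$ins_b <- w$ins_b
        rec$distance <- w$distance
        rec$status <- if (w$distance <= lk_max[i]) "satisfied" else "over_length"
      }
    }
    recs[[i]] <- rec
  }
  records <- if (length(recs)) bind_rows(recs) else empty_records()
  records <- arrange(records, .data$protein_a, .data$pos_a, .data$protein_b,
                     .data$pos_b, .data$linker)
  new_reports(tibble(
    protein_a = if (nrow(links)) links$protein_a[1] else NA_character_,
    protein_b = if (nrow(links)) links$protein_b[1] else NA_character_,
    entry_id = entry,
    n_total = nrow(records),
    n_mapped = sum(records$status != "unmapped"),
    n_satisfied = sum(records$status == "satisfied"),
    n_over = sum(records$status == "over_length"),
    n_unmapped = sum(records$status == "unmapped"),
    records = list(records)))
}

empty_records <- function() {
  tibble(protein_a = character(), pos_a = integer(), protein_b = character(),
         pos_b = integer(), linker = character(), spectral_count = integer(),
         entry_id = character(), chain_a = character(),
         auth_res_a = integer(), ins_a = character(), chain_b = character(),
         auth_res_b = integer(), ins_b = character(), distance = numeric(),
         max_ca_distance = numeric(), status = character())
}

new_reports <- function(df) {
  class(df) <- c("xlmap_reports", class(df))
  df
}

#' Evaluate all candidate PPI-structure pairs
#'
#' Runs [evaluate_pair()] over a candidate pair table, keeps only pairs with
#' at least one mapped link (pairs whose structure matches neither protein
#' carry no information), and attaches score features and the pair score.
#'
#' @param ppis PPI tibble from [group_ppis()].
#' @param pairs Candidate pair tibble from [candidate_pairs()].
#' @param maps Residue-map tibble from [build_residue_maps()].
#' @param linkers Linker table.
#' @param k Pseudo-count of the evidence feature (see [compute_features()]).
#' @param weights Score weights, see [compute_score()].
#' @param keep_unmapped Keep pairs with `n_mapped == 0` (default drops them).
#' @return An `xlmap_reports` tibble, one row per retained PPI-structure
#'   pair, with count, feature and `score` columns and a `records`
#'   list-column.
#' @export
evaluate_pairs <- function(ppis, pairs, maps, linkers = default_linkers(),
                           k = 3, weights = c(w_s = 0.7, w_c = 0.3, w_v = 0.2),
                           keep_unmapped = FALSE) {
  ppi_key <- paste(ppis$protein_a, ppis$protein_b, sep = "\r")
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    idx <- match(paste(pairs$protein_a[i], pairs$protein_b[i], sep = "\r"),
                 ppi_key)
    out[[i]] <- evaluate_pair(ppis$links[[idx]] |>
                                mutate(protein_a = ppis$protein_a[idx],
                                       protein_b = ppis$protein_b[idx]),
                              pairs$entry_id[i], maps, linkers)
  }
  reports <- bind_rows(out)
  if (nrow(reports) && !keep_unmapped) {
    reports <- reports[reports$n_mapped > 0, , drop = FALSE]
  }
  if (nrow(reports) == 0) {
    reports <- tibble(protein_a = character(), protein_b = character(),
                      entry_id = character(), n_total = integer(),
                      n_mapped = integer(), n_satisfied = integer(),
                      n_over = integer(), n_unmapped = integer(),
                      records = list())
  }
  reports <- compute_features(reports, k = k)
  reports <- compute_score(reports, weights = weights)
  new_reports(arrange(as_tibble(reports), .data$protein_a, .data$protein_b,
                      .data$entry_id))
}
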