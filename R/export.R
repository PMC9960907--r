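# Results export: the three TSV result files and per-pair PyMOL scripts.
# All files are written atomically (temp file + rename), carry a "#" header
# echoing the tool version (plus config where relevant), use tab separation
# (site strings never contain tabs), and report distances to 3 decimal
# places with round-half-even, so repeated runs on identical inputs are
# byte-identical.

#' Write the comprehensive distance file
#'
#' One row per distance record across all PPI-structure pairs: protein pair,
#' link sites, linker, structure entry, winning chains and author residue
#' numbers, distance (Angstrom, 3 decimals, empty when unmapped) and status.
#'
#' @param reports An `xlmap_reports` tibble.
#' @param path Output TSV path.
#' @param header_extra Additional "#" header lines (config echo).
#' @return The path, invisibly.
#' @export
write_comprehensive <- function(reports, path, header_extra = character()) {
  rec <- records_table(reports)
  df <- tibble(
    protein_a = rec$protein_a, pos_a = rec$pos_a,
    protein_b = rec$protein_b, pos_b = rec$pos_b,
    linker = rec$linker, spectral_count = rec$spectral_count,
    entry_id = rec$entry_id,
    chain_a = ifelse(is.na(rec$chain_a), "", rec$chain_a),
    auth_res_a = ifelse(is.na(rec$auth_res_a), "",
                        paste0(rec$auth_res_a, rec$ins_a)),
    chain_b = ifelse(is.na(rec$chain_b), "", rec$chain_b),
    auth_res_b = ifelse(is.na(rec$auth_res_b), "",
                        paste0(rec$auth_res_b, rec$ins_b)),
    distance = format_distance(rec$distance),
    status = rec$status)
  write_lines_atomic(c(tsv_header(header_extra), df_to_tsv_lines(df)), path)
}

# flatten the records list-column in deterministic order
records_table <- function(reports) {
  if (nrow(reports) == 0) return(empty_records())
  bind_rows(reports$records) |>
    arrange(.data$entry_id, .data$protein_a, .data$pos_a, .data$protein_b,
            .data$pos_b, .data$linker)
}

#' Write the by-structure summary file
#'
#' One row per structure entry: how many PPIs it covers, mapped / satisfied
#' / over-length link counts summed over its pairs, and the best score among
#' its pairs.
#'
#' @inheritParams write_comprehensive
#' @return The path, invisibly.
#' @export
write_by_structure <- function(reports, path, header_extra = character()) {
  df <- as_tibble(reports) |>
    group_by(.data$entry_id) |>
    summarise(n_ppis = n(),
              n_links_mapped = sum(.data$n_mapped),
              n_satisfied = sum(.data$n_satisfied),
              n_over = sum(.data$n_over),
              best_score = if (n() > 0) max(.data$score) else NA_real_,
              .groups = "drop") |>
    arrange(.data$entry_id) |>
    mutate(best_score = format_distance(.data$best_score))
  if (nrow(reports) == 0) {
    df <- tibble(entry_id = character(), n_ppis = integer(),
                 n_links_mapped = integer(), n_satisfied = integer(),
                 n_over = integer(), best_score = character())
  }
  write_lines_atomic(c(tsv_header(header_extra), df_to_tsv_lines(df)), path)
}

#' Write the score file
#'
#' The ranked PPI-structure score table from [score_table()], highest score
#' first. The header echoes the score weights so a run's scoring is
#' self-describing.
#'
#' @inheritParams write_comprehensive
#' @return The path, invisibly.
#' @export
write_scores <- function(reports, path, header_extra = character()) {
  tab <- score_table(reports)
  w <- attr(tab, "weights")
  wline <- if (!is.null(w)) {
    sprintf("# score weights: w_s=%g w_c=%g w_v=%g", w[["w_s"]], w[["w_c"]],
            w[["w_v"]])
  } else character()
  df <- tab |>
    mutate(f_sat = format_distance(.data$f_sat),
           coverage = format_distance(.data$coverage),
           violation = format_distance(.data$violation),
           score = format_distance(.data$score))
  write_lines_atomic(
    c(tsv_header(c(wline, header_extra)), df_to_tsv_lines(df)), path)
}

#' Write a PyMOL visualization script for one PPI-structure pair
#'
#' Emits a `.pml` script that loads `<entry>.cif`, draws one `distance`
#' object per mapped cross-link using author chain / residue / `CA`
#' selections (insertion codes included), colors satisfied and over-length
#' links with two configurable colors, and labels the run with the pair
#' score. Pairs with no mapped record produce no script.
#'
#' @param report One row of an `xlmap_reports` tibble.
#' @param dir Output directory for the script.
#' @param satisfied_color,over_color PyMOL color names for the two classes.
#' @param structure_dir Directory prefix for the `load` command (default:
#'   load `<entry>.cif` from the script's working directory).
#' @return The script path, or `NA` (with a message) if nothing was mapped.
#' @export
write_pymol <- function(report, dir, satisfied_color = "green",
                        over_color = "red", structure_dir = NULL) {
  rec <- report$records[[1]]
  rec <- rec[rec$status != "unmapped", , drop = FALSE]
  if (nrow(rec) == 0) {
    inform(sprintf("no mapped record for %s-%s on %s; no PyMOL script",
                   report$protein_a, report$protein_b, report$entry_id))
    return(invisible(NA_character_))
  }
  entry <- report$entry_id
  obj <- paste0("m_", entry)
  cif <- paste0(entry, ".cif")
  if (!is.null(structure_dir)) cif <- file.path(structure_dir, cif)
  lines <- c(
    sprintf("# xlmapr %s", as.character(packageVersion("xlmapr"))),
    sprintf("# PPI %s - %s on entry %s; score %s",
            report$protein_a, report$protein_b, entry,
            format_distance(report$score)),
    sprintf("load %s, %s", cif, obj),
    sprintf("hide everything, %s", obj),
    sprintf("show cartoon, %s", obj),
    sprintf("color grey80, %s", obj))
  sel <- function(chain, res, ins) {
    sprintf("%s and chain %s and resi %s%s and name CA", obj, chain, res, ins)
  }
  for (i in seq_len(nrow(rec))) {
    name <- sprintf("xl_%03d_%s", i,
                    ifelse(rec$status[i] == "satisfied", "sat", "over"))
    col <- if (rec$status[i] == "satisfied") satisfied_color else over_color
    lines <- c(
      lines,
      sprintf("distance %s, %s, %s", name,
              sel(rec$chain_a[i], rec$auth_res_a[i], rec$ins_a[i]),
              sel(rec$chain_b[i], rec$auth_res_b[i], rec$ins_b[i])),
      sprintf("set dash_color, %s, %s", col, name),
      sprintf("show spheres, %s", sel(rec$chain_a[i], rec$auth_res_a[i],
                                      rec$ins_a[i])),
      sprintf("show spheres, %s", sel(rec$chain_b[i], rec$auth_res_b[i],
                                      rec$ins_b[i])))
  }
  lines <- c(lines,
             sprintf("group xlinks_%s, xl_*", entry),
             sprintf("set label_size, 14"),
             sprintf("print \"xlmapr score for %s-%s on %s: %s\"",
                     report$protein_a, report$protein_b, entry,
                     format_distance(report$score)))
  path <- file.path(dir, sprintf("%s_%s_%s.pml", report$protein_a,
                                 report$protein_b, entry))
  write_lines_atomic(lines, path)
}

#' Write all run outputs
#'
#' Writes the three result files (comprehensive distances, by-structure
#' summary, score table) and, optionally, one PyMOL script per pair with
#' mapped records.
#'
#' @param reports A scored `xlmap_reports` tibble.
#' @param out_dir Output directory (created if needed).
#' @param pymol Generate `.pml` scripts under `out_dir/pymol/`?
#' @param header_extra Config-echo header lines for the TSVs.
#' @param satisfied_color,over_color Colors passed to [write_pymol()].
#' @param structure_dir Passed to [write_pymol()].
#' @return A list of paths: `comprehensive`, `by_structure`, `scores`,
#'   `pymol` (character vector, possibly empty).
#' @export
write_outputs <- function(reports, out_dir, pymol = TRUE,
                          header_extra = character(),
                          satisfied_color = "green", over_color = "red",
                          structure_dir = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  comp <- file.path(out_dir, "comprehensive.tsv")
  bys <- file.path(out_dir, "by_structure.tsv")
  sco <- file.path(out_dir, "scores.tsv")
  write_comprehensive(reports, comp, header_extra)
  write_by_structure(reports, bys, header_extra)
  write_scores(reports, sco, header_extra)
  pml <- character(0)
  if (pymol && nrow(reports) > 0) {
    pdir <- file.path(out_dir, "pymol")
    dir.create(pdir, showWarnings = FALSE)
    for (i in seq_len(nrow(reports))) {
      p <- write_pymol(reports[i, ], pdir,
                       satisfied_color = satisfied_color,
                       over_color = over_color,
                       structure_dir = structure_dir)
      if (!is.na(p)) pml <- c(pml, p)
    }
  }
  list(comprehensive = comp, by_structure = bys, scores = sco, pymol = pml)
}
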