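# Synthetic scenes: toy structures with known geometry plus matched FASTA
# and cross-link tables, so the full pipeline is testable offline with
# planted ground truth. Residues sit on idealized helical traces (rise
# 1.5 A/residue, radius 2.3 A, 100 degrees/residue), one chain per protein,
# chains offset along x; the geometry is smooth and controllable, which is
# what lets both satisfied and over-length links be planted deterministically.
# These fixtures test bookkeeping and math, not biophysics.

#' Generate a synthetic PPI-structure scene
#'
#' Builds a toy structure of `n_chains` helical chains (one synthetic
#' protein per chain), writes it as a valid mmCIF together with a matching
#' FASTA and a generic cross-link TSV, and plants `n_links` cross-links of
#' which a fraction `frac_over` measure beyond the linker maximum. Planned
#' distances are computed from the 3-decimal coordinates actually written to
#' the mmCIF, so the pipeline reproduces them to well under 1e-6 Angstrom.
#' Everything is fully determined by `seed`.
#'
#' @param n_chains Number of chains / proteins (>= 1).
#' @param chain_len Residues per chain (>= 10).
#' @param n_links Number of cross-links to plant.
#' @param frac_over Fraction of links planted over-length, in `[0, 1]`.
#' @param linker One-row linker table (name, max_ca_distance); default DSS
#'   at 30 Angstrom.
#' @param seed Integer RNG seed.
#' @param dir Output directory (created; default a fresh temp dir).
#' @param entry_id 4-character entry id for the structure file.
#' @return A list of class `xlmap_scene`: file paths (`structure_path`,
#'   `fasta_path`, `links_path`, `dir`), `entry_id`, `chains` (tibble:
#'   `chain_id`, `accession`, `sequence`), `residues` (the written
#'   coordinates), `planned` (tibble of planted links with
#'   `planned_distance` and `planned_status`), `linker`, and `seed`.
#' @examples
#' scene <- make_scene(n_chains = 2, chain_len = 20, n_links = 4,
#'                     frac_over = 0.5, seed = 7)
#' scene$planned
#' @export
make_scene <- function(n_chains = 2, chain_len = 40, n_links = 10,
                       frac_over = 0.3,
                       linker = tibble(name = "DSS", max_ca_distance = 30),
                       seed = 1, dir = tempfile("scene"),
                       entry_id = "9syn") {
  stopifnot(n_chains >= 1, chain_len >= 10, n_links >= 1,
            frac_over >= 0, frac_over <= 1, nrow(linker) == 1,
            linker$max_ca_distance > 0)
  withr::with_seed(seed, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    chain_ids <- LETTERS[seq_len(n_chains)]
    accessions <- paste0("SYN", chain_ids)
    seqs <- vapply(chain_ids, function(.)
      paste(sample(aa, chain_len, replace = TRUE), collapse = ""),
      character(1))

    # helical trace per chain: rise 1.5 A, radius 2.3 A, 100 deg/residue;
    # chains offset 8 A apart along x
    res <- lapply(seq_len(n_chains), function(j) {
      t <- seq_len(chain_len) - 1
      theta <- t * 100 * pi / 180
      tibble(chain_id = chain_ids[j],
             auth_seq_num = seq_len(chain_len),
             ins_code = "",
             aa = strsplit(seqs[j], "")[[1]],
             x = round(2.3 * cos(theta) + (j - 1) * 8, 3),
             y = round(2.3 * sin(theta), 3),
             z = round(1.5 * t, 3))
    })
    residues <- bind_rows(res)

    # candidate site pairs with exact planned distances (from the rounded,
    # written coordinates)
    if (n_chains >= 2) {
      combos <- cross_join(
        residues |> rename(chain_a = "chain_id", pos_a = "auth_seq_num",
                           xa = "x", ya = "y", za = "z") |>
          select("chain_a", "pos_a", "xa", "ya", "za"),
        residues |> rename(chain_b = "chain_id", pos_b = "auth_seq_num",
                           xb = "x", yb = "y", zb = "z") |>
          select("chain_b", "pos_b", "xb", "yb", "zb")) |>
        filter(.data$chain_a < .data$chain_b)
    } else {
      combos <- cross_join(
        residues |> rename(chain_a = "chain_id", pos_a = "auth_seq_num",
                           xa = "x", ya = "y", za = "z") |>
          select("chain_a", "pos_a", "xa", "ya", "za"),
        residues |> rename(chain_b = "chain_id", pos_b = "auth_seq_num",
                           xb = "x", yb = "y", zb = "z") |>
          select("chain_b", "pos_b", "xb", "yb", "zb")) |>
        filter(.data$chain_a == .data$chain_b, .data$pos_b - .data$pos_a >= 4)
    }
    combos <- combos |>
      mutate(distance = sqrt((.data$xa - .data$xb)^2 +
                             (.data$ya - .data$yb)^2 +
                             (.data$za - .data$zb)^2))
    lmax <- linker$max_ca_distance
    over_pool <- combos[combos$distance > lmax, , drop = FALSE]
    sat_pool <- combos[combos$distance <= lmax, , drop = FALSE]
    n_over <- round(frac_over * n_links)
    n_sat <- n_links - n_over
    if (nrow(over_pool) < n_over) {
      abort(sprintf(
        paste0("cannot plant %d over-length link(s): only %d site pairs ",
               "exceed %g A for this geometry (try longer chains)"),
        n_over, nrow(over_pool), lmax))
    }
    if (nrow(sat_pool) < n_sat) {
      abort(sprintf(
        paste0("cannot plant %d satisfied link(s): only %d site pairs are ",
               "within %g A for this geometry"),
        n_sat, nrow(sat_pool), lmax))
    }
    planted <- bind_rows(
      over_pool[sample(nrow(over_pool), n_over), ] |>
        mutate(planned_status = "over_length"),
      sat_pool[sample(nrow(sat_pool), n_sat), ] |>
        mutate(planned_status = "satisfied"))
    acc_of <- setNames(accessions, chain_ids)
    planned <- planted |>
      mutate(protein_a = acc_of[.data$chain_a],
             protein_b = acc_of[.data$chain_b],
             linker = .env$linker$name,
             count = 1L,
             planned_distance = .data$distance) |>
      select("protein_a", "pos_a", "protein_b", "pos_b", "linker", "count",
             "planned_distance", "planned_status") |>
      arrange(.data$protein_a, .data$pos_a, .data$protein_b, .data$pos_b)

    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    structure_path <- file.path(dir, paste0(entry_id, ".cif"))
    fasta_path <- file.path(dir, "sequences.fasta")
    links_path <- file.path(dir, "links.tsv")
    write_mmcif_ca(entry_id, residues, structure_path)
    write_lines_atomic(
      as.vector(rbind(paste0(">", accessions), unname(seqs))), fasta_path)
    write_lines_atomic(
      df_to_tsv_lines(select(planned, -"planned_distance",
                             -"planned_status")),
      links_path)

    structure(list(
      dir = dir, structure_path = structure_path, fasta_path = fasta_path,
      links_path = links_path, entry_id = entry_id,
      chains = tibble(chain_id = chain_ids, accession = accessions,
                      sequence = unname(seqs)),
      residues = residues, planned = planned, linker = linker, seed = seed),
      class = "xlmap_scene")
  })
}

#' @export
print.xlmap_scene <- function(x, ...) {
  cat(sprintf("<xlmap_scene %s: %d chain(s) x %d residues, %d planted link(s) in %s>\n",
              x$entry_id, nrow(x$chains), max(x$residues$auth_seq_num),
              nrow(x$planned), x$dir))
  invisible(x)
}

# Minimal but valid PDBx/mmCIF writer: one CA atom per residue, single
# model, full atom_site loop. Byte-deterministic for identical input.
write_mmcif_ca <- function(entry_id, residues, path) {
  hdr <- c(
    paste0("data_", toupper(entry_id)),
    "#",
    paste0("_entry.id ", toupper(entry_id)),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  aa3 <- setNames(bio3d::aa123(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  ent <- match(residues$chain_id, unique(residues$chain_id))
  rows <- sprintf(
    "ATOM %d C CA . %s %s %d %d %s %.3f %.3f %.3f 1.00 0.00 %d %s %s CA 1",
    seq_len(nrow(residues)),
    aa3[residues$aa], residues$chain_id, ent, residues$auth_seq_num,
    ifelse(residues$ins_code == "", "?", residues$ins_code),
    residues$x, residues$y, residues$z,
    residues$auth_seq_num, aa3[residues$aa], residues$chain_id)
  write_lines_atomic(c(hdr, rows, "#"), path)
}

#' Substitute residues in a sequence
#'
#' Replaces `n_subs` distinct positions of `sequence` with different
#' residues, reproducibly under `seed`. Used to exercise alignment identity
#' thresholds: a length-L sequence with `n_subs` substitutions aligns to the
#' original with identity `(L - n_subs) / L`.
#'
#' @param sequence Amino-acid string.
#' @param n_subs Number of positions to substitute (`< nchar(sequence)`).
#' @param seed Integer RNG seed.
#' @return The mutated sequence string.
#' @export
make_mutated_chain <- function(sequence, n_subs, seed = 1) {
  stopifnot(n_subs >= 0, n_subs < nchar(sequence))
  if (n_subs == 0) return(sequence)
  withr::with_seed(seed, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    chars <- strsplit(sequence, "")[[1]]
    pos <- sample(length(chars), n_subs)
    for (p in pos) {
      chars[p] <- sample(setdiff(aa, chars[p]), 1)
    }
    paste(chars, collapse = "")
  })
}
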