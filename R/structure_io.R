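#' Read an mmCIF structure file
#'
#' Parses a PDBx/mmCIF file (optionally gzipped) into a light structure
#' container. Only the first model is kept. Polymer residues are retained
#' (waters and non-polymer ligands are excluded); a residue is any distinct
#' (auth_asym_id, auth_seq_id, insertion code) with standard-residue atoms or
#' a carbon alpha-carbon atom. The one-letter code comes from the component
#' id via a 3-to-1 table, with unknown components mapped to `X`. The Ca
#' anchor coordinate is the `CA` atom with the highest occupancy (ties broken
#' by alphabetically first altloc); residues lacking a Ca keep their place in
#' the chain sequence but carry no coordinate.
#'
#' Author numbering (`auth_asym_id`, `auth_seq_id`, insertion code) is the
#' user-facing coordinate system throughout, so generated PyMOL selections
#' resolve in a viewer.
#'
#' @param path Path to a `.cif` or `.cif.gz` file.
#' @param entry_id Entry identifier; defaults to the file name stem.
#' @return An object of class `xlmap_structure`: a list with `entry_id`,
#'   `model_number`, `residues` (tibble: `chain_id`, `chain_pos`,
#'   `auth_seq_num`, `ins_code`, `aa`, `x`, `y`, `z`, `has_ca`) and `chains`
#'   (tibble: `chain_id`, `sequence`, `n_res`).
#' @export
read_mmcif <- function(path, entry_id = NULL) {
  if (!file.exists(path)) abort(paste0("mmCIF file not found: ", path))
  if (is.null(entry_id)) {
    entry_id <- sub("\\.cif(\\.gz)?$", "", basename(path))
  }
  pdb <- tryCatch({
    res <- NULL
    utils::capture.output(
      res <- suppressWarnings(suppressMessages(
        bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))))
    res
  }, error = function(e) abort(paste0("cannot parse mmCIF ", path, ": ",
                                      conditionMessage(e))))
  atoms <- as_tibble(pdb$atom)
  if (nrow(atoms) == 0) abort(paste0("no atoms in ", path))

  atoms <- atoms |>
    mutate(ins_code = blank_ins(.data$insert),
           alt = ifelse(is.na(.data$alt), "", as.character(.data$alt)),
           o = ifelse(is.na(.data$o), 1, .data$o))

  # polymer filter: standard ATOM residues, plus HETATM residues that carry a
  # carbon CA (e.g. MSE); drops waters, ions and other ligands
  res_key <- paste(atoms$chain, atoms$resno, atoms$ins_code, sep = "\r")
  has_polymer_ca <- tapply(
    atoms$elety == "CA" & atoms$elesy %in% c("C", NA), res_key, any)
  is_atom_rec <- tapply(atoms$type == "ATOM", res_key, any)
  keep_keys <- names(has_polymer_ca)[has_polymer_ca | is_atom_rec]
  atoms <- atoms[res_key %in% keep_keys, , drop = FALSE]
  if (nrow(atoms) == 0) {
    abort(paste0("no polymer chains in ", path), class = "xlmap_no_polymer")
  }

  residues <- atoms |>
    group_by(chain_id = as.character(.data$chain),
             auth_seq_num = as.integer(.data$resno),
             ins_code = .data$ins_code) |>
    summarise(
      aa = aa_one_letter(first(.data$resid)),
      .ca = list({
        ca <- dplyr::pick(dplyr::everything()) |>
          filter(.data$elety == "CA", .data$elesy %in% c("C", NA))
        if (nrow(ca) == 0) c(NA_real_, NA_real_, NA_real_) else {
          ca <- ca[order(-ca$o, ca$alt), , drop = FALSE]
          c(ca$x[1], ca$y[1], ca$z[1])
        }
      }),
      .groups = "drop") |>
    mutate(x = map_dbl(.data$.ca, 1), y = map_dbl(.data$.ca, 2),
           z = map_dbl(.data$.ca, 3)) |>
    select(-".ca") |>
    mutate(has_ca = !is.na(.data$x)) |>
    arrange(.data$chain_id, .data$auth_seq_num, .data$ins_code) |>
    group_by(.data$chain_id) |>
    mutate(chain_pos = row_number()) |>
    ungroup() |>
    select("chain_id", "chain_pos", "auth_seq_num", "ins_code", "aa",
           "x", "y", "z", "has_ca")

  chains <- residues |>
    group_by(.data$chain_id) |>
    summarise(sequence = paste(.data$aa, collapse = ""), n_res = n(),
              .groups = "drop")

  structure(list(entry_id = entry_id, model_number = 1L,
                 residues = residues, chains = chains),
            class = "xlmap_structure")
}

# 3-letter -> 1-letter residue codes via bio3d's table; unknown -> X
aa_one_letter <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  out
}

#' @export
print.xlmap_structure <- function(x, ...) {
  cat(sprintf("<xlmap_structure %s: %d chain(s), %d residue(s)>\n",
              x$entry_id, nrow(x$chains), nrow(x$residues)))
  print(x$chains)
  invisible(x)
}

#' Load a set of mmCIF structures from a directory
#'
#' Reads `<entry>.cif` (or `.cif.gz`) for each requested entry from a local
#' directory (a pre-populated download cache works the same way). Entries
#' that are missing or fail to parse are logged and skipped; the pipeline
#' only stops if nothing survives.
#'
#' @param dir Directory containing structure files.
#' @param entries Character vector of entry ids; default: every `*.cif`/
#'   `*.cif.gz` file in `dir`.
#' @return A named list of `xlmap_structure` objects sorted by entry id, with
#'   a `failures` attribute (tibble: `entry_id`, `reason`).
#' @export
load_structure_set <- function(dir, entries = NULL) {
  if (!dir.exists(dir)) abort(paste0("structure directory not found: ", dir))
  if (is.null(entries)) {
    files <- list.files(dir, pattern = "\\.cif(\\.gz)?$")
    entries <- unique(sub("\\.cif(\\.gz)?$", "", files))
  }
  entries <- sort(unique(entries))
  out <- list()
  failures <- tibble(entry_id = character(), reason = character())
  for (e in entries) {
    path <- file.path(dir, paste0(e, ".cif"))
    if (!file.exists(path)) path <- file.path(dir, paste0(e, ".cif.gz"))
    if (!file.exists(path)) {
      failures <- bind_rows(failures, tibble(entry_id = e, reason = "not found"))
      next
    }
    s <- tryCatch(read_mmcif(path, entry_id = e), error = function(err) err)
    if (inherits(s, "error")) {
      failures <- bind_rows(failures,
                            tibble(entry_id = e, reason = conditionMessage(s)))
    } else {
      out[[e]] <- s
    }
  }
  if (length(out) == 0) {
    msg <- paste0("no structure loaded from ", dir,
                  if (nrow(failures)) paste0("; reasons: ",
                    paste(failures$entry_id, failures$reason,
                          sep = ": ", collapse = "; ")))
    abort(msg)
  }
  attr(out, "failures") <- failures
  out
}

#' Enumerate candidate PPI-structure pairs
#'
#' Pairs each PPI with the structures it should be evaluated on. With a
#' protein-to-entry mapping table, a PPI is paired only with entries listed
#' for either of its proteins; without one, every PPI is paired with every
#' structure and the sequence alignment stage discards non-matches.
#'
#' @param ppis PPI tibble from [group_ppis()].
#' @param structures Structure list from [load_structure_set()].
#' @param mapping Optional tibble with columns `accession`, `entry_id`.
#' @return A tibble with columns `protein_a`, `protein_b`, `entry_id`, in
#'   deterministic order.
#' @export
candidate_pairs <- function(ppis, structures, mapping = NULL) {
  entry_ids <- sort(unname(vapply(structures, function(s) s$entry_id,
                                  character(1))))
  pairs <- cross_join(
    select(ppis, "protein_a", "protein_b"),
    tibble(entry_id = entry_ids))
  if (!is.null(mapping)) {
    miss <- setdiff(c("accession", "entry_id"), names(mapping))
    if (length(miss)) {
      abort(paste0("mapping table missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    allowed <- paste(mapping$accession, mapping$entry_id, sep = "\r")
    pairs <- pairs[
      paste(pairs$protein_a, pairs$entry_id, sep = "\r") %in% allowed |
      paste(pairs$protein_b, pairs$entry_id, sep = "\r") %in% allowed, ,
      drop = FALSE]
  }
  arrange(pairs, .data$protein_a, .data$protein_b, .data$entry_id)
}
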