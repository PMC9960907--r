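#' Read a FASTA sequence database
#'
#' Reads an amino-acid FASTA file into a tibble of protein sequences.
#' Accessions are the first whitespace-delimited header token, with UniProt
#' `sp|ACC|NAME` / `tr|ACC|NAME` headers resolved to the accession field.
#' Sequences are upper-cased; gap (`-`, `.`) and stop (`*`) characters are
#' stripped, and any character outside the 20 standard residues is replaced
#' by `X`. Duplicate accessions keep the first record with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `sequence`, `length`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P02769|ALBU_BOVIN", "MKWVTF"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) abort(paste0("cannot read FASTA: ",
                                                   conditionMessage(e))))
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  acc <- resolve_accession(names(set))
  seqs <- unname(toupper(as.character(set)))
  seqs <- gsub("[-.*]", "", seqs)
  seqs <- gsub(sprintf("[^%s]", "ACDEFGHIKLMNPQRSTVWYX"), "X", seqs)
  keep <- !duplicated(acc)
  if (any(!keep)) {
    warn(paste0("duplicate accession(s) in FASTA, keeping first: ",
                paste(unique(acc[!keep]), collapse = ", ")))
  }
  out <- tibble(accession = acc[keep], sequence = seqs[keep])
  if (any(nchar(out$sequence) == 0)) abort("FASTA contains an empty sequence")
  out$length <- nchar(out$sequence)
  out
}

# Canonically order link endpoints so (protein_a, pos_a) <= (protein_b, pos_b)
# lexicographically, collapse duplicates over the full dedup key
# (protein_a, pos_a, protein_b, pos_b, linker), and validate endpoints against
# the sequence database. Rejected rows are recorded in the "rejections"
# attribute (columns: row, reason).
normalize_links <- function(df, sequences, source_row = NULL) {
  stopifnot(all(c("protein_a", "pos_a", "protein_b", "pos_b",
                  "linker", "spectral_count") %in% names(df)))
  if (is.null(source_row)) source_row <- seq_len(nrow(df))
  df$.row <- source_row

  swap <- df$protein_b < df$protein_a |
    (df$protein_b == df$protein_a & df$pos_b < df$pos_a)
  tmp_p <- df$protein_a[swap]; tmp_s <- df$pos_a[swap]
  df$protein_a[swap] <- df$protein_b[swap]; df$pos_a[swap] <- df$pos_b[swap]
  df$protein_b[swap] <- tmp_p; df$pos_b[swap] <- tmp_s

  len <- setNames(sequences$length, sequences$accession)
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(len[df$protein_a])] <- "accession not in FASTA"
  reason[is.na(reason) & is.na(len[df$protein_b])] <- "accession not in FASTA"
  ok <- is.na(reason)
  bad_pos <- ok & (df$pos_a > len[df$protein_a] | df$pos_b > len[df$protein_b])
  reason[bad_pos] <- "position beyond sequence length"
  reason[is.na(reason) & (df$pos_a < 1 | df$pos_b < 1)] <- "position < 1"

  rejections <- tibble(row = df$.row[!is.na(reason)],
                       reason = reason[!is.na(reason)])
  df <- df[is.na(reason), , drop = FALSE]

  out <- df |>
    group_by(.data$protein_a, .data$pos_a, .data$protein_b, .data$pos_b,
             .data$linker) |>
    summarise(spectral_count = sum(.data$spectral_count), .groups = "drop") |>
    mutate(intra = .data$protein_a == .data$protein_b) |>
    arrange(.data$protein_a, .data$pos_a, .data$protein_b, .data$pos_b,
            .data$linker)
  attr(out, "rejections") <- rejections
  out
}

#' Read pLink2-style cross-link identifications
#'
#' Parses a pLink2 cross-linked-peptides CSV in which each row is one PSM and
#' the linked sites are given as `ACC(pos)-ACC(pos)` in a `Proteins` column
#' (case-insensitive; UniProt `sp|ACC|NAME` tokens are resolved to the
#' accession). Site positions refer to database sequence coordinates. Rows
#' carrying more than one candidate site pair (ambiguous localization) are
#' dropped with a warning. PSM rows sharing the same canonical
#' (protein_a, pos_a, protein_b, pos_b, linker) collapse into one cross-link
#' whose `spectral_count` is the number of supporting rows.
#'
#' Links whose accession is missing from `sequences`, or whose position
#' exceeds that sequence's length, are dropped and recorded in the
#' `rejections` attribute.
#'
#' @param path Path to the CSV file.
#' @param sequences Sequence database tibble from [read_fasta()].
#' @param linker Linker name to assign when the file has no `Linker` column.
#' @return A tibble of cross-links with columns `protein_a`, `pos_a`,
#'   `protein_b`, `pos_b`, `linker`, `spectral_count`, `intra`, and a
#'   `rejections` attribute (tibble: `row`, `reason`).
#' @export
read_plink2 <- function(path, sequences, linker = "DSS") {
  if (!file.exists(path)) abort(paste0("pLink2 file not found: ", path))
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("cannot read pLink2 CSV: ",
                                     conditionMessage(e))))
  pcol <- names(raw)[tolower(names(raw)) %in% c("proteins", "protein")][1]
  if (is.na(pcol)) abort("pLink2 CSV lacks a 'Proteins' column")
  lcol <- names(raw)[tolower(names(raw)) == "linker"][1]

  sites <- as.character(raw[[pcol]])
  linkers <- if (!is.na(lcol)) as.character(raw[[lcol]]) else rep(linker, length(sites))

  # accessions may contain "-" (UniProt isoforms); the ")(" parentheses
  # disambiguate the pair separator
  pat <- "([^()/\\s,]+)\\((\\d+)\\)-([^()/\\s,]+)\\((\\d+)\\)"
  parsed <- vector("list", length(sites))
  skipped <- integer(0)
  for (i in seq_along(sites)) {
    s <- sub("/\\s*$", "", trimws(sites[i]))
    hits <- regmatches(s, gregexpr(pat, s))[[1]]
    if (length(hits) != 1L) {
      skipped <- c(skipped, i)
      next
    }
    g <- regmatches(hits, regexec(pat, hits))[[1]]
    parsed[[i]] <- tibble(
      protein_a = resolve_accession(g[2]), pos_a = as.integer(g[3]),
      protein_b = resolve_accession(g[4]), pos_b = as.integer(g[5]),
      linker = linkers[i], spectral_count = 1L, .row = i)
  }
  if (length(skipped)) {
    warn(sprintf("%d pLink2 row(s) skipped (malformed or ambiguous site string)",
                 length(skipped)))
  }
  df <- bind_rows(parsed)
  if (nrow(df) == 0) {
    df <- tibble(protein_a = character(), pos_a = integer(),
                 protein_b = character(), pos_b = integer(),
                 linker = character(), spectral_count = integer(), .row = integer())
  }
  out <- normalize_links(df, sequences, source_row = df$.row)
  attr(out, "skipped_rows") <- skipped
  out
}

#' Read generic cross-link TSV
#'
#' Reads the package's generic cross-link exchange format: a TSV with header
#' columns `protein_a`, `pos_a`, `protein_b`, `pos_b`, `linker`, and an
#' optional `count` column (default 1) giving the spectral evidence per row.
#' Normalization is the same as [read_plink2()]: canonical endpoint ordering,
#' deduplication over (protein_a, pos_a, protein_b, pos_b, linker) with
#' counts summed, and bounds checking against the sequence database.
#'
#' @inheritParams read_plink2
#' @param path Path to the TSV file.
#' @return A tibble of cross-links; see [read_plink2()].
#' @export
read_xlink_tsv <- function(path, sequences) {
  if (!file.exists(path)) abort(paste0("cross-link TSV not found: ", path))
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("protein_a", "pos_a", "protein_b", "pos_b", "linker")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("cross-link TSV missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"count" %in% names(raw)) raw$count <- "1"
  pos_a <- suppressWarnings(as.integer(raw$pos_a))
  pos_b <- suppressWarnings(as.integer(raw$pos_b))
  cnt <- suppressWarnings(as.integer(raw$count))
  cnt[is.na(cnt)] <- 1L
  bad <- is.na(pos_a) | is.na(pos_b)
  if (any(bad)) {
    warn(sprintf("%d row(s) skipped: non-integer position", sum(bad)))
  }
  df <- tibble(protein_a = as.character(raw$protein_a), pos_a = pos_a,
               protein_b = as.character(raw$protein_b), pos_b = pos_b,
               linker = as.character(raw$linker), spectral_count = cnt)[!bad, ]
  normalize_links(df, sequences, source_row = which(!bad))
}

#' Write cross-links as a generic TSV
#'
#' Serializes a cross-link tibble back to the generic TSV format read by
#' [read_xlink_tsv()] (columns `protein_a`, `pos_a`, `protein_b`, `pos_b`,
#' `linker`, `count`). Parsing the written file again reproduces the
#' collection exactly.
#'
#' @param links Cross-link tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_xlink_tsv <- function(links, path) {
  df <- tibble(protein_a = links$protein_a, pos_a = links$pos_a,
               protein_b = links$protein_b, pos_b = links$pos_b,
               linker = links$linker, count = links$spectral_count)
  write_lines_atomic(df_to_tsv_lines(df), path)
}

#' Group cross-links into protein-protein interactions
#'
#' Partitions a cross-link tibble into PPIs, one per unordered protein pair.
#' Intra-protein links (both sites on the same protein) form single-protein
#' PPIs flagged `intra`.
#'
#' @param links Cross-link tibble from [read_plink2()] or [read_xlink_tsv()].
#' @return A tibble with one row per PPI: `protein_a`, `protein_b`, `intra`,
#'   `n_links`, `spectral_count`, and a `links` list-column of per-PPI
#'   cross-link tibbles.
#' @export
group_ppis <- function(links) {
  if (nrow(links) == 0) {
    return(tibble(protein_a = character(), protein_b = character(),
                  intra = logical(), n_links = integer(),
                  spectral_count = integer(), links = list()))
  }
  links |>
    nest(links = -c("protein_a", "protein_b", "intra")) |>
    mutate(n_links = map_int(.data$links, nrow),
           spectral_count = map_int(.data$links,
                                    ~ sum(.x$spectral_count))) |>
    select("protein_a", "protein_b", "intra", "n_links",
           "spectral_count", "links") |>
    arrange(.data$protein_a, .data$protein_b)
}
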