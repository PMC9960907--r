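#' Optimal local sequence alignment
#'
#' Smith-Waterman local alignment of a database protein sequence (query)
#' against a structure chain sequence (target), scored with BLOSUM62 and
#' affine gaps at the classic protein-BLAST defaults (gap existence 11,
#' extension 1, so a gap of length L costs 11 + L). The alignment is exact,
#' not heuristic, and deterministic. If no positive-scoring alignment exists
#' the result is the empty alignment with score 0.
#'
#' @param query,target Amino-acid strings (20 standard residues plus `X`).
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return A list of class `xlmap_alignment`: `score`, `identity` (fraction
#'   of identical residues over aligned columns), `query_span` and
#'   `target_span` (1-based inclusive `c(start, end)`), and `aligned_pairs`
#'   (tibble `query_pos`, `target_index` for match/mismatch columns, strictly
#'   increasing in both coordinates).
#' @examples
#' local_align("MKVLA", "AAAMKVLAAA")
#' @export
local_align <- function(query, target, gap_opening = 11, gap_extension = 1) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  pa <- Biostrings::pairwiseAlignment(
    query, target, type = "local",
    substitutionMatrix = blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(structure(list(
      score = 0, identity = 0,
      query_span = c(NA_integer_, NA_integer_),
      target_span = c(NA_integer_, NA_integer_),
      aligned_pairs = tibble(query_pos = integer(), target_index = integer())),
      class = "xlmap_alignment"))
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qi <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  ti <- Biostrings::start(Biostrings::subject(pa)) - 1L
  qpos <- integer(0); tpos <- integer(0); ident <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") qi <- qi + 1L
    if (s[k] != "-") ti <- ti + 1L
    if (p[k] != "-" && s[k] != "-") {
      qpos <- c(qpos, qi); tpos <- c(tpos, ti)
      if (p[k] == s[k]) ident <- ident + 1L
    }
  }
  structure(list(
    score = sc,
    identity = if (length(qpos)) ident / length(qpos) else 0,
    query_span = c(min(qpos), max(qpos)),
    target_span = c(min(tpos), max(tpos)),
    aligned_pairs = tibble(query_pos = qpos, target_index = tpos)),
    class = "xlmap_alignment")
}

# cache the substitution matrix; Biostrings ships it as a data object
blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

#' @export
print.xlmap_alignment <- function(x, ...) {
  cat(sprintf(
    "<xlmap_alignment score=%.0f identity=%.3f query %s-%s target %s-%s (%d columns)>\n",
    x$score, x$identity, x$query_span[1], x$query_span[2],
    x$target_span[1], x$target_span[2], nrow(x$aligned_pairs)))
  invisible(x)
}

#' Map a protein sequence onto structure chains
#'
#' Aligns one database protein against every chain of a structure and keeps
#' each chain whose local alignment reaches the identity and coverage
#' thresholds. All accepted chains are retained: in a homo-oligomer one
#' protein legitimately maps to several chain copies. The result is a
#' position-level map from database sequence coordinates to structure
#' residues (gap columns are unmapped).
#'
#' Identity is the fraction of identical residues over aligned columns;
#' coverage is the aligned query span length divided by the query length.
#' High identity guards against mapping paralogs; modest coverage tolerates
#' the partial constructs common in crystal structures.
#'
#' @param protein One-row tibble (or list) with `accession` and `sequence`.
#' @param structure An `xlmap_structure` from [read_mmcif()].
#' @param min_identity,min_coverage Acceptance thresholds in `[0, 1]`.
#' @return A tibble with one row per mapped database position per accepted
#'   chain: `accession`, `entry_id`, `chain_id`, `identity`, `coverage`,
#'   `align_score`, `db_pos`, `chain_pos`, `auth_seq_num`, `ins_code`, `aa`,
#'   `x`, `y`, `z`, `has_ca`. Zero rows if no chain is accepted.
#' @export
build_residue_map <- function(protein, structure,
                              min_identity = 0.9, min_coverage = 0.3) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1)
  qlen <- nchar(protein$sequence)
  maps <- list()
  for (i in seq_len(nrow(structure$chains))) {
    ch <- structure$chains[i, ]
    al <- local_align(protein$sequence, ch$sequence)
    if (nrow(al$aligned_pairs) == 0) next
    coverage <- (al$query_span[2] - al$query_span[1] + 1) / qlen
    if (al$identity < min_identity || coverage < min_coverage) next
    res <- filter(structure$residues, .data$chain_id == ch$chain_id)
    maps[[length(maps) + 1L]] <- al$aligned_pairs |>
      rename(db_pos = "query_pos", chain_pos = "target_index") |>
      left_join(res, by = "chain_pos") |>
      mutate(accession = protein$accession, entry_id = structure$entry_id,
             identity = al$identity, coverage = coverage,
             align_score = al$score) |>
      select("accession", "entry_id", "chain_id", "identity", "coverage",
             "align_score", "db_pos", "chain_pos", "auth_seq_num",
             "ins_code", "aa", "x", "y", "z", "has_ca")
  }
  if (length(maps) == 0) {
    return(tibble(accession = character(), entry_id = character(),
                  chain_id = character(), identity = numeric(),
                  coverage = numeric(), align_score = numeric(),
                  db_pos = integer(), chain_pos = integer(),
                  auth_seq_num = integer(), ins_code = character(),
                  aa = character(), x = numeric(), y = numeric(),
                  z = numeric(), has_ca = logical()))
  }
  bind_rows(maps)
}

#' Build residue maps for many proteins against many structures
#'
#' Convenience wrapper running [build_residue_map()] for every needed
#' (protein, structure) combination and row-binding the results.
#'
#' @param sequences Sequence tibble from [read_fasta()].
#' @param structures Structure list from [load_structure_set()].
#' @param needed Optional tibble of (`accession`, `entry_id`) combinations to
#'   restrict the work to (e.g. derived from [candidate_pairs()]).
#' @inheritParams build_residue_map
#' @return A single residue-map tibble (see [build_residue_map()]).
#' @export
build_residue_maps <- function(sequences, structures,
                               needed = NULL,
                               min_identity = 0.9, min_coverage = 0.3) {
  structures <- setNames(
    structures, vapply(structures, function(s) s$entry_id, character(1)))
  combos <- cross_join(
    tibble(accession = sequences$accession),
    tibble(entry_id = names(structures)))
  if (!is.null(needed)) {
    key <- paste(needed$accession, needed$entry_id, sep = "\r")
    combos <- combos[paste(combos$accession, combos$entry_id, sep = "\r")
                     %in% key, , drop = FALSE]
  }
  combos <- arrange(combos, .data$accession, .data$entry_id)
  res <- pmap(combos, function(accession, entry_id) {
    build_residue_map(
      sequences[sequences$accession == accession, ],
      structures[[entry_id]],
      min_identity = min_identity, min_coverage = min_coverage)
  })
  bind_rows(res)
}

#' Resolve a cross-link site to structure residues
#'
#' Returns every structure residue a database position maps to across the
#' accepted chains of the given residue maps. Positions falling in gap
#' columns, or mapping only to residues without a Ca atom, yield no hit.
#'
#' @param accession Protein accession.
#' @param pos 1-based database sequence position.
#' @param maps Residue-map tibble from [build_residue_map()] or
#'   [build_residue_maps()].
#' @param entry_id Optional entry filter.
#' @return Rows of `maps` (one per chain copy hit) with a present Ca.
#' @export
map_site <- function(accession, pos, maps, entry_id = NULL) {
  hits <- maps[maps$accession == accession & maps$db_pos == pos &
                 maps$has_ca, , drop = FALSE]
  if (!is.null(entry_id)) hits <- hits[hits$entry_id == entry_id, , drop = FALSE]
  arrange(hits, .data$entry_id, .data$chain_id)
}
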