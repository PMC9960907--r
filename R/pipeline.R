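#' Run the full cross-link-to-structure mapping pipeline
#'
#' Orchestrates parse -> map -> evaluate -> score -> export from a single
#' configuration: reads the cross-link table and FASTA, loads the mmCIF
#' structure set, aligns proteins to chains, measures every cross-link on
#' every candidate PPI-structure pair, scores the pairs, and writes the
#' three result files (plus optional PyMOL scripts), a rejection log and a
#' run manifest. Execution is single-process and deterministic: two runs on
#' identical inputs and configuration produce byte-identical outputs.
#'
#' @param config A named list, or the path to a YAML file, with fields:
#' \describe{
#'   \item{links}{Path to the cross-link table (required).}
#'   \item{links_format}{`"generic"` (default) or `"plink2"`.}
#'   \item{fasta}{Path to the FASTA database (required).}
#'   \item{structure_dir}{Directory of `.cif`/`.cif.gz` files (required).}
#'   \item{entries}{Optional character vector of entry ids to load.}
#'   \item{mapping}{Optional path to a TSV (`accession`, `entry_id`)
#'     restricting which structures each protein is evaluated on.}
#'   \item{linker_table}{Optional path to a linker TSV; default the packaged
#'     DSS/BS3/DSBU table.}
#'   \item{min_identity, min_coverage}{Alignment acceptance thresholds
#'     (defaults 0.9 and 0.3).}
#'   \item{score}{Optional list `w_s`, `w_c`, `w_v`, `k` (defaults 0.7,
#'     0.3, 0.2, 3).}
#'   \item{out_dir}{Output directory (required).}
#'   \item{pymol}{Write PyMOL scripts (default `TRUE`).}
#'   \item{satisfied_color, over_color}{PyMOL colors (defaults green/red).}
#'   \item{default_linker}{Linker name assumed for pLink2 files without a
#'     linker column (default `"DSS"`).}
#' }
#' @return Invisibly, a list: `reports` (the scored `xlmap_reports`
#'   tibble), `outputs` (paths), `manifest` (the run manifest list).
#' @export
xlmap_run <- function(config) {
  cfg <- read_run_config(config)

  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  linkers <- read_linker_table(cfg$linker_table)
  say("linker table: %s", paste(sprintf("%s<=%gA", linkers$name,
                                        linkers$max_ca_distance),
                                collapse = ", "))

  sequences <- read_fasta(cfg$fasta)
  say("sequences: %d protein(s) from %s", nrow(sequences), cfg$fasta)

  links <- switch(cfg$links_format,
    generic = read_xlink_tsv(cfg$links, sequences),
    plink2 = read_plink2(cfg$links, sequences, linker = cfg$default_linker),
    abort(paste0("unknown links_format: ", cfg$links_format)))
  rejections <- attr(links, "rejections")
  say("cross-links: %d unique link(s), %d spectral counts, %d rejected row(s)",
      nrow(links), sum(links$spectral_count), nrow(rejections))

  ppis <- group_ppis(links)
  say("PPIs: %d (%d intra-protein)", nrow(ppis), sum(ppis$intra))

  structures <- load_structure_set(cfg$structure_dir, cfg$entries)
  fails <- attr(structures, "failures")
  say("structures: %d loaded, %d failed", length(structures), nrow(fails))

  mapping <- NULL
  if (!is.null(cfg$mapping)) {
    mapping <- readr::read_tsv(cfg$mapping, show_col_types = FALSE,
                               progress = FALSE, comment = "#")
  }
  pairs <- candidate_pairs(ppis, structures, mapping)
  say("candidate PPI-structure pairs: %d", nrow(pairs))

  needed <- tibble(
    accession = c(pairs$protein_a, pairs$protein_b),
    entry_id = c(pairs$entry_id, pairs$entry_id)) |> distinct()
  maps <- build_residue_maps(sequences, structures, needed = needed,
                             min_identity = cfg$min_identity,
                             min_coverage = cfg$min_coverage)
  say("residue maps: %d accepted (protein, chain) pairing(s)",
      nrow(distinct(maps, .data$accession, .data$entry_id, .data$chain_id)))

  weights <- c(w_s = cfg$score$w_s, w_c = cfg$score$w_c, w_v = cfg$score$w_v)
  reports <- evaluate_pairs(ppis, pairs, maps, linkers,
                            k = cfg$score$k, weights = weights)
  say("scored pairs (>=1 mapped link): %d", nrow(reports))

  header_extra <- c(
    sprintf("# links=%s fasta=%s structure_dir=%s", cfg$links, cfg$fasta,
            cfg$structure_dir),
    sprintf("# min_identity=%g min_coverage=%g k=%g", cfg$min_identity,
            cfg$min_coverage, cfg$score$k))
  outputs <- write_outputs(reports, cfg$out_dir, pymol = cfg$pymol,
                           header_extra = header_extra,
                           satisfied_color = cfg$satisfied_color,
                           over_color = cfg$over_color,
                           structure_dir = cfg$structure_dir)

  rej_path <- file.path(cfg$out_dir, "rejections.tsv")
  write_lines_atomic(df_to_tsv_lines(rejections), rej_path)
  outputs$rejections <- rej_path

  manifest <- list(
    tool = "xlmapr", version = as.character(packageVersion("xlmapr")),
    config = cfg[setdiff(names(cfg), "entries")],
    counts = list(
      n_proteins = nrow(sequences),
      n_links = nrow(links),
      n_spectra = sum(links$spectral_count),
      n_rejected = nrow(rejections),
      n_ppis = nrow(ppis),
      n_structures = length(structures),
      n_structure_failures = nrow(fails),
      n_candidate_pairs = nrow(pairs),
      n_pairs_scored = nrow(reports),
      n_records_mapped = sum(reports$n_mapped),
      n_satisfied = sum(reports$n_satisfied),
      n_over = sum(reports$n_over)))
  man_path <- file.path(cfg$out_dir, "manifest.json")
  write_lines_atomic(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                     null = "null"),
    man_path)
  outputs$manifest <- man_path
  write_lines_atomic(log_lines, file.path(cfg$out_dir, "run.log"))

  invisible(list(reports = reports, outputs = outputs, manifest = manifest))
}

# Normalize and validate a run configuration (list or YAML path); every
# referenced path is checked before any computation starts.
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  defaults <- list(
    links_format = "generic",
    linker_table = system.file("extdata", "linkers.tsv", package = "xlmapr"),
    min_identity = 0.9, min_coverage = 0.3,
    score = list(), pymol = TRUE,
    satisfied_color = "green", over_color = "red",
    default_linker = "DSS", entries = NULL, mapping = NULL,
    allow_online_fetch = FALSE)
  cfg <- utils::modifyList(defaults, config)
  score_defaults <- list(w_s = 0.7, w_c = 0.3, w_v = 0.2, k = 3)
  cfg$score <- utils::modifyList(score_defaults, as.list(cfg$score))
  for (f in c("links", "fasta", "structure_dir", "out_dir")) {
    if (is.null(cfg[[f]])) abort(paste0("config field required: ", f))
  }
  if (isTRUE(cfg$allow_online_fetch)) {
    abort("online structure fetching is not implemented; pre-populate structure_dir")
  }
  for (f in c("links", "fasta", "linker_table")) {
    if (!file.exists(cfg[[f]])) {
      abort(paste0("config path does not exist: ", f, " = ", cfg[[f]]))
    }
  }
  if (!dir.exists(cfg$structure_dir)) {
    abort(paste0("config path does not exist: structure_dir = ",
                 cfg$structure_dir))
  }
  if (!is.null(cfg$mapping) && !file.exists(cfg$mapping)) {
    abort(paste0("config path does not exist: mapping = ", cfg$mapping))
  }
  cfg
}

#' Generate and analyze a demo scene
#'
#' Builds a synthetic three-chain scene with planted cross-links
#' (see [make_scene()]), writes a matching run configuration, and runs the
#' full pipeline on it. This is the offline stand-in for a worked
#' walkthrough on real data: a ready-made end-to-end example whose ground
#' truth is known.
#'
#' @param out_dir Directory for the scene and results.
#' @param seed Integer RNG seed for the scene.
#' @param n_chains,chain_len,n_links,frac_over Scene parameters, passed to
#'   [make_scene()]; defaults 3 chains of 40 residues, 12 links, 25%
#'   over-length.
#' @return Invisibly, a list: `scene`, plus the [xlmap_run()] result fields.
#' @export
xlmap_demo <- function(out_dir, seed = 1, n_chains = 3, chain_len = 40,
                       n_links = 12, frac_over = 0.25) {
  scene_dir <- file.path(out_dir, "scene")
  scene <- make_scene(n_chains = n_chains, chain_len = chain_len,
                      n_links = n_links, frac_over = frac_over,
                      seed = seed, dir = scene_dir)
  cfg <- list(links = scene$links_path, fasta = scene$fasta_path,
              structure_dir = scene$dir,
              out_dir = file.path(out_dir, "results"))
  cfg_path <- file.path(out_dir, "run.yaml")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, cfg_path)
  res <- xlmap_run(cfg_path)
  invisible(c(list(scene = scene, config_path = cfg_path), res))
}
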