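#' Cross-linker specification table
#'
#' A linker table maps each cross-linker name to the maximum Ca-Ca distance
#' (in Angstrom) a link bridged by that reagent may span on a structure.
#' Links measuring beyond the maximum are classified as over-length.
#'
#' The default table covers DSS, BS3 and DSBU at 30 Angstrom each: spacer-arm
#' length plus two lysine side chains and coordinate uncertainty, the common
#' convention for Ca-anchored cross-link validation. Thresholds are data, not
#' constants: override them with a TSV via [read_linker_table()].
#'
#' @return A tibble with columns `name` (character) and `max_ca_distance`
#'   (Angstrom, positive numeric).
#' @examples
#' default_linkers()
#' @export
default_linkers <- function() {
  read_linker_table(system.file("extdata", "linkers.tsv", package = "xlmapr"))
}

#' Read a linker table from TSV
#'
#' @param path TSV file with header columns `name` and `max_ca_distance`.
#' @return A tibble with columns `name`, `max_ca_distance`.
#' @export
read_linker_table <- function(path) {
  if (!file.exists(path)) abort(paste0("linker table not found: ", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("name", "max_ca_distance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("linker table missing column(s): ", paste(miss, collapse = ", ")))
  }
  df <- tibble(name = as.character(df$name),
               max_ca_distance = as.numeric(df$max_ca_distance))
  if (anyNA(df$max_ca_distance) || any(df$max_ca_distance <= 0)) {
    abort("linker max_ca_distance must be a positive number")
  }
  if (anyDuplicated(df$name)) abort("duplicate linker names in table")
  df
}

# Look up max distances for a vector of linker names; unknown names are fatal
# (forces explicit configuration rather than silently guessing a threshold).
linker_max <- function(linker, linkers) {
  idx <- match(linker, linkers$name)
  if (anyNA(idx)) {
    abort(paste0("linker(s) absent from linker table: ",
                 paste(unique(linker[is.na(idx)]), collapse = ", ")))
  }
  linkers$max_ca_distance[idx]
}
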