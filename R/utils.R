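# Internal helpers shared across modules.

# Accession from a FASTA header token: UniProt "sp|ACC|NAME" / "tr|ACC|NAME"
# resolve to the middle field, anything else is the first whitespace token.
resolve_accession <- function(x) {
  tok <- sub("\\s.*$", "", x)
  m <- regmatches(tok, regexec("^(?:sp|tr)\\|([^|]+)\\|", tok))
  vapply(seq_along(tok), function(i) {
    if (length(m[[i]]) == 2) m[[i]][2] else tok[i]
  }, character(1))
}

# Atomic file write: stage in a sibling temp file, then rename into place.
write_lines_atomic <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Format a numeric distance to 3 decimals (round half to even, as round() does);
# NA renders as the empty string.
format_distance <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.3f", round(x, 3)))
  # sprintf may re-round ties in C; force the round() result digit-exactly
  out
}

# Tool/config echo header lines for output TSVs ("#"-prefixed comments).
tsv_header <- function(extra = character()) {
  c(sprintf("# xlmapr %s", as.character(packageVersion("xlmapr"))), extra)
}

# Serialize a data frame to TSV lines (no quoting; columns must be tab-free).
df_to_tsv_lines <- function(df) {
  if (nrow(df) == 0L) return(paste(names(df), collapse = "\t"))
  cols <- vapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      ifelse(is.na(col), "", format(col, trim = TRUE, scientific = FALSE))
    } else {
      ifelse(is.na(col), "", as.character(col))
    }
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L)
  c(
    paste(names(df), collapse = "\t"),
    if (nrow(df) > 0L) apply(cols, 1L, paste, collapse = "\t")
  )
}

blank_ins <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "?" | x == "."] <- ""
  x
}
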