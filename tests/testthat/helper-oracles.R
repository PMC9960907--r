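# Independent oracles used to cross-check the package implementation.
# These deliberately share no code with the package.

# Brute-force Smith-Waterman with affine gaps: a gap of length L costs
# open + ext * L. Returns only the optimal local score.
sw_oracle <- function(q, t, mat, open = 11, ext = 1) {
  qq <- strsplit(q, "")[[1]]
  tt <- strsplit(t, "")[[1]]
  n <- length(qq); m <- length(tt)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qq[i - 1], tt[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

blosum62_oracle <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Exhaustive distance/classification oracle for a synthetic scene: for each
# planted link, enumerate all chain-copy combinations directly from the
# generator's coordinate table and classify against the linker maximum.
scene_oracle <- function(scene) {
  res <- scene$residues
  acc_chain <- stats::setNames(scene$chains$chain_id, scene$chains$accession)
  lmax <- scene$linker$max_ca_distance
  out <- scene$planned
  out$oracle_distance <- NA_real_
  for (i in seq_len(nrow(out))) {
    ra <- res[res$chain_id == acc_chain[out$protein_a[i]] &
                res$auth_seq_num == out$pos_a[i], ]
    rb <- res[res$chain_id == acc_chain[out$protein_b[i]] &
                res$auth_seq_num == out$pos_b[i], ]
    d <- Inf
    for (a in seq_len(nrow(ra))) for (b in seq_len(nrow(rb))) {
      d <- min(d, sqrt((ra$x[a] - rb$x[b])^2 + (ra$y[a] - rb$y[b])^2 +
                         (ra$z[a] - rb$z[b])^2))
    }
    out$oracle_distance[i] <- d
  }
  out$oracle_status <- ifelse(out$oracle_distance <= lmax,
                              "satisfied", "over_length")
  out
}

# A tiny hand-written mmCIF fixture: two chains, optional quirks.
fixture_cif_lines <- function(rows) {
  c("data_FIX", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    rows, "#")
}

cif_atom_row <- function(id, comp, chain, seq, x, y, z, ins = "?",
                         atom = "CA", elem = "C", occ = "1.00", alt = ".",
                         model = 1, group = "ATOM") {
  sprintf("%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %s 0.00 %d %s %s %s %d",
          group, id, elem, atom, alt, comp, chain, seq, ins, x, y, z, occ,
          seq, comp, chain, atom, model)
}

write_fixture_cif <- function(rows, path = tempfile(fileext = ".cif")) {
  writeLines(fixture_cif_lines(rows), path)
  path
}
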