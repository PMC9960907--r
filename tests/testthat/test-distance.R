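# Build a two-protein fixture with fully controlled CA coordinates: two
# chains of identical random sequences to their database proteins, so every
# position maps 1:1 and distances are known from construction.
two_chain_setup <- function(coords_a, coords_b, len = 12, seed = 3) {
  set.seed(seed)
  seq_a <- random_aa(len); seq_b <- random_aa(len)
  res <- tibble::tibble(
    chain_id = rep(c("A", "B"), each = len),
    auth_seq_num = rep(seq_len(len), 2),
    ins_code = "",
    aa = c(strsplit(seq_a, "")[[1]], strsplit(seq_b, "")[[1]]),
    x = c(coords_a[, 1], coords_b[, 1]),
    y = c(coords_a[, 2], coords_b[, 2]),
    z = c(coords_a[, 3], coords_b[, 3]))
  cif <- tempfile(fileext = ".cif")
  xlmapr:::write_mmcif_ca("test", res, cif)
  s <- read_mmcif(cif)
  seqs <- tibble::tibble(accession = c("PA", "PB"),
                         sequence = c(seq_a, seq_b),
                         length = c(len, len))
  maps <- build_residue_maps(seqs, list(test = s))
  list(structure = s, seqs = seqs, maps = maps)
}

line_coords <- function(len, origin = c(0, 0, 0), step = c(4, 0, 0)) {
  t(vapply(seq_len(len) - 1, function(i) origin + i * step, numeric(3)))
}

test_that("residue_distance is the Euclidean norm, symmetric, zero on self", {
  expect_equal(residue_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(residue_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(77)
  for (i in 1:20) {
    a <- rnorm(3, sd = 30); b <- rnorm(3, sd = 30)
    expect_equal(residue_distance(a, b), residue_distance(b, a))
  }
})

test_that("links are classified satisfied / over-length by constructed geometry", {
  # chain B is chain A translated by 8 A in y: site i-i distances are 8 A
  fix <- two_chain_setup(line_coords(12),
                         line_coords(12, origin = c(0, 8, 0)))
  links <- tibble::tibble(protein_a = "PA", pos_a = c(3L, 1L),
                          protein_b = "PB", pos_b = c(3L, 12L),
                          linker = "DSS", spectral_count = 1L)
  rep <- evaluate_pair(links, fix$structure, fix$maps)
  rec <- rep$records[[1]]
  near <- rec[rec$pos_a == 3, ]; far <- rec[rec$pos_a == 1, ]
  expect_equal(near$distance, 8)                  # same index: 8 A apart
  expect_equal(near$status, "satisfied")
  expect_equal(far$distance, sqrt(44^2 + 64))     # 1 -> 12: 44 A in x, 8 in y
  expect_equal(far$status, "over_length")
  expect_equal(rep$n_satisfied, 1L)
  expect_equal(rep$n_over, 1L)
})

test_that("a site that cannot be mapped yields an unmapped record", {
  fix <- two_chain_setup(line_coords(12), line_coords(12, origin = c(0, 8, 0)))
  maps <- fix$maps[fix$maps$accession != "PB", ] # drop all of PB
  links <- tibble::tibble(protein_a = "PA", pos_a = 3L,
                          protein_b = "PB", pos_b = 3L,
                          linker = "DSS", spectral_count = 1L)
  rep <- evaluate_pair(links, fix$structure, maps)
  rec <- rep$records[[1]]
  expect_equal(rec$status, "unmapped")
  expect_true(is.na(rec$distance))
  expect_equal(rep$n_mapped, 0L)
})

test_that("a linker missing from the table is fatal and named", {
  fix <- two_chain_setup(line_coords(12), line_coords(12, origin = c(0, 8, 0)))
  links <- tibble::tibble(protein_a = "PA", pos_a = 3L,
                          protein_b = "PB", pos_b = 3L,
                          linker = "EDC", spectral_count = 1L)
  expect_error(evaluate_pair(links, fix$structure, fix$maps), "EDC")
})

test_that("homodimer distances take the minimum over chain-copy combinations", {
  # two identical chains; protein HOMO maps to both; cross-link between two
  # HOMO sites enumerates the copy combinations
  len <- 12
  set.seed(8)
  seqh <- random_aa(len)
  coords_a <- line_coords(len)
  coords_b <- line_coords(len, origin = c(0, 40, 0))
  res <- tibble::tibble(
    chain_id = rep(c("A", "B"), each = len),
    auth_seq_num = rep(seq_len(len), 2), ins_code = "",
    aa = rep(strsplit(seqh, "")[[1]], 2),
    x = c(coords_a[, 1], coords_b[, 1]),
    y = c(coords_a[, 2], coords_b[, 2]),
    z = c(coords_a[, 3], coords_b[, 3]))
  cif <- tempfile(fileext = ".cif")
  xlmapr:::write_mmcif_ca("hdim", res, cif)
  s <- read_mmcif(cif)
  seqs <- tibble::tibble(accession = "HOMO", sequence = seqh, length = len)
  maps <- build_residue_maps(seqs, list(hdim = s))
  links <- tibble::tibble(protein_a = "HOMO", pos_a = 2L,
                          protein_b = "HOMO", pos_b = 5L,
                          linker = "DSS", spectral_count = 1L)
  rep <- evaluate_pair(links, s, maps)
  rec <- rep$records[[1]]
  # oracle: exhaustive enumeration over the 2x2 copy combinations, excluding
  # identical-residue self pairs
  combos <- expand.grid(ca = c("A", "B"), cb = c("A", "B"),
                        stringsAsFactors = FALSE)
  dists <- mapply(function(ca, cb) {
    a <- res[res$chain_id == ca & res$auth_seq_num == 2, ]
    b <- res[res$chain_id == cb & res$auth_seq_num == 5, ]
    sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  }, combos$ca, combos$cb)
  expect_equal(rec$distance, min(dists))
  expect_equal(rec$distance, 12)  # within one copy: 3 residues * 4 A
  expect_equal(rec$status, "satisfied")
})

test_that("intra-protein self-pairings on the same residue are excluded", {
  len <- 12
  set.seed(9)
  seqh <- random_aa(len)
  res <- tibble::tibble(
    chain_id = rep(c("A", "B"), each = len),
    auth_seq_num = rep(seq_len(len), 2), ins_code = "",
    aa = rep(strsplit(seqh, "")[[1]], 2),
    x = c(line_coords(len)[, 1], line_coords(len)[, 1]),
    y = c(rep(0, len), rep(10, len)),
    z = 0)
  cif <- tempfile(fileext = ".cif")
  xlmapr:::write_mmcif_ca("hdim", res, cif)
  s <- read_mmcif(cif)
  maps <- build_residue_maps(
    tibble::tibble(accession = "HOMO", sequence = seqh, length = len),
    list(hdim = s))
  # same database position on both ends: only the cross-copy pairing is legal
  links <- tibble::tibble(protein_a = "HOMO", pos_a = 4L,
                          protein_b = "HOMO", pos_b = 4L,
                          linker = "DSS", spectral_count = 1L)
  rec <- evaluate_pair(links, s, maps)$records[[1]]
  expect_equal(rec$distance, 10)  # A:4 to B:4, never A:4 to A:4 (0 A)
  expect_false(rec$chain_a == rec$chain_b &&
                 rec$auth_res_a == rec$auth_res_b)
})

test_that("distances are invariant under rigid motions of the structure", {
  set.seed(19)
  for (trial in 1:5) {
    scene <- make_scene(n_chains = 2, chain_len = 25, n_links = 6,
                        frac_over = 0.5, seed = 100 + trial)
    s <- read_mmcif(scene$structure_path)
    seqs <- read_fasta(scene$fasta_path)
    links <- read_xlink_tsv(scene$links_path, seqs)
    maps <- build_residue_maps(seqs, stats::setNames(list(s), scene$entry_id))
    ppis <- group_ppis(links)
    pairs <- candidate_pairs(ppis, stats::setNames(list(s), scene$entry_id))
    base <- evaluate_pairs(ppis, pairs, maps)
    d0 <- tidy(base)$distance

    # random rotation (QR of a Gaussian matrix) + translation
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_); if (det(R) < 0) R[, 1] <- -R[, 1]
    tvec <- rnorm(3, sd = 50)
    xyz <- as.matrix(scene$residues[, c("x", "y", "z")]) %*% t(R)
    res2 <- scene$residues
    res2$x <- xyz[, 1] + tvec[1]
    res2$y <- xyz[, 2] + tvec[2]
    res2$z <- xyz[, 3] + tvec[3]
    maps2 <- maps
    key <- paste(maps$chain_id, maps$auth_seq_num)
    rkey <- paste(res2$chain_id, res2$auth_seq_num)
    idx <- match(key, rkey)
    maps2$x <- res2$x[idx]; maps2$y <- res2$y[idx]; maps2$z <- res2$z[idx]
    moved <- evaluate_pairs(ppis, pairs, maps2)
    d1 <- tidy(moved)$distance
    expect_lt(max(abs(d1 - d0)), 1e-6)
  }
})

test_that("raising the linker maximum never demotes satisfied links", {
  scene <- make_scene(n_chains = 2, chain_len = 30, n_links = 8,
                      frac_over = 0.5, seed = 33)
  s <- read_mmcif(scene$structure_path)
  seqs <- read_fasta(scene$fasta_path)
  links <- read_xlink_tsv(scene$links_path, seqs)
  ppis <- group_ppis(links)
  structures <- stats::setNames(list(s), scene$entry_id)
  maps <- build_residue_maps(seqs, structures)
  pairs <- candidate_pairs(ppis, structures)
  n_sat <- vapply(c(5, 15, 30, 45, 100), function(mx) {
    linkers <- tibble::tibble(name = "DSS", max_ca_distance = mx)
    sum(evaluate_pairs(ppis, pairs, maps, linkers)$n_satisfied)
  }, integer(1))
  expect_true(all(diff(n_sat) >= 0))
})

test_that("counts are conserved: n_total = unmapped + satisfied + over_length", {
  scene <- make_scene(n_chains = 3, chain_len = 30, n_links = 10,
                      frac_over = 0.3, seed = 44)
  s <- read_mmcif(scene$structure_path)
  seqs <- read_fasta(scene$fasta_path)
  links <- read_xlink_tsv(scene$links_path, seqs)
  ppis <- group_ppis(links)
  structures <- stats::setNames(list(s), scene$entry_id)
  maps <- build_residue_maps(seqs, structures)
  reports <- evaluate_pairs(ppis, candidate_pairs(ppis, structures), maps)
  expect_equal(reports$n_total,
               reports$n_unmapped + reports$n_satisfied + reports$n_over)
  expect_equal(reports$n_mapped, reports$n_satisfied + reports$n_over)
  expect_equal(sum(reports$n_total), nrow(links))
})
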