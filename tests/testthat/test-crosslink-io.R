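seqs3 <- function() {
  tibble::tibble(accession = c("P1", "P2", "P3"),
                 sequence = c(strrep("K", 50), strrep("A", 50), strrep("S", 20)),
                 length = c(50L, 50L, 20L))
}

test_that("FASTA parsing handles plain and UniProt headers, cleanup rules", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "mkv-",
               ">sp|P02769|ALBU_BOVIN", "MKWVTF*",
               ">tr|Q99999|SOMETHING", "ACDB"), fa)
  out <- read_fasta(fa)
  expect_equal(out$accession, c("P1", "P02769", "Q99999"))
  expect_equal(out$sequence, c("MKV", "MKWVTF", "ACDX")) # upper, strip, X
  expect_equal(out$length, c(3L, 6L, 4L))
})

test_that("duplicate accessions keep the first record with a warning", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKV", ">P1", "AAAA"), fa)
  expect_warning(out <- read_fasta(fa), "duplicate")
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, "MKV")
})

test_that("empty FASTA is an error", {
  fa <- tempfile(fileext = ".fasta")
  file.create(fa)
  expect_error(read_fasta(fa), "empty|read")
})

test_that("pLink2 rows collapse over the canonical dedup key", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("Proteins",
               "P1(5)-P2(9)", "P1(5)-P2(9)", "P2(9)-P1(5)"), csv)
  out <- read_plink2(csv, seqs3())
  expect_equal(nrow(out), 1L)
  expect_equal(out$spectral_count, 3L)
  expect_equal(out$protein_a, "P1")
  expect_equal(out$pos_a, 5L)
})

test_that("out-of-bounds and unknown-accession links are rejected and logged", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("Proteins", "P1(99)-P2(3)", "P9(1)-P1(2)", "P1(4)-P2(6)"), csv)
  out <- read_plink2(csv, seqs3())
  expect_equal(nrow(out), 1L)
  rej <- attr(out, "rejections")
  expect_equal(nrow(rej), 2L)
  expect_setequal(rej$reason,
                  c("position beyond sequence length", "accession not in FASTA"))
})

test_that("pLink2 spectral counts aggregate per distinct site pair", {
  # 10 PSM rows over 4 distinct site pairs; expected grouping computed
  # independently with table() over the raw site strings
  rows <- c("P1(5)-P2(9)", "P1(5)-P2(9)", "P1(5)-P2(9)", "P2(2)-P1(7)",
            "P1(7)-P2(2)", "P3(4)-P1(1)", "P3(4)-P1(1)", "P3(4)-P1(1)",
            "P3(4)-P1(1)", "P1(10)-P1(30)")
  canon <- vapply(rows, function(r) {
    g <- regmatches(r, regexec("(\\w+)\\((\\d+)\\)-(\\w+)\\((\\d+)\\)", r))[[1]]
    ep <- list(c(g[2], g[3]), c(g[4], g[5]))
    o <- order(vapply(ep, function(e) sprintf("%s\r%09d", e[1],
                                              as.integer(e[2])), ""))
    paste(unlist(ep[o]), collapse = "|")
  }, character(1))
  expected <- table(canon)
  csv <- tempfile(fileext = ".csv")
  writeLines(c("Proteins", rows), csv)
  out <- read_plink2(csv, seqs3())
  expect_equal(nrow(out), length(expected))
  expect_equal(sum(out$spectral_count), 10L)
  got <- stats::setNames(
    out$spectral_count,
    paste(out$protein_a, out$pos_a, out$protein_b, out$pos_b, sep = "|"))
  expect_equal(sort(as.integer(got)), sort(as.integer(expected)))
})

test_that("ambiguous or malformed pLink2 site strings are skipped with warning", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("Proteins", "P1(5)-P2(9)/P3(4)-P2(9)", "garbage",
               "P1(5)-P2(9)"), csv)
  expect_warning(out <- read_plink2(csv, seqs3()), "skipped")
  expect_equal(nrow(out), 1L)
})

test_that("generic TSV parsing: defaults, type errors, linker in dedup key", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tpos_a\tprotein_b\tpos_b\tlinker",
               "P1\t5\tP2\t9\tDSS",
               "P1\tabc\tP2\t9\tDSS",
               "P1\t5\tP2\t9\tDSBU"), tsv)
  expect_warning(out <- read_xlink_tsv(tsv, seqs3()), "non-integer")
  expect_equal(nrow(out), 2L) # same sites, two linkers -> two links
  expect_true(all(out$spectral_count == 1L))
})

test_that("missing mandatory column in generic TSV is fatal and named", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tpos_a\tprotein_b\tlinker", "P1\t5\tP2\tDSS"), tsv)
  expect_error(read_xlink_tsv(tsv, seqs3()), "pos_b")
})

test_that("spectral counts are conserved through parsing (generic counts)", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tpos_a\tprotein_b\tpos_b\tlinker\tcount",
               "P1\t5\tP2\t9\tDSS\t4",
               "P2\t9\tP1\t5\tDSS\t2",
               "P1\t1\tP3\t3\tDSS\t5"), tsv)
  out <- read_xlink_tsv(tsv, seqs3())
  expect_equal(sum(out$spectral_count), 11L)
  expect_equal(out$spectral_count[out$pos_a == 5], 6L)
})

test_that("generic TSV round-trips: write then re-parse is identical", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tpos_a\tprotein_b\tpos_b\tlinker\tcount",
               "P2\t9\tP1\t5\tDSS\t2",
               "P1\t5\tP2\t9\tBS3\t1",
               "P1\t10\tP1\t2\tDSS\t3"), tsv)
  out1 <- read_xlink_tsv(tsv, seqs3())
  back <- tempfile(fileext = ".tsv")
  write_xlink_tsv(out1, back)
  out2 <- read_xlink_tsv(back, seqs3())
  expect_equal(as.data.frame(out1), as.data.frame(out2))
})

test_that("dedup key is exactly (protein_a,pos_a,protein_b,pos_b,linker)", {
  set.seed(11)
  base <- expand.grid(pa = c("P1", "P2"), sa = c(3L, 7L),
                      pb = "P3", sb = c(2L, 9L),
                      lk = c("DSS", "BS3"), stringsAsFactors = FALSE)
  for (rep in 1:5) {
    idx <- sample(nrow(base), 30, replace = TRUE)
    rows <- base[idx, ]
    # randomly flip endpoint order
    flip <- sample(c(TRUE, FALSE), nrow(rows), replace = TRUE)
    df <- data.frame(
      protein_a = ifelse(flip, rows$pb, rows$pa),
      pos_a = ifelse(flip, rows$sb, rows$sa),
      protein_b = ifelse(flip, rows$pa, rows$pb),
      pos_b = ifelse(flip, rows$sa, rows$sb),
      linker = rows$lk, count = 1L)
    tsv <- tempfile(fileext = ".tsv")
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- read_xlink_tsv(tsv, seqs3())
    expect_equal(nrow(out), length(unique(idx)))
    expect_equal(sum(out$spectral_count), 30L)
    key <- paste(out$protein_a, out$pos_a, out$protein_b, out$pos_b, out$linker)
    expect_false(any(duplicated(key)))
    # canonical endpoint ordering
    expect_true(all(out$protein_a < out$protein_b |
                      (out$protein_a == out$protein_b &
                         out$pos_a <= out$pos_b)))
  }
})

test_that("group_ppis partitions links and conserves counts", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tpos_a\tprotein_b\tpos_b\tlinker\tcount",
               "P1\t5\tP2\t9\tDSS\t1",
               "P1\t7\tP2\t2\tDSS\t2",
               "P1\t1\tP3\t3\tDSS\t1"), tsv)
  links <- read_xlink_tsv(tsv, seqs3())
  ppis <- group_ppis(links)
  expect_equal(nrow(ppis), 2L)
  expect_equal(ppis$n_links, c(2L, 1L))
  expect_equal(sum(ppis$spectral_count), sum(links$spectral_count))
  expect_false(any(ppis$intra))
})

test_that("intra-protein links form a flagged single-protein PPI", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tpos_a\tprotein_b\tpos_b\tlinker",
               "P1\t30\tP1\t10\tDSS"), tsv)
  links <- read_xlink_tsv(tsv, seqs3())
  ppis <- group_ppis(links)
  expect_equal(nrow(ppis), 1L)
  expect_true(ppis$intra)
  expect_equal(ppis$protein_a, ppis$protein_b)
  # canonical ordering puts the smaller position first
  expect_equal(ppis$links[[1]]$pos_a, 10L)
})

test_that("zero links yield zero PPIs", {
  empty <- tibble::tibble(
    protein_a = character(), pos_a = integer(), protein_b = character(),
    pos_b = integer(), linker = character(), spectral_count = integer(),
    intra = logical())
  expect_equal(nrow(group_ppis(empty)), 0L)
})
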