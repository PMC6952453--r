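test_that("tryptic cleavage follows the K/R rule with proline suppression", {
  d <- digest("AAAKGGGRCCC", "Trypsin/P", 0L)
  expect_equal(d$sequence, c("AAAK", "GGGR", "CCC"))
  expect_equal(d$missed_cleavages, c(0L, 0L, 0L))

  # Trypsin does not cut K|P; Trypsin/P does
  expect_equal(digest("AAAKPGGG", "Trypsin", 0L)$sequence, "AAAKPGGG")
  expect_equal(digest("AAAKPGGG", "Trypsin/P", 0L)$sequence, c("AAAK", "PGGG"))
  expect_error(digest("AAAK", "Chymotrypsin", 0L), "unknown enzyme")
})

test_that("digest records protein flanks and positions", {
  seq <- "MASKLLRAVILGPPGSGKGTVCQRI"
  d <- digest(seq, "Trypsin/P", 1L)  # LLR|AVILGPPGSGK spans one missed site
  i <- which(d$sequence == "LLRAVILGPPGSGK")
  expect_equal(d$n_flank[i], "MASK")
  expect_equal(d$c_flank[i], "GTVCQRI")
  first <- which(d$start == 1L)
  expect_true(all(d$n_flank[first] == ""))
  expect_equal(substr(seq, d$start[i], d$end[i]), d$sequence[i])
})

test_that("digests equal the brute-force window enumeration", {
  prots <- generate_random_proteome(10, c(200L, 400L), seed = 31)
  for (i in seq_len(nrow(prots))) {
    s <- prots$sequence[i]
    for (enzyme in c("Trypsin", "Trypsin/P")) {
      for (mm in 0:2) {
        d <- digest(s, enzyme, mm)
        got <- sort(paste0(d$sequence, "@", d$start))
        expect_identical(got, oracle_digest(s, enzyme, mm))
      }
    }
  }
})

test_that("zero-missed Trypsin/P peptides concatenate to the protein", {
  prots <- generate_random_proteome(5, seed = 33)
  for (s in prots$sequence) {
    d <- digest(s, "Trypsin/P", 0L)
    expect_identical(paste(d$sequence, collapse = ""), s)
  }
})

test_that("missed-cleavage counts equal the internal-site count", {
  prots <- generate_random_proteome(5, seed = 35)
  for (s in prots$sequence) {
    d <- digest(s, "Trypsin/P", 2L)
    sites <- dialib:::.cleavage_sites(s, "Trypsin/P")
    internal <- vapply(seq_len(nrow(d)), function(i)
      sum(sites >= d$start[i] & sites < d$end[i]), integer(1))
    expect_equal(d$missed_cleavages, internal)
  }
})

test_that("the no-missed union combines Trypsin and Trypsin/P digests", {
  # no K-P/R-P motif: union equals either digest
  s <- "AAAKGGGRCCCDDDK"
  u <- combine_no_missed_union(s)
  expect_setequal(u$sequence, digest(s, "Trypsin", 0L)$sequence)
  # a K-P site makes the union strictly larger than plain trypsin
  s2 <- "AAAKPGGGRCCC"
  u2 <- combine_no_missed_union(s2)
  expect_gt(nrow(u2), nrow(digest(s2, "Trypsin", 0L)))
  expect_setequal(u2$sequence, c("AAAKPGGGR", "AAAK", "PGGGR", "CCC"))
  expect_false(any(duplicated(paste(u2$sequence, u2$start))))
})

test_that("length and mass filters keep 7-50 aa peptides at <= 6000 Da", {
  d <- data.frame(sequence = c("SHORT", "PEPTIDEK", strrep("W", 45),
                               strrep("A", 51)),
                  stringsAsFactors = FALSE)
  f <- filter_peptides(d)
  expect_true("PEPTIDEK" %in% f$sequence)
  expect_false("SHORT" %in% f$sequence)           # length 5 < 7
  expect_false(strrep("A", 51) %in% f$sequence)   # length > 50
  expect_false(strrep("W", 45) %in% f$sequence)   # 45 x 186 Da > 6000
  expect_true(all(nchar(f$sequence) >= 7))
  expect_true(all(peptide_mass(f$sequence) <= 6000))
})

test_that("FASTA round-trip preserves entries and parses UniProt accessions", {
  prots <- generate_random_proteome(3, seed = 41)
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P01234|NAME_HUMAN Some protein", prots$sequence[1],
               ">tr|Q99999|OTHER_MOUSE", prots$sequence[2],
               ">PLAIN0001 plain header", prots$sequence[3]), path)
  fa <- read_fasta(path)
  expect_equal(fa$accession, c("P01234", "Q99999", "PLAIN0001"))
  expect_equal(fa$sequence, prots$sequence)

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fa, out)
  back <- read_fasta(out)
  expect_equal(back$accession, fa$accession)
  expect_equal(back$sequence, fa$sequence)

  # lowercase input is normalized to uppercase on read
  lcpath <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", tolower(prots$sequence[1])), lcpath)
  lc <- read_fasta(lcpath)
  expect_equal(lc$sequence, prots$sequence[1])

  duppath <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "AAAK", ">p1", "CCCK"), duppath)
  expect_warning(dup <- read_fasta(duppath), "duplicate")
  expect_equal(dup$sequence, "AAAK")
})

test_that("entrapment sets are seeded, flagged and size-matched", {
  target <- generate_random_proteome(20, seed = 51, prefix = "TGT")
  pool <- generate_random_proteome(100, seed = 52, prefix = "TRAP")
  merged <- build_entrapment_set(target, pool, seed = 9)
  expect_equal(nrow(merged), 40L)
  expect_equal(sum(merged$entrapment), 20L)
  merged2 <- build_entrapment_set(target, pool, seed = 9)
  expect_identical(merged, merged2)
  merged3 <- build_entrapment_set(target, pool, seed = 10)
  expect_false(identical(merged$accession, merged3$accession))
  expect_warning(all_pool <- build_entrapment_set(target, pool[1:5, ], seed = 1),
                 "smaller")
  expect_equal(sum(all_pool$entrapment), 5L)
})

test_that("dedupe_peptides merges parent accessions and entrapment flags", {
  d <- data.frame(
    sequence = c("PEPTIDEK", "PEPTIDEK", "OTHERK"),
    n_flank = c("AAAA", "CCCC", "GGGG"), c_flank = c("R", "K", "R"),
    missed_cleavages = 0L, start = 1L, end = 8L,
    accession = c("P1", "P2", "P3"),
    entrapment = c(FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  u <- dedupe_peptides(d)
  expect_equal(nrow(u), 2L)
  expect_equal(u$accession[u$sequence == "PEPTIDEK"], "P1;P2")
  # shared target/entrapment peptide counts as target
  expect_false(u$entrapment[u$sequence == "PEPTIDEK"])
  expect_true(u$entrapment[u$sequence == "OTHERK"])
})
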