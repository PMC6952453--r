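# Library assembly and CSV round-trip, using tiny trained models so the
# whole flow runs in seconds.

tiny_models <- local({
  models <- NULL
  function() {
    if (!is.null(models)) return(models)
    rule <- fragmentation_rule(seed = 81)
    rt_rule <- retention_rule(noise_sigma = 0, seed = 81)
    peps <- simulate_peptides(60, seed = 81)
    train <- data.frame(sequence = peps$sequence, charge = 2L,
                        stringsAsFactors = FALSE)
    train$target <- lapply(train$sequence,
                           function(s) simulate_fragmentation(s, rule)$matrix)
    m2 <- train_msms(build_msms_model(2L, seed = 81), train, epochs = 3,
                     batch_size = 32, seed = 81, patience = 100)
    train3 <- transform(train, charge = 3L)
    train3$target <- train$target
    m3 <- train_msms(build_msms_model(3L, seed = 82), train3, epochs = 3,
                     batch_size = 32, seed = 82, patience = 100)
    rt_train <- data.frame(sequence = train$sequence,
                           irt = simulate_rt(train$sequence, rt_rule))
    mrt <- train_rt(build_rt_model(seed = 83), rt_train, epochs = 3,
                    batch_size = 32, seed = 83, patience = 100)
    models <<- list(msms = list("2" = m2, "3" = m3), rt = mrt)
    models
  }
})

test_that("assembled libraries have one entry per precursor and consistent m/z", {
  mods <- tiny_models()
  peps <- simulate_peptides(10, seed = 85)
  lib <- assemble_library(peps, mods$msms, mods$rt, min_fragments = 1L)
  key <- unique(lib[, c("StrippedPeptide", "PrecursorCharge")])
  expect_equal(nrow(key), 20L)  # 10 peptides x 2 charges

  # every fragment m/z re-derivable from the sequence
  for (i in seq_len(nrow(lib))) {
    expect_equal(lib$FragmentMz[i],
                 oracle_fragment_mz(lib$StrippedPeptide[i],
                                    lib$FragmentType[i],
                                    lib$FragmentNumber[i],
                                    lib$FragmentCharge[i],
                                    lib$FragmentLossType[i]),
                 tolerance = 1e-4)
  }
  # precursor m/z consistent with peptide mass
  expect_equal(lib$PrecursorMz,
               precursor_mz(lib$StrippedPeptide, lib$PrecursorCharge),
               tolerance = 1e-9)
  expect_true(all(lib$RelativeIntensity > 0 & lib$RelativeIntensity <= 1))
  # fragment export rule: at most 20 fragments per precursor
  counts <- table(paste(lib$StrippedPeptide, lib$PrecursorCharge))
  expect_true(all(counts <= 20))
})

test_that("entry counts match a brute-force enumeration of surviving peptides", {
  mods <- tiny_models()
  prot <- generate_random_proteome(3, seed = 86)
  dig <- dedupe_peptides(filter_peptides(digest_proteins(prot, "Trypsin/P", 0L)))
  lib <- assemble_library(dig, mods$msms, mods$rt, min_fragments = 1L,
                          min_intensity = 0)
  expect_equal(length(unique(paste(lib$StrippedPeptide, lib$PrecursorCharge))),
               2L * nrow(dig))
})

test_that("library CSV round-trips and renders the modification dialect", {
  mods <- tiny_models()
  peps <- simulate_peptides(5, seed = 87)
  lib <- assemble_library(peps, mods$msms, mods$rt, min_fragments = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_library_csv(lib, path)
  back <- read_library_csv(path)
  expect_equal(back, lib, tolerance = 1e-9)
  expect_equal(nrow(back), nrow(lib))  # one row per fragment

  expect_equal(modified_peptide_string("VCK"), "_VC[Carbamidomethyl (C)]K_")
  cpep <- lib$ModifiedPeptide[grepl("C", lib$StrippedPeptide)]
  if (length(cpep))
    expect_true(all(grepl("C[Carbamidomethyl (C)]", cpep, fixed = TRUE)))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_library_csv(bad), "missing column")
})

test_that("filtering before or after assembly yields the same library", {
  mods <- tiny_models()
  peps <- simulate_peptides(20, seed = 88)
  scores <- seq(0, 1, length.out = 20)
  pre <- assemble_library(filter_by_detectability(peps, scores, 0.5),
                          mods$msms, mods$rt, min_fragments = 1L)
  full <- assemble_library(peps, mods$msms, mods$rt, min_fragments = 1L)
  post <- full[full$StrippedPeptide %in% peps$sequence[scores >= 0.5], ,
               drop = FALSE]
  rownames(post) <- NULL
  expect_equal(pre, post, tolerance = 1e-12)
})

test_that("detectability filtering is inclusive and monotone", {
  peps <- data.frame(sequence = sprintf("PEP%02dK", 1:3))
  scores <- c(0.4, 0.5, 0.6)
  expect_equal(nrow(filter_by_detectability(peps, scores, 0.5)), 2L)
  expect_equal(nrow(filter_by_detectability(peps, scores, 0)), 3L)
  expect_equal(nrow(filter_by_detectability(peps, scores, 1.5)), 0L)

  set.seed(89)
  sc <- runif(50)
  pep50 <- data.frame(sequence = sprintf("P%02dK", 1:50))
  prev <- pep50
  for (th in seq(0, 1, by = 0.1)) {
    cur <- filter_by_detectability(pep50, sc, th)
    expect_true(all(cur$sequence %in% prev$sequence))
    prev <- cur
  }
})

test_that("protein grouping merges identical retained peptide sets", {
  peptides <- data.frame(
    sequence = c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"),
    accession = c("P1;P2", "P1;P2", "P3"), stringsAsFactors = FALSE)
  g <- group_proteins(peptides)
  expect_equal(g$group_id[g$accession == "P1"], "P1;P2")
  expect_equal(g$group_id[g$accession == "P2"], "P1;P2")
  expect_equal(g$group_id[g$accession == "P3"], "P3")
})

test_that("second-pass libraries restrict to first-pass proteins", {
  mods <- tiny_models()
  prot <- generate_random_proteome(6, seed = 90)
  dig <- dedupe_peptides(filter_peptides(digest_proteins(prot, "Trypsin/P", 2L)))
  # detectability stand-in: deterministic scores via a seeded untrained model
  dmodel <- build_detectability_model(seed = 90)
  first_pass <- prot$accession[1:3]
  expect_warning(
    res <- build_second_pass_library(c(first_pass, "GHOST1"), prot, dmodel,
                                     mods$msms, mods$rt, threshold = 0,
                                     min_fragments = 1L),
    "GHOST1")
  expect_true(all(res$peptides$accession %in%
                    dig$accession[grepl(paste(first_pass, collapse = "|"),
                                        dig$accession)] |
                    res$peptides$accession %in% first_pass |
                    grepl(";", res$peptides$accession)))
  # restriction property: second-pass peptides are a subset of the full digest
  expect_true(all(res$peptides$sequence %in% dig$sequence))
  expect_true(all(res$groups$accession %in% first_pass))
})
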