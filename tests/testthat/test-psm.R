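make_psm_file <- function(rows, path, sep = "\t") {
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

test_that("PSM reports are read through a declarative column map", {
  rows <- data.frame(
    PEP.Sequence = c("PEPTIDEK", "AVLGTSNFK", "SAMPLERK"),
    PP.Charge = c(2, 2, 3), PSM.Qvalue = c(0.001, 0.01, 0.002),
    PP.RT = c(10.5, 44.2, 80.1), Spec.Ref = c("s1", "s2", "s3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  make_psm_file(rows, path)
  psms <- read_psm_report(path, c(sequence = "PEP.Sequence",
                                  charge = "PP.Charge",
                                  q_value = "PSM.Qvalue", rt = "PP.RT",
                                  spectrum_ref = "Spec.Ref"))
  expect_equal(nrow(psms), 3L)
  expect_equal(psms$sequence[2], "AVLGTSNFK")
  expect_error(read_psm_report(path, c(sequence = "NoSuchColumn",
                                       charge = "PP.Charge",
                                       q_value = "PSM.Qvalue", rt = "PP.RT",
                                       spectrum_ref = "Spec.Ref")),
               "NoSuchColumn")
  expect_error(read_psm_report(path, c(sequence = "PEP.Sequence",
                                       charge = "PP.Charge",
                                       q_value = "PSM.Qvalue",
                                       spectrum_ref = "Spec.Ref")),
               "rt")
})

test_that("duplicate precursors survive reading and are resolved by selection", {
  rows <- data.frame(
    sequence = c("PEPTIDEK", "PEPTIDEK", "PEPTIDEK", "PEPTIDEK", "OTHERPEPK"),
    charge = c(2, 2, 1, 4, 2),
    q_value = c(0.003, 0.001, 0.0005, 0.0005, 0.02),
    rt = c(10, 10.1, 10.2, 10.2, 50),
    spectrum_ref = c("s1", "s2", "s3", "s4", "s5"))
  path <- withr::local_tempfile(fileext = ".csv")
  make_psm_file(rows, path, sep = ",")
  psms <- read_psm_report(path)
  expect_equal(nrow(psms), 5L)  # duplicates preserved at this stage

  best <- select_best_psms(psms)
  # charges 1 and 4 dropped for MS/MS training
  expect_true(all(best$charge %in% c(2, 3)))
  # minimum q-value wins
  expect_equal(best$spectrum_ref[best$sequence == "PEPTIDEK"], "s2")
  expect_equal(nrow(best), 2L)
})

test_that("q-value ties break deterministically", {
  psms <- data.frame(
    sequence = "PEPTIDEK", charge = 2,
    q_value = c(0.001, 0.001, 0.001),
    rt = c(1, 2, 3),
    matched_intensity = c(5, 9, 9),
    spectrum_ref = c("specA", "specC", "specB"))
  b1 <- select_best_psms(psms)
  # highest matched intensity, then lexicographic spectrum_ref
  expect_equal(b1$spectrum_ref, "specB")
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    expect_equal(select_best_psms(psms[perm, ])$spectrum_ref, "specB")
  }
})

test_that("annotate_spectrum recovers a constructed spectrum exactly", {
  p <- "AVLGTSNFK"
  sim <- simulate_fragmentation(p, fragmentation_rule(seed = 5,
                                                      noise_peak_rate = 0))
  mat <- annotate_spectrum(sim$peaks, p, tolerance = 20)
  # exact up to theoretical m/z collisions (e.g. b4 2+ vs b2 1+ sharing one
  # m/z), which the most-intense-peak assignment cannot distinguish
  expect_gte(dot_product(mat, sim$matrix), 0.98)
  expect_gte(mean(abs(mat - sim$matrix) < 1e-9), 0.98)
  # re-annotating a spectrum synthesized from the annotated matrix is exact
  mat2 <- annotate_spectrum(synthesize_peaks(p, mat), p, tolerance = 20)
  expect_equal(as.numeric(mat2), as.numeric(mat), tolerance = 1e-12)
  expect_false(attr(mat, "empty"))

  # scale invariance
  scaled <- sim$peaks
  scaled$intensity <- scaled$intensity * 1234
  mat2 <- annotate_spectrum(scaled, p)
  expect_equal(as.numeric(mat2), as.numeric(mat), tolerance = 1e-12)
})

test_that("annotation flags empty matches and picks the strongest in-window peak", {
  p <- "PEPTIDEK"
  far <- data.frame(mz = c(10.0, 20.0), intensity = c(1, 1))
  expect_true(attr(annotate_spectrum(far, p), "empty"))
  expect_true(all(annotate_spectrum(far, p) == 0))

  # two peaks inside one window: more intense assigned
  fr <- enumerate_fragments(p)
  target <- fr[fr$series == "y" & fr$index == 4 & fr$charge == 1 &
                 fr$loss == "noloss", ]
  peaks <- data.frame(mz = c(target$mz - target$mz * 5e-6,
                             target$mz + target$mz * 5e-6),
                      intensity = c(30, 80))
  mat <- annotate_spectrum(peaks, p, tolerance = 20)
  expect_equal(unname(mat[target$row, target$site]), 1)  # 80 max-normalized
})

test_that("MGF files round-trip spectra and titles", {
  spectra <- list(
    "run1.001" = data.frame(mz = c(100.1, 200.223456, 300.5),
                            intensity = c(10, 50, 5)),
    "run1.002" = data.frame(mz = numeric(), intensity = numeric()))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(spectra, path,
            precursors = data.frame(pepmass = c(450.1, 500.2), charge = c(2, 3)))
  back <- read_mgf(path)
  expect_equal(names(back), names(spectra))
  expect_equal(back[[1]]$mz, spectra[[1]]$mz, tolerance = 1e-6)
  expect_equal(back[[1]]$intensity, spectra[[1]]$intensity, tolerance = 1e-6)
  expect_equal(nrow(back[[2]]), 0L)
})

test_that("iRT calibration recovers a linear RT map per run", {
  ref <- data.frame(sequence = paste0("REFPEP", 1:5, "K"),
                    irt = c(0, 25, 50, 75, 100))
  # two-point exact case
  psms <- data.frame(sequence = c(ref$sequence[1], ref$sequence[5], "NEWPEPK"),
                     charge = 2, q_value = 0.001,
                     rt = c(10, 110, 60), spectrum_ref = "s", run_id = "r1")
  cal <- calibrate_irt(psms, ref[c(1, 5), ])
  expect_equal(cal$calibration$slope, 1, tolerance = 1e-9)
  expect_equal(cal$calibration$intercept, -10, tolerance = 1e-9)
  expect_equal(cal$psms$irt[3], 50, tolerance = 1e-9)

  # noiseless synthetic run with a known line: exact recovery
  set.seed(71)
  rts <- runif(5, 5, 115)
  psms2 <- data.frame(sequence = ref$sequence, charge = 2, q_value = 0.001,
                      rt = rts, spectrum_ref = "s", run_id = "r1")
  truth <- list(slope = 0.9, intercept = -12)
  ref2 <- data.frame(sequence = ref$sequence,
                     irt = truth$intercept + truth$slope * rts)
  cal2 <- calibrate_irt(psms2, ref2)
  expect_equal(cal2$calibration$slope, truth$slope, tolerance = 1e-9)
  expect_equal(cal2$calibration$intercept, truth$intercept, tolerance = 1e-9)

  expect_error(calibrate_irt(psms2[1, ], ref2), ">= 2 reference")
})

test_that("noisy iRT calibration recovers the line within 1%", {
  set.seed(72)
  n <- 40
  rts <- runif(n, 5, 115)
  ref <- data.frame(sequence = sprintf("REF%02dK", 1:n),
                    irt = -12 + 0.9 * rts)
  psms <- data.frame(sequence = ref$sequence, charge = 2, q_value = 0.001,
                     rt = rts + rnorm(n, 0, 0.1), spectrum_ref = "s",
                     run_id = "r1")
  cal <- calibrate_irt(psms, ref)
  expect_equal(cal$calibration$slope, 0.9, tolerance = 0.01)
  expect_equal(cal$calibration$intercept, -12, tolerance = 0.1)
})

test_that("training-set split is a disjoint, seed-reproducible 2/3-1/3 partition", {
  ds <- data.frame(sequence = sprintf("PEP%03dK", 1:300), charge = 2,
                   stringsAsFactors = FALSE)
  sp <- build_training_set(ds, charge = 2, split_seed = 5)
  expect_equal(nrow(sp$train), 200L)
  expect_equal(nrow(sp$test), 100L)
  expect_length(intersect(sp$train$sequence, sp$test$sequence), 0L)

  sp2 <- build_training_set(ds, charge = 2, split_seed = 5)
  expect_identical(sp$train$sequence, sp2$train$sequence)
  sp3 <- build_training_set(ds, charge = 2, split_seed = 6)
  expect_false(identical(sp$train$sequence, sp3$train$sequence))
  expect_error(build_training_set(ds[1:5, ], charge = 2), "too few")

  # duplicated sequences (e.g. 2+ and 3+ precursors) never straddle the split
  ds2 <- rbind(ds, transform(ds[1:50, ], charge = 3))
  sp4 <- build_training_set(ds2, charge = NULL, split_seed = 7)
  expect_length(intersect(sp4$train$sequence, sp4$test$sequence), 0L)
})
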