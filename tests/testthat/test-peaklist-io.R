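test_that("canonical TSV peak lists parse, honor the NA sentinel, and round-trip", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("resnum\trestype\tH_ppm\tN_ppm",
               "170\tG\t8.21\t109.85",
               "172\tV\t7.95\t121.3",
               "173\tE\tNA\tNA"), tf)
  pl <- readPeakList(tf)
  expect_equal(nrow(pl), 3L)
  expect_equal(pl$residue, c(170L, 172L, 173L))
  expect_equal(pl$type, c("G", "V", "E"))
  expect_equal(pl$dH, c(8.21, 7.95, NA))
  expect_equal(pl$dN, c(109.85, 121.3, NA))
  expect_equal(pl$present, c(TRUE, TRUE, FALSE))

  # round trip is value-exact
  out <- withr::local_tempfile(fileext = ".tsv")
  writePeakList(pl, out)
  expect_identical(readPeakList(out), pl)
})

test_that("peak-list parsing is order-independent and rejects bad input by name", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("172 V 7.95 121.3", "170 G 8.21 109.85"), tf)
  pl <- readPeakList(tf)
  expect_equal(pl$residue, c(172L, 170L))  # input order preserved

  dup <- withr::local_tempfile()
  writeLines(c("172 V 7.95 121.3", "172 V 7.95 121.3"), dup)
  expect_error(readPeakList(dup), "duplicate residue number 172")

  bad <- withr::local_tempfile()
  writeLines(c("170 G 8.21 109.85", "172 V seven 121.3"), bad)
  expect_error(readPeakList(bad), "line 2")

  hdr <- withr::local_tempfile()
  writeLines(c("resnum\trestype\tH_ppm", "170\tG\t8.2"), hdr)
  expect_error(readPeakList(hdr), "N_ppm")
})

test_that("sparky dialect parses assignment labels with w1 = 15N, w2 = 1H", {
  tf <- withr::local_tempfile()
  writeLines(c("Assignment  w1      w2",
               "G172N-H     109.85  8.21",
               "V173N-H     121.30  7.95"), tf)
  pl <- readPeakList(tf, dialect = "sparky")
  expect_equal(pl$residue, c(172L, 173L))
  expect_equal(pl$type, c("G", "V"))
  expect_equal(pl$dH, c(8.21, 7.95))
  expect_equal(pl$dN, c(109.85, 121.30))
  bad <- withr::local_tempfile()
  writeLines("G172HA-HB 4.1 3.2", bad)
  expect_error(readPeakList(bad, dialect = "sparky"), "label")
})

test_that("shifts outside the amide windows warn but still parse", {
  tf <- withr::local_tempfile()
  writeLines("170 G 3.50 109.85", tf)
  expect_warning(pl <- readPeakList(tf), "1H")
  expect_equal(pl$dH, 3.5)
})

test_that("titration configs build a validated series with derived quantities", {
  dir <- withr::local_tempdir()
  pl <- csptitr:::.newPeakList(c(170L, 172L, 175L), c("G", "V", "A"),
                               c(8.2, 7.9, 8.5), c(110, 121, 118))
  for (i in 0:3) writePeakList(pl, file.path(dir, sprintf("p%d.tsv", i)))
  cfg <- file.path(dir, "design.yaml")
  writeLines(c("protein_name: demo", "ligand_name: pep",
               "protein_conc: 0.1", "points:",
               "  - {peaklist: p0.tsv, molar_ratio: 0}",
               "  - {peaklist: p1.tsv, molar_ratio: 1}",
               "  - {peaklist: p2.tsv, molar_ratio: 4}",
               "  - {peaklist: p3.tsv, molar_ratio: 16}"), cfg)
  ser <- readTitration(cfg)
  expect_s4_class(ser, "TitrationSeries")
  expect_equal(nPoints(ser), 4L)
  expect_equal(ligandConc(ser), c(0, 0.1, 0.4, 1.6))   # ratio x [P]
  expect_equal(molarRatio(ser), c(0, 1, 4, 16))
  expect_true(validObject(ser))

  # series/design round trip through writeTitration
  dir2 <- withr::local_tempdir()
  writeTitration(ser, dir2)
  ser2 <- readTitration(file.path(dir2, "design.yaml"))
  expect_equal(ligandConc(ser2), ligandConc(ser))
  expect_identical(peakLists(ser2), peakLists(ser))
})

test_that("titration design invariants are enforced", {
  dir <- withr::local_tempdir()
  pl <- csptitr:::.newPeakList(170L, "G", 8.2, 110)
  for (i in 0:2) writePeakList(pl, file.path(dir, sprintf("p%d.tsv", i)))
  mk <- function(ratios) {
    cfg <- file.path(dir, "cfg.yaml")
    writeLines(c("protein_conc: 0.1", "points:",
                 sprintf("  - {peaklist: p%d.tsv, molar_ratio: %g}",
                         seq_along(ratios) - 1L, ratios)), cfg)
    cfg
  }
  expect_error(readTitration(mk(c(0, 1))), "at least 3 points")
  expect_error(readTitration(mk(c(0, 4, 1))), "strictly increasing")
  expect_error(readTitration(mk(c(1, 2, 4))), "apo")
})

test_that("per-point protein concentration overrides are honored verbatim", {
  dir <- withr::local_tempdir()
  pl <- csptitr:::.newPeakList(170L, "G", 8.2, 110)
  for (i in 0:2) writePeakList(pl, file.path(dir, sprintf("p%d.tsv", i)))
  cfg <- file.path(dir, "cfg.yaml")
  writeLines(c("protein_conc: 0.1", "points:",
               "  - {peaklist: p0.tsv, ligand_conc: 0}",
               "  - {peaklist: p1.tsv, ligand_conc: 0.1}",
               "  - {peaklist: p2.tsv, ligand_conc: 0.4, protein_conc: 0.08}"),
             cfg)
  ser <- readTitration(cfg)
  expect_equal(proteinConc(ser), c(0.1, 0.1, 0.08))
  expect_equal(molarRatio(ser)[3], 0.4 / 0.08)
})
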