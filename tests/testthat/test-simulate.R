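test_that("noiseless binder endpoints equal the forward isotherm exactly", {
  sim <- simulateTitration(trueKd = 0.3, proteinConc = 0.1, noiseSd = 0,
                           seed = 4)
  x <- computeCSPs(sim$series)
  L <- ligandConc(sim$series)
  ep <- endpointCSP(x)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    want <- if (tr$binder)
      isotherm(L[length(L)], 0.1, tr$kd, tr$ddmax) else 0
    expect_equal(unname(ep[as.character(tr$residue)]), want,
                 tolerance = 1e-12)
  }
})

test_that("identical seeds give bit-identical series; different noise seeds differ", {
  s1 <- simulateTitration(seed = 11)
  s2 <- simulateTitration(seed = 11)
  expect_identical(s1$series@peakLists, s2$series@peakLists)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateTitration(seed = 11, noiseSeed = 99L)
  expect_identical(s1$truth, s3$truth)          # same geometry
  expect_false(identical(s1$series@peakLists, s3$series@peakLists))
})

test_that("a binder-free simulation moves residues only by noise", {
  sim <- simulateTitration(binderFraction = 0, noiseSd = 0.005, seed = 8)
  x <- computeCSPs(sim$series)
  ep <- unname(endpointCSP(x))
  # every endpoint CSP within ~4 sd of the noise-difference scale
  expect_true(all(ep < 4 * sqrt(2) * 0.005 * sqrt(1 + 0.2^2)))
  expect_true(all(!sim$truth$binder))
})

test_that("broadening removes binder peaks inside the fraction-bound window", {
  sim <- simulateTitration(trueKd = 0.3, noiseSd = 0,
                           broadening = c(0.3, 0.7), seed = 5)
  fb <- isotherm(ligandConc(sim$series), 0.1, 0.3, 1)
  inWin <- which(fb >= 0.3 & fb <= 0.7)
  expect_gt(length(inWin), 0)
  binders <- sim$truth$residue[sim$truth$binder]
  pl <- peakLists(sim$series)[[inWin[1]]]
  expect_true(all(!pl$present[pl$residue %in% binders]))
  expect_true(all(pl$present[!pl$residue %in% binders]))
  x <- computeCSPs(sim$series)
  st <- residueStatus(x)
  expect_true(all(st[as.character(binders)] == "broadened"))
})

test_that("simulated titrations validate and invalid configs are rejected", {
  sim <- simulateTitration(seed = 2)
  expect_true(validObject(sim$series))
  expect_error(simulateTitration(molarRatios = c(1, 2, 4)), "start at 0")
  expect_error(simulateTitration(noiseSd = -1), "noiseSd")
  expect_error(simulateTitration(binderFraction = 2), "binderFraction")
  expect_error(simulateTitration(ddmaxRange = c(-0.1, 0.2)), "ddmaxRange")
})

test_that("planted peak pairs qualify by construction under the gap rule", {
  ps <- simulatePeakSets(nA = 50, nB = 50, sharedFraction = 1,
                         jitterBp = 0, seed = 6)
  s <- overlapPeaks(ps$a, ps$b, maxGap = 150)
  expect_equal(s@aWithB, 50L)                    # every A touched
  ps2 <- simulatePeakSets(nA = 40, nB = 60, sharedFraction = 0.5,
                          jitterBp = 150, seed = 7)
  planted <- which(ps2$truth$planted)
  p <- overlapPairs(ps2$a, ps2$b, maxGap = 150)
  # every planted (anchor, b) pair appears among the qualifying pairs
  for (i in planted) {
    anchor <- ps2$truth$anchor[i]
    hit <- p$start_a == GenomicRanges::start(ps2$a)[anchor] - 1L &
      p$start_b == GenomicRanges::start(ps2$b)[i] - 1L
    expect_true(any(hit))
  }
  # and the planted gap is realized exactly
  expect_true(all(ps2$truth$gap[planted] <= 150))
})

test_that("unshared peaks on a sparse genome do not overlap", {
  ps <- simulatePeakSets(nA = 20, nB = 20, genomeSize = 5e8,
                         sharedFraction = 0, jitterBp = 0, seed = 9)
  expect_equal(overlapPeaks(ps$a, ps$b)@pairs, 0L)
})

test_that("seeded peak-set simulation is deterministic", {
  p1 <- simulatePeakSets(seed = 123)
  p2 <- simulatePeakSets(seed = 123)
  expect_identical(p1$truth, p2$truth)
  expect_true(identical(GenomicRanges::start(p1$a),
                        GenomicRanges::start(p2$a)))
})
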