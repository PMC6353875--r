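# Build a CSPExperiment whose endpoint CSPs are exactly `values`.
cspFromValues <- function(values, residues = seq_along(values) + 100L,
                          status = NULL) {
  n <- length(values)
  if (is.null(status)) status <- rep("assigned", n)
  csp <- cbind(0, values)
  csp[status != "assigned", ] <- NA
  ep <- ifelse(status == "assigned", values, NA_real_)
  new("CSPExperiment", residue = as.integer(residues),
      type = rep("A", n), status = status,
      dH = csp, dN = csp * 0, csp = csp, endpointCSP = ep,
      firstAbsent = ifelse(status == "broadened", 2L, NA_integer_),
      design = S4Vectors::DataFrame(ligandConc = c(0, 1),
                                    proteinConc = c(0.1, 0.1),
                                    molarRatio = c(0, 10)),
      nitrogenWeight = 0.2)
}

test_that("the trimmed threshold reproduces the hand-computed 10-residue case", {
  vals <- c(rep(0.01, 8), 0.05, 0.50)
  x <- cspFromValues(vals)
  r <- classifySignificance(x)
  expect_equal(sum(r@trimmed), 1L)                 # ceil(0.1 * 10)
  expect_equal(r@residue[r@trimmed], 110L)         # the 0.50
  expect_equal(r@populationMean, 0.0144444, tolerance = 1e-5)
  expect_equal(r@populationSD, 0.0133333, tolerance = 1e-5)
  expect_equal(r@threshold1sd, 0.0277778, tolerance = 1e-5)
  expect_equal(sort(significantResidues(r, "ge_1sd")), c(109L, 110L))
})

test_that("degenerate populations classify nothing under strict comparison", {
  r <- classifySignificance(cspFromValues(rep(0.02, 10)))
  expect_equal(r@populationSD, 0)
  expect_equal(r@threshold1sd, 0.02)
  expect_length(significantResidues(r), 0)         # strict ">"
  r0 <- classifySignificance(cspFromValues(rep(0, 10)))
  expect_length(significantResidues(r0), 0)
  expect_error(classifySignificance(cspFromValues(rep(0.1, 4))),
               "at least 5")
})

test_that("classification matches a brute-force oracle on 1000 random populations", {
  set.seed(20260923)
  maxDiff <- 0
  setsAgree <- TRUE
  for (i in 1:1000) {
    n <- sample(5:200, 1)
    vals <- abs(rnorm(n, 0.02, 0.03))
    res <- sample(1000L, n)
    r <- classifySignificance(cspFromValues(vals, residues = res))
    o <- bruteSignificance(vals, residues = res)
    maxDiff <- max(maxDiff,
                   abs(r@populationMean - o$mean), abs(r@populationSD - o$sd),
                   abs(r@threshold1sd - o$t1), abs(r@threshold1p5sd - o$t15))
    setsAgree <- setsAgree &&
      identical(sort(r@residue[r@trimmed]), o$trimmed) &&
      identical(sort(significantResidues(r, "ge_1sd")), o$sig1) &&
      identical(sort(significantResidues(r, "ge_1p5sd")), o$sig15)
  }
  expect_lt(maxDiff, 1e-12)
  expect_true(setsAgree)
})

test_that("unassigned and broadened residues never move the thresholds", {
  vals <- c(0.01, 0.012, 0.009, 0.05, 0.2, 0.011, 0.013, 0.008, 0.01, 0.3)
  base <- classifySignificance(cspFromValues(vals))
  withExtra <- classifySignificance(
    cspFromValues(c(vals, 5, 10),
                  residues = c(seq_along(vals) + 100L, 300L, 301L),
                  status = c(rep("assigned", 10), "broadened", "proline")))
  expect_equal(withExtra@threshold1sd, base@threshold1sd)
  expect_equal(withExtra@threshold1p5sd, base@threshold1p5sd)
  expect_equal(length(withExtra@residue), length(base@residue))
})

test_that("thresholds and tiers are scale-equivariant", {
  set.seed(5)
  vals <- abs(rnorm(40, 0.02, 0.02))
  r1 <- classifySignificance(cspFromValues(vals))
  for (cc in c(0.1, 3, 100)) {
    r2 <- classifySignificance(cspFromValues(vals * cc))
    expect_equal(r2@threshold1sd, r1@threshold1sd * cc)
    expect_equal(r2@threshold1p5sd, r1@threshold1p5sd * cc)
    expect_equal(r2@tier, r1@tier)
  }
})

test_that("trimmed residues are still classified against the thresholds", {
  vals <- c(rep(0.01, 8), 0.05, 0.50)
  r <- classifySignificance(cspFromValues(vals))
  expect_equal(unname(tiers(r)["110"]), "ge_1p5sd")  # trimmed but labeled
  expect_true(r@trimmed[r@residue == 110L])
})

test_that("significance tables round-trip the tier assignments", {
  vals <- c(rep(0.01, 8), 0.05, 0.50)
  r <- classifySignificance(cspFromValues(vals))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeSignificanceTable(r, tf)
  tab <- read.delim(tf, comment.char = "#")
  expect_equal(nrow(tab), 10L)
  # 0.05 exceeds mean + 1.5 SD (0.0344) as well
  expect_equal(tab$tier[tab$residue == 109], "ge_1p5sd")
  expect_equal(tab$tier[tab$residue == 101], "not_significant")
})
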