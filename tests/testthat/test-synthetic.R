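test_that("every generator is a pure function of spec and seed", {
  arms <- syntheticArmModel()
  expect_identical(genCatalog(200, arms, terminalBiasBeta = 2, seed = 9),
                   genCatalog(200, arms, terminalBiasBeta = 2, seed = 9))
  a1 <- genArray(studyMotifs()[["CEB1"]], 5, pointMutationRate = 0.02,
                 seed = 4)
  a2 <- genArray(studyMotifs()[["CEB1"]], 5, pointMutationRate = 0.02,
                 seed = 4)
  expect_identical(as.character(arraySeq(a1)), as.character(arraySeq(a2)))
  expect_identical(attr(a1, "mutatedPositions"),
                   attr(a2, "mutatedPositions"))
  ta <- TandemArray(studyMotifs()[["CEB25"]], 10, motifName = "CEB25")
  expect_identical(genJunctionReads(ta, 20, seed = 5),
                   genJunctionReads(ta, 20, seed = 5))
  expect_identical(simulateLD(1e-8, 1e8, 30, seed = 6)@r,
                   genFluctuation(1e-8, 1e8, 30, seed = 6)@r)
  ## different seeds decorrelate
  expect_false(identical(genCatalog(200, arms, seed = 9),
                         genCatalog(200, arms, seed = 10)))
})

test_that("unmutated generated arrays carry the expected G4 structure", {
  m <- studyMotifs()
  for (k in c(2, 5, 8)) {
    ceb1 <- genArray(m[["CEB1"]], k, pointMutationRate = 0, seed = 1)
    expect_equal(countG4(ceb1), k - 1L)
    ceb25 <- genArray(m[["CEB25"]], k, pointMutationRate = 0, seed = 1)
    expect_equal(countG4(ceb25), k)
  }
  expect_error(genArray(m[["CEB1"]], 3, pointMutationRate = 1),
               "pointMutationRate")
})

test_that("point mutations land where the truth record says", {
  m <- studyMotifs()
  ta <- genArray(m[["CEB1"]], 20, pointMutationRate = 0.05, seed = 12)
  mut <- attr(ta, "mutatedPositions")
  expect_gt(length(mut), 0)
  ref <- strrep(as.character(m[["CEB1"]]), 20)
  got <- as.character(arraySeq(ta))
  diffs <- which(strsplit(ref, "")[[1]] != strsplit(got, "")[[1]])
  expect_identical(diffs, mut)
})

test_that("catalog terminal mass follows the analytic density integral", {
  arms <- syntheticArmModel()
  for (beta in c(0, 4, 12)) {
    cat0 <- genCatalog(4000, arms, terminalBiasBeta = beta, seed = 21)
    p <- mean(cat0$true_norm_pos > 0.9)
    expected <- terminalMassBeta(beta, 0.10)
    expect_lt(abs(p - expected), 3 * sqrt(expected * (1 - expected) / 4000))
  }
})

test_that("telomeric tracts obey the grammar at any length", {
  expect_equal(genTelomereTract(0), "")
  for (len in c(1, 2, 17, 120)) {
    t <- genTelomereTract(len, seed = len)
    expect_equal(nchar(t), len)
    expect_true(isTelomericSeq(t, partial = TRUE))
  }
  ## strict acceptance when the truncation preserves whole repeats
  t <- genTelomereTract(300, seed = 2)
  expect_true(isTelomericSeq(sub("T[G]{0,3}$", "", t), partial = TRUE))
})

test_that("junction reads embed their declared breakpoints and truth", {
  ta <- TandemArray(studyMotifs()[["CEB1"]], 10, motifName = "CEB1")
  arr <- as.character(arraySeq(ta))
  reads <- genJunctionReads(ta, 50, seed = 8)
  expect_equal(nrow(reads), 50L)
  for (i in seq_len(10)) {
    r <- reads$read[i]
    bp <- reads$breakpoint[i]
    expect_identical(substr(r, 1, bp), substr(arr, 1, bp))
    expect_true(reads$true_junction[i] >= bp)
    if (!is.na(reads$true_shared_start[i]))
      expect_lte(reads$true_shared_start[i], reads$true_junction[i])
  }
  ## telomere length 0 ends the read at the breakpoint
  r0 <- genJunctionReads(ta, 3, breakpoint = 39L,
                         telomereLengthMean = 0, telomereLengthSD = 0,
                         seed = 2)
  expect_equal(nchar(r0$read), rep(39L, 3))
  ## n = 0 gives an empty set
  expect_equal(nrow(genJunctionReads(ta, 0, seed = 1)), 0L)
})

test_that("junction annotation recovers generated truth almost surely", {
  ta <- TandemArray(studyMotifs()[["CEB1"]], 15, motifName = "CEB1")
  reads <- genJunctionReads(ta, 1000, seed = 33)
  ok <- 0L
  for (i in seq_len(nrow(reads))) {
    ann <- annotateJunction(reads$read[i], studyMotifs()[["CEB1"]])
    hit <- ann$junctionIndex == reads$true_junction[i] &&
      identical(ann$sharedSpan,
                if (is.na(reads$true_shared_start[i])) NULL else
                  c(reads$true_shared_start[i], reads$true_shared_end[i]))
    ok <- ok + hit
  }
  expect_gte(ok / nrow(reads), 0.99)
})
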