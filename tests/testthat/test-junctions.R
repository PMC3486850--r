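ceb1 <- as.character(studyMotifs()[["CEB1"]])
ceb25 <- as.character(studyMotifs()[["CEB25"]])

test_that("the seed map reproduces the G4-region overlap statistic", {
  sm <- seedMap(ceb1, g4Region = c(1, 17))
  expect_equal(sm$count, 20L)
  expect_equal(sm$overlapCount, 12L)
  expect_equal(sm$overlapFraction, 0.6)
  ## overlapping seeds are allowed
  expect_equal(seedMap("TGTG")$positions, c(1L, 2L, 3L))
  expect_equal(seedMap("AAAA")$count, 0L)
})

test_that("seed count agrees with the forward dinucleotide count", {
  set.seed(707)
  for (i in 1:50) {
    s <- randomSeq(sample(10:100, 1), gProb = .4)
    expect_equal(seedMap(s)$count, dinucBias(s)$forward)
  }
})

test_that("longest motif-telomere homology is GGGTGG and matches the oracle", {
  telo <- genTelomereTract(60, seed = 3)
  hom <- longestTelomereHomology(ceb1, paste0("TG", "TGG", "TGGG",
                                              "TGG", "TGGG", "TG"))
  expect_equal(hom$substring, "GGGTGG")
  expect_equal(hom$length, 6L)
  ## identical inputs give the whole string; disjoint alphabets nothing
  expect_equal(longestTelomereHomology("ACGT", "ACGT")$substring, "ACGT")
  expect_equal(longestTelomereHomology("AAAA", "GGGG")$length, 0L)
  ## brute-force all-substrings oracle on random pairs
  set.seed(808)
  for (i in 1:30) {
    a <- randomSeq(sample(5:60, 1)); b <- randomSeq(sample(5:60, 1))
    expect_equal(nchar(longestTelomereHomology(a, b)$substring),
                 nchar(bruteForceLCS(a, b)))
  }
  ## in real telomeric tracts too
  hom2 <- longestTelomereHomology(ceb1, telo)
  expect_equal(nchar(hom2$substring), nchar(bruteForceLCS(ceb1, telo)))
})

test_that("the TG1-3 grammar separates strict and partial acceptance", {
  expect_true(isTelomericSeq("TGTGGTGGG"))
  expect_true(isTelomericSeq("TG"))
  expect_false(isTelomericSeq("GGGTGG"))       # partial leading repeat
  expect_true(isTelomericSeq("GGGTGG", partial = TRUE))
  expect_false(isTelomericSeq("TGGGG"))        # 4 G exceeds the repeat
  expect_false(isTelomericSeq(""))
  expect_false(isTelomericSeq("TGATG"))
  expect_true(isTelomericSeq("T", partial = TRUE))
})

test_that("junction annotation recovers constructed junctions", {
  ## CEB1 cut after nt 17 (...GGGTGG), telomere continues with TGG:
  ## the shared span is the 6-nt GGGTGG homology block
  read <- paste0(substr(ceb1, 1, 17), "TGGTGGGTGTGGGTG")
  ann <- annotateJunction(read, ceb1)
  expect_equal(ann$junctionIndex, 17L)
  expect_equal(ann$sharedSpan, c(12L, 17L))
  expect_equal(ann$sharedLength, 6L)
  ## junction with no shared nucleotide: cut after a C (which cannot be
  ## telomeric), telomere resuming mid-repeat with G while the motif
  ## continues with T, so neither side extends into the other
  idxC <- 19L
  read0 <- paste0(substr(ceb1, 1, idxC), "GGTGTGGTGGG")
  ann0 <- annotateJunction(read0, ceb1)
  expect_equal(ann0$junctionIndex, idxC)
  expect_null(ann0$sharedSpan)
  expect_equal(ann0$sharedLength, 0L)
  ## an entirely telomeric read has junction index 0
  annT <- annotateJunction("TGGTGGGTGTGG", ceb1)
  expect_equal(annT$junctionIndex, 0L)
  ## a read with no telomeric suffix errors
  expect_error(annotateJunction(paste0(substr(ceb1, 1, 20), "CCCCAACC"),
                                ceb1),
               "no telomeric suffix")
})

test_that("junction SNVs are reported and filtered by read support", {
  ## introduce a mismatch 5 nt before the junction
  pre <- substr(ceb1, 1, 17)
  substr(pre, 13, 13) <- "A"   # reference has G at 13
  read <- paste0(pre, "TGTGGTGGG")
  ann <- annotateJunction(read, ceb1, maxMismatches = 1)
  expect_equal(ann$junctionIndex, 17L)
  expect_equal(ann$snvs, 13L)
  expect_equal(supportedSNVs(list(13L, 13L, 13L, 2L), minReads = 3), 13L)
  expect_equal(length(supportedSNVs(list(13L, 13L), minReads = 3)), 0L)
})

test_that("remaining-motif estimation inverts the fragment-size model", {
  expect_equal(remainingMotifsFromFragment(1375, 50, 350, 39), 25L)
  expect_equal(remainingMotifsFromFragment(2200, 1800, 300, 52), 2L)
  expect_equal(remainingMotifsFromFragment(2100, 1800, 300, 52), 0L)
  expect_warning(r <- remainingMotifsFromFragment(100, 50, 300, 39),
                 "reporting 0")
  expect_equal(r, 0L)
  ## exact inverse of the forward fragment-size construction
  tm <- telomereModel()
  for (k in c(0, 5, 25, 43)) {
    frag <- tm$flankBp + tm$meanLengthWT + k * 39
    expect_equal(remainingMotifsFromFragment(frag, tm$flankBp,
                                             tm$meanLengthWT, 39), k)
  }
})

test_that("Cdc13 site search finds the consensus and near-consensus sites", {
  expect_equal(findCdc13Sites(ceb25), 31L)
  expect_identical(substr(ceb25, 31, 41), cdc13Consensus())
  expect_equal(length(findCdc13Sites(strrep("A", 60))), 0L)
  ## overlapping exact sites are all reported
  expect_gte(length(findCdc13Sites(strrep(cdc13Consensus(), 2))), 2L)
  ## critical-prefix mode admits TG-rich near-consensus windows
  relaxed <- findCdc13Sites(ceb25, mode = "critical_prefix")
  expect_true(31L %in% relaxed)
  expect_gte(length(relaxed), length(findCdc13Sites(ceb25)))
  ## a GTGT prefix in an AT-rich window does not qualify
  expect_equal(length(findCdc13Sites("GTGTAAAAAAA", "critical_prefix")), 0L)
})
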