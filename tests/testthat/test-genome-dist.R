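arms <- syntheticArmModel(nChrom = 3)

test_that("normalised arm positions anchor centromere at 0, telomere at 1", {
  cat0 <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chrX"),
    start = c(5e6, 1, 3.75e6, 6e6 + 1, 100),
    end   = c(5e6, 1, 3.75e6, 6e6 + 1, 200))
  expect_warning(pos <- normalizedArmPosition(cat0, arms), "outside")
  expect_equal(pos[1], 0)            # p-arm centromeric end
  expect_equal(pos[2], 1, tolerance = 1e-6)  # p-arm telomeric end
  expect_equal(pos[3], 0.25, tolerance = 1e-6)
  expect_equal(pos[4], 0)            # q-arm centromeric end
  expect_true(is.na(pos[5]))         # unknown chromosome excluded
  ## a midpoint inside the centromere gap is flagged
  gapRec <- data.frame(chrom = "chr1", start = 5.5e6, end = 5.5e6)
  expect_warning(expect_true(is.na(normalizedArmPosition(gapRec, arms))))
})

test_that("uniform catalogs give uniform normalised positions", {
  cat0 <- genCatalog(3000, arms, terminalBiasBeta = 0, seed = 17)
  pos <- normalizedArmPosition(cat0, arms)
  expect_false(anyNA(pos))
  expect_equal(pos, cat0$true_norm_pos, tolerance = 1e-3)
  ks <- suppressWarnings(ks.test(pos, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("terminal enrichment detects biased catalogs and not uniform ones", {
  unif <- genCatalog(2000, arms, terminalBiasBeta = 0, seed = 23)
  posU <- normalizedArmPosition(unif, arms)
  resU <- terminalEnrichment(posU, 0.10)
  expect_equal(resU$proportion, 0.10,
               tolerance = 3 * sqrt(0.1 * 0.9 / 2000) / 0.10)
  biased <- genCatalog(2000, arms, terminalBiasBeta = 8, seed = 23)
  posB <- normalizedArmPosition(biased, arms)
  resB <- terminalEnrichment(posB, 0.10)
  expect_lt(resB$p_one_tailed, 1e-6)
  expect_equal(resB$proportion, terminalMassBeta(8, 0.10),
               tolerance = 3 * sqrt(0.25 / 2000) / terminalMassBeta(8, 0.10))
  ## terminal 5% can never hold more records than terminal 10%
  expect_lte(terminalEnrichment(posB, 0.05)$observed, resB$observed)
})

test_that("G4 stratification tracks a generator with G4-linked bias", {
  ## catalog with a terminal bias that sharpens with the G4 count:
  ## stratum g has positions u^(1/(1+2g)), terminal-10% mass
  ## 1 - 0.9^(1+2g) (0.10, 0.27, 0.41)
  set.seed(31)
  g4 <- rep(0:2, each = 1500)
  pos <- runif(length(g4))^(1 / (1 + 2 * g4))
  cat0 <- data.frame(g4_w30 = g4, gc_content = runif(length(g4), .3, .7))
  strat <- stratifyByG4(cat0, pos, minG4 = 0:2, f = 0.10)
  expect_equal(strat$n, c(4500L, 3000L, 1500L))
  expect_true(all(diff(strat$terminal_proportion) > 0))
  ## t = 0 stratum reduces to the overall terminal proportion
  expect_equal(strat$terminal_proportion[1],
               terminalEnrichment(pos, 0.10)$proportion)
  ## strata above the maximum count are empty and flagged
  stratE <- stratifyByG4(cat0, pos, minG4 = 5, f = 0.10)
  expect_equal(stratE$n, 0L)
  expect_true(is.na(stratE$terminal_proportion))
})

test_that("duplicate elimination keeps the longest overlapping array", {
  cat0 <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(100, 150, 5000, 150, 100),
    end   = c(400, 450, 5300, 450, 400),
    motif_size = c(20, 20, 20, 35, 20),
    array_length = c(301, 350, 301, 301, 301))
  dd <- dedupCatalog(cat0)
  ## the two overlapping motif-20 records on chr1 collapse to the longer
  expect_equal(nrow(dd), 4L)
  expect_equal(attr(dd, "removed"), 1L)
  expect_true(any(dd$start == 150 & dd$motif_size == 20))
  ## overlapping records with different motif sizes are both kept
  expect_true(any(dd$motif_size == 35))
  ## idempotent
  dd2 <- dedupCatalog(dd)
  expect_equal(attr(dd2, "removed"), 0L)
  expect_equal(nrow(dd2), nrow(dd))
  ## identical intervals collapse to one
  twin <- cat0[c(1, 1), ]
  expect_equal(nrow(dedupCatalog(twin)), 1L)
})

test_that("GC classification partitions exactly at 50%", {
  cat0 <- data.frame(gc_content = c(0.2, 0.5, 0.500001, 0.8))
  cls <- gcClass(cat0)
  expect_equal(cls, c("GC-poor", "GC-poor", "GC-rich", "GC-rich"))
  big <- genCatalog(500, arms, seed = 5)
  expect_true(all(gcClass(big) %in% c("GC-rich", "GC-poor")))
})

test_that("catalog and arm-model TSV dialects round-trip", {
  cat0 <- genCatalog(50, arms, seed = 7)
  f <- tempfile(fileext = ".tsv")
  writeTsv(cat0, f, seed = 7, params = list(window = 30))
  expect_true(startsWith(readLines(f, n = 1), "# miniGCR"))
  back <- readCatalogTsv(f)
  expect_equal(back$start, cat0$start)
  expect_equal(back$g4_w30, cat0$g4_w30)
  ## compact arm dialect expands to two arms per chromosome
  fa <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tp_start\tp_end\tcentromere\tq_end",
               "chr1\t1\t5000000\t6000000\t14000000"), fa)
  am <- readArmModelTsv(fa)
  expect_equal(nrow(am), 2L)
  expect_equal(am$centromere_side, c("end", "start"))
  ## BED-like dialect converts to 1-based inclusive
  fb <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", fb)
  bed <- readCatalogTsv(fb, dialect = "bed")
  expect_equal(bed$start, 1L)
  expect_equal(bed$end, 100L)
})
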