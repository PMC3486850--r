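## Seeded generators for every input class the analysis consumes, each
## returning ground truth sufficient to compute the expected downstream
## output. Each generator draws from an independent stream derived from
## (seed, generator name), so adding a generator never shifts the
## output of another.

## name-salted 32-bit stream seed
streamSeed <- function(seed, name) {
  salt <- c(catalog = 101L, array = 211L, junction = 307L,
            fluctuation = 401L, telomere = 503L, arms = 601L)
  if (!name %in% names(salt)) stop("unknown stream: ", name)
  as.integer((as.numeric(seed) * 48271 + salt[[name]]) %% 2147483647)
}

## evaluate expr under a local RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Synthetic chromosome-arm model
#'
#' A simple arm geometry for simulation and testing: `nChrom`
#' chromosomes, each with a p and a q arm of the given lengths
#' separated by a centromere gap.
#'
#' @param nChrom number of chromosomes.
#' @param pLen,qLen arm lengths (bp).
#' @param gap centromere gap (bp).
#' @return an arm-model `data.frame` (see [normalizedArmPosition()]).
#' @export
syntheticArmModel <- function(nChrom = 4L, pLen = 5e6, qLen = 8e6,
                              gap = 1e6) {
  do.call(rbind, lapply(seq_len(nChrom), function(i) {
    chrom <- paste0("chr", i)
    data.frame(
      chrom = chrom,
      arm = c("p", "q"),
      arm_start = c(1, pLen + gap + 1),
      arm_end = c(pLen, pLen + gap + qLen),
      centromere_side = c("end", "start"))
  }))
}

#' Generate a synthetic minisatellite catalog
#'
#' Emulates the structure of a genome-wide tandem-repeat catalog:
#' positions along normalised arms follow the density proportional to
#' `1 + beta * x` on \[0, 1\] (`beta = 0` is uniform; larger `beta`
#' pushes mass toward the telomere at 1, with terminal-fraction mass
#' available in closed form via [terminalMassBeta()]). GC content is a
#' two-component (GC-poor / GC-rich) truncated-normal mixture, and G4
#' counts are Poisson with a class-dependent mean, extended monotonely
#' across window sizes. Ground-truth columns (`true_norm_pos`,
#' `gc_class_true`) are carried for recovery tests.
#'
#' @param nRecords number of records.
#' @param arms arm model (default [syntheticArmModel()]).
#' @param terminalBiasBeta non-negative slope of the position density.
#' @param gcMixture list with `weightRich`, `meanPoor`, `sdPoor`,
#'   `meanRich`, `sdRich`.
#' @param g4Lambda named numeric `c(poor = , rich = )` Poisson means
#'   for the window-30 G4 count.
#' @param seed integer seed.
#' @return a catalog `data.frame` with columns `chrom`, `start`, `end`,
#'   `motif_size`, `copy_number`, `array_length`, `gc_content`,
#'   `gc_bias`, `g4_w30`, `g4_w40`, `g4_w50`, `g4_w100`, `g4_strand`,
#'   plus truth columns.
#' @export
genCatalog <- function(nRecords, arms = syntheticArmModel(),
                       terminalBiasBeta = 0,
                       gcMixture = list(weightRich = 0.24,
                                        meanPoor = 0.38, sdPoor = 0.07,
                                        meanRich = 0.62, sdRich = 0.07),
                       g4Lambda = c(poor = 0.02, rich = 0.8),
                       seed = 1L) {
  stopifnot(nrow(arms) > 0, terminalBiasBeta >= 0,
            gcMixture$weightRich >= 0, gcMixture$weightRich <= 1)
  beta <- terminalBiasBeta
  withSeed(streamSeed(seed, "catalog"), {
    armIdx <- sample.int(nrow(arms), nRecords, replace = TRUE,
                         prob = arms$arm_end - arms$arm_start)
    ## inverse-CDF sample of density (1 + beta x) / (1 + beta/2)
    u <- runif(nRecords)
    x <- if (beta == 0) u else
      (sqrt(1 + 2 * beta * u * (1 + beta / 2)) - 1) / beta
    motifSize <- sample(10:100, nRecords, replace = TRUE)
    copyNumber <- round(runif(nRecords, 2, 40), 1)
    arrayLength <- as.integer(round(motifSize * copyNumber))
    rich <- runif(nRecords) < gcMixture$weightRich
    gc <- ifelse(rich,
                 rnorm(nRecords, gcMixture$meanRich, gcMixture$sdRich),
                 rnorm(nRecords, gcMixture$meanPoor, gcMixture$sdPoor))
    gc <- pmin(0.99, pmax(0.01, gc))
    gcb <- pmin(1, pmax(0, rnorm(nRecords, 0.5 + 0.3 * rich, 0.1)))
    g30 <- rpois(nRecords, ifelse(rich, g4Lambda[["rich"]],
                                  g4Lambda[["poor"]]))
    g40 <- g30 + rpois(nRecords, 0.1 * g30)
    g50 <- g40 + rpois(nRecords, 0.1 * g30)
    g100 <- g50 + rpois(nRecords, 0.2 * g30)
    strand <- ifelse(g30 == 0, "none",
                     ifelse(runif(nRecords) < 0.5, "G", "C"))
  })
  len <- arms$arm_end[armIdx] - arms$arm_start[armIdx]
  mid <- ifelse(arms$centromere_side[armIdx] == "start",
                arms$arm_start[armIdx] + x * len,
                arms$arm_end[armIdx] - x * len)
  start <- pmax(arms$arm_start[armIdx],
                as.integer(round(mid - arrayLength / 2)))
  data.frame(
    chrom = arms$chrom[armIdx],
    start = start,
    end = start + arrayLength - 1L,
    motif_size = motifSize,
    copy_number = copyNumber,
    array_length = arrayLength,
    gc_content = gc,
    gc_bias = gcb,
    g4_w30 = g30, g4_w40 = g40, g4_w50 = g50, g4_w100 = g100,
    g4_strand = strand,
    true_norm_pos = x,
    gc_class_true = ifelse(rich, "GC-rich", "GC-poor"))
}

#' Closed-form terminal mass of the biased position density
#'
#' The probability that a position drawn from the density proportional
#' to `1 + beta * x` on \[0, 1\] falls beyond `1 - f`:
#' `(f + beta * (1 - (1-f)^2) / 2) / (1 + beta / 2)`.
#'
#' @param beta density slope (>= 0).
#' @param f terminal fraction.
#' @return probability.
#' @export
terminalMassBeta <- function(beta, f = 0.10) {
  (f + beta * (1 - (1 - f)^2) / 2) / (1 + beta / 2)
}

#' Generate a tandem array with seeded point variation
#'
#' Concatenates `copies` copies of the motif and applies independent
#' per-nucleotide point mutations at rate `pointMutationRate` (each
#' mutated position is replaced by a uniformly drawn different base).
#'
#' @param motif motif sequence.
#' @param copies number of copies.
#' @param pointMutationRate per-nucleotide mutation probability in
#'   \[0, 1).
#' @param orientation array orientation (`"G"` or `"C"`).
#' @param motifName label.
#' @param seed integer seed.
#' @return a [TandemArray-class]; the attribute `mutatedPositions`
#'   records the ground-truth mutated positions (on the G-strand
#'   concatenation).
#' @export
genArray <- function(motif, copies, pointMutationRate = 0,
                     orientation = "G", motifName = "motif", seed = 1L) {
  stopifnot(pointMutationRate >= 0, pointMutationRate < 1)
  motif <- asDNAString(motif)
  base <- strrep(as.character(motif), copies)
  mut <- integer()
  if (pointMutationRate > 0) {
    withSeed(streamSeed(seed, "array"), {
      hit <- which(runif(nchar(base)) < pointMutationRate)
      if (length(hit)) {
        ch <- strsplit(base, "")[[1L]]
        ch[hit] <- vapply(ch[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        base <- paste(ch, collapse = "")
      }
      mut <- hit
    })
  }
  ta <- suppressWarnings(TandemArray(
    motif, copies = copies, orientation = orientation,
    motifName = motifName,
    variant = if (length(mut)) base else NULL))
  attr(ta, "mutatedPositions") <- mut
  ta
}

#' Generate a random TG1-3 telomeric tract
#'
#' Repeats of `T` followed by 1-3 `G` (uniform on k) until at least
#' `length` nt, then truncated to exactly `length` nt.
#'
#' @param length target length (nt); 0 gives an empty string.
#' @param seed integer seed.
#' @return character telomeric sequence.
#' @export
genTelomereTract <- function(length, seed = 1L) {
  if (length <= 0) return("")
  withSeed(streamSeed(seed, "telomere"), {
    reps <- character(0)
    total <- 0L
    while (total < length) {
      k <- sample.int(3L, 1L)
      reps <- c(reps, paste0("T", strrep("G", k)))
      total <- total + 1L + k
    }
  })
  substr(paste(reps, collapse = ""), 1L, length)
}

#' Generate telomere-addition junction reads with ground truth
#'
#' Each read is the array prefix up to a breakpoint followed by a
#' telomeric suffix drawn from the TG1-3 grammar, emulating sequenced
#' array-telomere junctions. The ground truth records the breakpoint
#' and the analytically determined junction index and shared span (the
#' rightmost motif-templated position and the interval of nucleotides
#' compatible with both the motif continuation and the telomeric
#' grammar), computed directly from the definitions at generation time.
#'
#' @param array a [TandemArray-class] (orientation G).
#' @param n number of reads.
#' @param breakpoint `"random"` or integer vector of 1-based array
#'   positions (last array-templated nucleotide).
#' @param telomereLengthMean,telomereLengthSD normal law for the
#'   telomeric suffix length (defaults 300 and 75 bp, wild-type).
#' @param seed integer seed.
#' @return a `data.frame` with columns `read`, `breakpoint`,
#'   `true_junction`, `true_shared_start`, `true_shared_end` (`NA` when
#'   no nucleotide is shared), `telo_len`.
#' @export
genJunctionReads <- function(array, n, breakpoint = "random",
                             telomereLengthMean = 300,
                             telomereLengthSD = 75, seed = 1L) {
  stopifnot(is(array, "TandemArray"))
  arr <- as.character(arraySeq(array))
  mo <- as.character(motifSeq(array))
  withSeed(streamSeed(seed, "junction"), {
    bp <- if (identical(breakpoint, "random"))
      sample.int(nchar(arr), n, replace = TRUE) else
      rep_len(as.integer(breakpoint), n)
    tlen <- pmax(0L, as.integer(round(
      rnorm(n, telomereLengthMean, telomereLengthSD))))
    teloSeed <- sample.int(1e6L, n)
  })
  reads <- character(n)
  truth <- matrix(NA_integer_, n, 3)
  for (i in seq_len(n)) {
    telo <- genTelomereTract(tlen[i], seed = teloSeed[i])
    read <- paste0(substr(arr, 1L, bp[i]), telo)
    reads[i] <- read
    nn <- nchar(read)
    ## truth from the definitions: maximal matching prefix vs the
    ## infinite motif repetition, and minimal telomeric suffix start
    ref <- substr(strrep(mo, ceiling(nn / nchar(mo)) + 1L), 1L, nn)
    cmp <- strsplit(read, "")[[1L]] == strsplit(ref, "")[[1L]]
    a <- if (all(cmp)) nn else which(!cmp)[1L] - 1L
    s <- nn + 1L
    for (st in seq_len(nn + 1L)) {
      if (st > nn ||
            isTelomericSeq(substr(read, st, nn), partial = TRUE)) {
        s <- st
        break
      }
    }
    truth[i, ] <- c(a, if (s <= a) s else NA_integer_,
                    if (s <= a) a else NA_integer_)
  }
  data.frame(read = reads, breakpoint = bp,
             true_junction = truth[, 1],
             true_shared_start = truth[, 2],
             true_shared_end = truth[, 3],
             telo_len = tlen)
}

#' Generate fluctuation-assay data
#'
#' Convenience wrapper around [simulateLD()] so every synthetic input
#' class is produced by a generator with the same seeding protocol.
#'
#' @inheritParams simulateLD
#' @return a [FluctuationExperiment-class].
#' @export
genFluctuation <- function(mu, Nt, C, seed = 1L, label = "simulated") {
  simulateLD(mu = mu, Nt = Nt, C = C, seed = seed, label = label)
}
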