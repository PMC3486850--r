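## Independent oracles used across the suite. These re-derive expected
## values from definitions (naive enumeration, closed forms), never by
## calling the implementation under test.

## naive per-position dinucleotide counter
naiveDinucCounts <- function(s) {
  fwd <- 0L; rev <- 0L
  for (i in seq_len(nchar(s) - 1L)) {
    d <- substr(s, i, i + 1L)
    if (d %in% c("TG", "GG", "GT")) fwd <- fwd + 1L
    if (d %in% c("CA", "CC", "AC")) rev <- rev + 1L
  }
  c(forward = fwd, reverse = rev)
}

## brute-force maximum number of pairwise-disjoint valid G4 windows:
## enumerate all consecutive n-tuples of maximal G-runs satisfying the
## loop and minimal-span constraints, then take a maximum-cardinality
## disjoint selection by dynamic programming over interval end points.
bruteForceG4Count <- function(s, params = G4ScanParams()) {
  runs <- findGRuns(s, params@tractMinG)
  n <- params@nTracts; k <- params@tractMinG
  lmin <- params@loopMin; lmax <- loopMax(params)
  cand <- list()
  if (nrow(runs) >= n) {
    for (i in seq_len(nrow(runs) - n + 1L)) {
      st <- runs$start[i:(i + n - 1L)]
      le <- runs$length[i:(i + n - 1L)]
      gaps <- st[-1L] - (st[-n] + le[-n])
      span <- (st[n] + k - 1L) - (st[1L] + le[1L] - k) + 1L
      if (all(gaps >= lmin & gaps <= lmax) && span <= params@windowMax)
        cand[[length(cand) + 1L]] <- c(st[1L], st[n] + le[n] - 1L)
    }
  }
  if (!length(cand)) return(0L)
  iv <- do.call(rbind, cand)
  iv <- iv[order(iv[, 2L]), , drop = FALSE]
  ## DP: best[j] = max windows using candidates 1..j
  best <- integer(nrow(iv))
  for (j in seq_len(nrow(iv))) {
    compat <- which(iv[, 2L] < iv[j, 1L])
    best[j] <- 1L + if (length(compat)) max(best[compat]) else 0L
  }
  max(best)
}

## brute-force longest common substring by full enumeration
bruteForceLCS <- function(a, b) {
  best <- ""
  for (i in seq_len(nchar(a))) {
    for (j in i:nchar(a)) {
      sub <- substr(a, i, j)
      if (nchar(sub) > nchar(best) && grepl(sub, b, fixed = TRUE))
        best <- sub
    }
  }
  best
}

## brute-force two-sided Fisher p by total enumeration over tables
## with the observed margins (point-probability rule)
bruteForceFisherP <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  pk <- dhyper(ks, r1, r2, c1)
  pObs <- dhyper(a, r1, r2, c1)
  sum(pk[pk <= pObs * (1 + 1e-7)])
}

## random ACGT sequence
randomSeq <- function(len, gProb = 0.25) {
  p <- c((1 - gProb) / 3, (1 - gProb) / 3, gProb, (1 - gProb) / 3)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

revCompChar <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
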