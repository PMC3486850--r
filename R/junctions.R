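## Telomere-addition junction analysis: seed maps, motif-telomere
## homology, the TG1-3 repeat grammar, junction annotation, remaining-
## motif estimation from restriction-fragment sizes, and Cdc13
## consensus-site search.

#' Map telomere-seed dinucleotides on a motif
#'
#' De novo telomere addition can initiate at as little as 2 nt of
#' homology to the telomeric repeat: a TG, GG or GT dinucleotide. This
#' returns every (possibly overlapping) start position of such a seed
#' on the given strand, and, when a G-quadruplex-forming region of the
#' motif is configured, the fraction of seeds overlapping it (a seed
#' overlaps if either of its two nucleotides falls in the region).
#'
#' @inheritParams gcContent
#' @param g4Region optional 1-based inclusive `c(start, end)` interval
#'   of the motif designated as the G-quadruplex-forming sequence (for
#'   CEB1 the G-rich 5' block, nt 1-17).
#' @return a list with integer `positions` (1-based starts), `count`,
#'   and when `g4Region` is given, `overlapCount` and
#'   `overlapFraction`.
#' @examples
#' seedMap(studyMotifs()[["CEB1"]], g4Region = c(1, 17))  # 12/20 = 60%
#' @export
seedMap <- function(x, g4Region = NULL) {
  s <- seqChar(x)
  if (nchar(s) < 2L) stop("need at least 2 nt")
  d <- substring(s, seq_len(nchar(s) - 1L), 2:nchar(s))
  pos <- which(d %in% c("TG", "GG", "GT"))
  out <- list(positions = pos, count = length(pos))
  if (!is.null(g4Region)) {
    stopifnot(length(g4Region) == 2L, g4Region[1L] <= g4Region[2L])
    ov <- pos <= g4Region[2L] & (pos + 1L) >= g4Region[1L]
    out$overlapCount <- sum(ov)
    out$overlapFraction <-
      if (length(pos)) sum(ov) / length(pos) else NA_real_
  }
  out
}

#' Longest common substring between a motif and a telomeric sequence
#'
#' The longest contiguous run of nucleotides present in both sequences
#' (for CEB1 against yeast TG1-3 telomeric DNA this is `GGGTGG`,
#' 6 nt). Ties are broken by the leftmost position in the motif.
#'
#' @param motif,telomere sequences (character or
#'   [Biostrings::DNAString]).
#' @return a list with `substring`, `length`, and 1-based `motifStart`,
#'   `telomereStart` (all `NA`/0 when there is no common nucleotide).
#' @examples
#' longestTelomereHomology(studyMotifs()[["CEB1"]], "TGTGGGTGGGTGTGG")
#' @export
longestTelomereHomology <- function(motif, telomere) {
  a <- seqChar(motif); b <- seqChar(telomere)
  if (!nchar(a) || !nchar(b)) stop("both sequences must be non-empty")
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  n <- length(ca); m <- length(cb)
  best <- 0L; bestA <- NA_integer_; bestB <- NA_integer_
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    match <- ca[i] == cb
    cur[match] <- c(0L, prev)[which(match)] + 1L
    if (length(cur) && max(cur) > best) {   # strict > keeps leftmost motif tie
      j <- which.max(cur)
      best <- cur[j]; bestA <- i - best + 1L; bestB <- j - best + 1L
    }
    prev <- cur
  }
  if (best == 0L)
    return(list(substring = "", length = 0L, motifStart = NA_integer_,
                telomereStart = NA_integer_))
  list(substring = substr(a, bestA, bestA + best - 1L), length = best,
       motifStart = bestA, telomereStart = bestB)
}

#' Yeast TG1-3 telomeric repeat grammar
#'
#' The irregular yeast telomeric repeat on the G-rich strand is
#' modelled as one or more repeats of `T` followed by 1-3 `G`
#' (`(TG{1,3})+`). Whole-string acceptance (`partial = FALSE`) requires
#' complete repeats; suffix parsing at junctions (`partial = TRUE`)
#' additionally permits a partial leading repeat (up to 3 bare `G`,
#' continuing a repeat cut by the junction) and a partial trailing
#' repeat (a bare `T`).
#'
#' @param x character vector of sequences.
#' @param partial allow partial leading/trailing repeats.
#' @return logical vector.
#' @examples
#' isTelomericSeq("TGTGGTGGG")            # TRUE
#' isTelomericSeq("GGGTGG")               # FALSE: partial leading repeat
#' isTelomericSeq("GGGTGG", partial = TRUE)
#' @export
isTelomericSeq <- function(x, partial = FALSE) {
  x <- toupper(x)
  pat <- if (partial) "^G{0,3}(TG{1,3})*T?$" else "^(TG{1,3})+$"
  nzchar(x) & grepl(pat, x)
}

#' Annotate a telomere-addition junction read
#'
#' A junction read consists of a motif-templated prefix (sequence
#' copied from the tandem array) followed by a de novo telomeric
#' suffix. The junction index is the end of the maximal motif-templated
#' prefix (read positions matching the tandem repetition of the motif,
#' tolerating up to `maxMismatches` mismatches, with the junction
#' position itself required to match). The shared span is the maximal
#' interval around the junction whose nucleotides are simultaneously
#' motif-templated and parse under the TG1-3 grammar with partial
#' edges: because telomere addition seeds on motif-telomere homology,
#' several nucleotides typically belong to both, and junction ambiguity
#' resolves to the rightmost motif-templated position. Mismatches
#' within `snvWindow` nt before the junction are reported as candidate
#' SNVs (apply [supportedSNVs()] across reads for the >= 3-read support
#' rule).
#'
#' @param read read sequence (character or [Biostrings::DNAString]).
#' @param motif the reference motif (G-rich strand); the read is
#'   assumed to start in phase with the motif (use `phase` otherwise).
#' @param phase 1-based motif position at which the read starts.
#' @param maxMismatches mismatches tolerated in the motif-templated
#'   prefix (default 0).
#' @param snvWindow window before the junction scanned for SNVs (nt).
#' @return a list with `junctionIndex` (last motif-templated read
#'   position; 0 for an entirely telomeric read), `sharedSpan`
#'   (`c(start, end)` read interval, or `NULL` when no nucleotide is
#'   shared), `sharedLength`, `snvs` (integer read positions), and
#'   `telomereStart` (first read position of the maximal telomeric
#'   suffix).
#' @examples
#' ceb1 <- as.character(studyMotifs()[["CEB1"]])
#' read <- paste0(substr(ceb1, 1, 17), "TGGTGGGTGTGGGTG")
#' annotateJunction(read, ceb1)
#' @export
annotateJunction <- function(read, motif, phase = 1L, maxMismatches = 0L,
                             snvWindow = 30L) {
  r <- seqChar(read); mo <- seqChar(motif)
  n <- nchar(r); L <- nchar(mo)
  stopifnot(phase >= 1L, phase <= L)
  ## reference: tandem repetition of the motif from the given phase
  ref <- substr(strrep(mo, ceiling((n + phase) / L) + 1L), phase,
                phase + n - 1L)
  rc <- strsplit(r, "")[[1L]]; fc <- strsplit(ref, "")[[1L]]
  match <- rc == fc
  ## maximal telomeric suffix: smallest start whose suffix parses
  teloStart <- n + 1L
  for (s in seq_len(n + 1L)) {
    if (s > n || isTelomericSeq(substr(r, s, n), partial = TRUE)) {
      teloStart <- s
      break
    }
  }
  ## maximal motif-templated prefix end
  mism <- cumsum(!match)
  ok <- which(match & mism <= maxMismatches)
  a <- if (length(ok)) max(ok) else 0L
  if (teloStart > a + 1L)
    stop("no telomeric suffix adjoining the motif-templated prefix")
  shared <- if (teloStart <= a) c(teloStart, a) else NULL
  snvs <- if (a > 0L) {
    w <- max(1L, a - snvWindow + 1L):a
    w[!match[w]]
  } else integer()
  list(junctionIndex = a,
       sharedSpan = shared,
       sharedLength = if (is.null(shared)) 0L else
         shared[2L] - shared[1L] + 1L,
       snvs = as.integer(snvs),
       telomereStart = teloStart)
}

#' SNVs supported by at least three reads
#'
#' Aggregates candidate SNV positions over several junction reads
#' covering the same junction and keeps positions reported by at least
#' `minReads` reads.
#'
#' @param snvLists list of integer vectors as returned in the `snvs`
#'   field of [annotateJunction()].
#' @param minReads minimum supporting reads (default 3).
#' @return integer vector of supported positions.
#' @export
supportedSNVs <- function(snvLists, minReads = 3L) {
  tab <- table(unlist(snvLists))
  as.integer(names(tab)[tab >= minReads])
}

#' Remaining motif copies from a restriction-fragment size
#'
#' Telomere-addition positions are estimated from the size of the
#' smeared restriction fragment by subtracting the flanking sequence
#' and the mean telomere length, then dividing by the motif length:
#' `(fragment - flank - telomereMean) / motifLen`, rounded to the
#' nearest whole motif. A negative remainder returns 0 with a warning.
#'
#' @param fragmentBp fragment size (bp).
#' @param flankBp flanking sequence size (bp); 50 for the CEB1
#'   construct, 1800 for the CEB25 construct.
#' @param telomereMeanBp mean telomere size (bp); 300 in wild-type
#'   cells, 400 in pif1-deleted cells.
#' @param motifLenBp motif length (bp).
#' @return non-negative integer motif count.
#' @examples
#' remainingMotifsFromFragment(1375, 50, 350, 39)   # 25 motifs
#' remainingMotifsFromFragment(2200, 1800, 300, 52) # ~100 bp -> 2
#' @export
remainingMotifsFromFragment <- function(fragmentBp, flankBp,
                                        telomereMeanBp, motifLenBp) {
  stopifnot(motifLenBp > 0)
  rem <- (fragmentBp - flankBp - telomereMeanBp) / motifLenBp
  if (any(rem < 0)) {
    warning("fragment smaller than flank + mean telomere; reporting 0")
    rem[rem < 0] <- 0
  }
  as.integer(floor(rem + 0.5))
}

#' Find Cdc13 consensus binding sites
#'
#' `mode = "exact"` finds exact occurrences of the 11-nt high-affinity
#' consensus `GTGTGGGTGTG`. `mode = "critical_prefix"` finds positions
#' where the critical `GTGT` prefix begins a TG-rich 11-nt window (at
#' least 9 of 11 nucleotides in `{T, G}`), a relaxed criterion for
#' near-consensus sites. Overlapping sites are allowed; only the given
#' strand is scanned.
#'
#' @inheritParams gcContent
#' @param mode `"exact"` or `"critical_prefix"`.
#' @return integer vector of 1-based start positions.
#' @examples
#' findCdc13Sites(studyMotifs()[["CEB25"]])  # one exact site at 31
#' @export
findCdc13Sites <- function(x, mode = c("exact", "critical_prefix")) {
  mode <- match.arg(mode)
  s <- seqChar(x)
  if (mode == "exact") {
    if (nchar(s) < 11L) return(integer())
    m <- gregexpr("(?=GTGTGGGTGTG)", s, perl = TRUE)[[1L]]
    return(if (m[1L] == -1L) integer() else as.integer(m))
  }
  if (nchar(s) < 11L) return(integer())
  starts <- seq_len(nchar(s) - 10L)
  hits <- vapply(starts, function(i) {
    if (substr(s, i, i + 3L) != "GTGT") return(FALSE)
    win <- strsplit(substr(s, i, i + 10L), "")[[1L]]
    sum(win %in% c("T", "G")) >= 9L
  }, logical(1))
  starts[hits]
}
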