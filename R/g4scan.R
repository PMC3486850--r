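## G-quadruplex-forming-sequence scanner: n tracts of >= k consecutive G
## within a bounded window, bounded loops, counted greedily without
## overlap (the rule used for the genome-wide minisatellite annotation).

#' Maximal G-runs of a sequence
#'
#' All maximal runs of consecutive `G` of at least `minLen` nt, left to
#' right. Runs are maximal: `GGGGGG` is a single run of 6, never two
#' runs of 3 (splitting would imply a zero-length loop, excluded by the
#' scanner's minimal loop of 1 nt).
#'
#' @inheritParams gcContent
#' @param minLen minimum run length.
#' @return a `data.frame` with 1-based `start` and `length` columns.
#' @examples
#' findGRuns(studyMotifs()[["CEB1"]], 3)
#' @export
findGRuns <- function(x, minLen = 3L) {
  s <- seqChar(x)
  m <- gregexpr("G+", s)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(), length = integer()))
  len <- attr(m, "match.length")
  keep <- len >= minLen
  data.frame(start = as.integer(m[keep]), length = as.integer(len[keep]))
}

#' Scan a sequence for G-quadruplex-forming sequences
#'
#' Greedy left-to-right non-overlapping scan: repeatedly find the
#' leftmost set of `nTracts` *consecutive* maximal G-runs whose loops
#' (gaps between consecutive tracts) all lie in
#' `[loopMin, loopMax(params)]` and whose tightest qualifying span fits
#' in `windowMax` nt; emit a hit and resume scanning strictly after the
#' hit's end, so a long G-run consumed by one hit cannot seed the next.
#'
#' The window test uses the minimal span: when a tract is longer than
#' `tractMinG`, the first tract contributes only its trailing
#' `tractMinG` G and the last tract only its leading `tractMinG` G, so a
#' long 5' G-run cannot disqualify an otherwise identical motif. The
#' reported hit interval still covers the full maximal tracts.
#'
#' @inheritParams gcContent
#' @param params a [G4ScanParams-class].
#' @return a `data.frame` of hits with 1-based inclusive `start`, `end`,
#'   and comma-separated `tract_starts` and `tract_lengths` columns.
#' @seealso [countG4()] for counting, [annotateCatalogG4()] for catalog
#'   annotation.
#' @examples
#' g4Hits(studyMotifs()[["CEB25"]])                      # one hit
#' g4Hits(TandemArray(studyMotifs()[["CEB1"]], copies = 2)) # junction hit
#' @export
g4Hits <- function(x, params = G4ScanParams()) {
  stopifnot(is(params, "G4ScanParams"))
  runs <- findGRuns(x, params@tractMinG)
  n <- params@nTracts
  k <- params@tractMinG
  lmin <- params@loopMin
  lmax <- loopMax(params)
  hits <- list()
  i <- 1L
  while (i + n - 1L <= nrow(runs)) {
    st <- runs$start[i:(i + n - 1L)]
    le <- runs$length[i:(i + n - 1L)]
    gaps <- st[-1L] - (st[-n] + le[-n])
    ## tightest span: suffix of k G in first tract .. prefix of k G in last
    span <- (st[n] + k - 1L) - (st[1L] + le[1L] - k) + 1L
    if (all(gaps >= lmin & gaps <= lmax) && span <= params@windowMax) {
      hitEnd <- st[n] + le[n] - 1L
      hits[[length(hits) + 1L]] <- data.frame(
        start = st[1L], end = hitEnd,
        tract_starts = paste(st, collapse = ","),
        tract_lengths = paste(le, collapse = ","))
      ## resume strictly after the hit
      nxt <- which(runs$start > hitEnd)
      i <- if (length(nxt)) nxt[1L] else nrow(runs) + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(), end = integer(),
               tract_starts = character(), tract_lengths = character())
}

#' Count non-overlapping G-quadruplex-forming sequences
#'
#' @inheritParams g4Hits
#' @param strandMode `"given"` scans the given strand only; `"both"`
#'   scans the given strand and its reverse complement independently.
#' @return for `strandMode = "given"`, a single integer; for `"both"`, a
#'   named integer vector `c(given = , reverse = )`.
#' @examples
#' countG4(studyMotifs()[["HRAS1"]])                       # 0
#' countG4(TandemArray(studyMotifs()[["CEB25"]], 3))       # 3
#' @export
countG4 <- function(x, params = G4ScanParams(),
                    strandMode = c("given", "both")) {
  strandMode <- match.arg(strandMode)
  s <- seqChar(x)
  given <- nrow(g4Hits(s, params))
  if (strandMode == "given") return(given)
  c(given = given, reverse = nrow(g4Hits(revComp(s), params)))
}

#' Annotate a minisatellite catalog with per-window G4 counts
#'
#' For each catalog record carrying its array sequence, counts
#' non-overlapping G-quadruplex-forming sequences at every window size
#' in `windows` (columns `g4_w<window>`) and labels the strand carrying
#' hits at the smallest window: `"G"` for the given strand, `"C"` for
#' the reverse complement, `"GC"` for both, `"none"` for neither.
#' Counts are monotonically non-decreasing in the window size.
#'
#' @param catalog a `data.frame` of minisatellite records with a
#'   `sequence` column (see [readCatalogTsv()] / [genCatalog()]).
#' @param windows integer window sizes in nt.
#' @param params base [G4ScanParams-class]; its `windowMax` is replaced
#'   by each element of `windows` in turn.
#' @return `catalog` with added `g4_w*` columns and a `g4_strand`
#'   column. Records without a sequence are skipped with a warning
#'   (their counts are `NA`).
#' @export
annotateCatalogG4 <- function(catalog, windows = c(30L, 40L, 50L, 100L),
                              params = G4ScanParams()) {
  stopifnot(is.data.frame(catalog))
  if (is.null(catalog$sequence))
    stop("catalog has no 'sequence' column")
  windows <- sort(as.integer(windows))
  noSeq <- is.na(catalog$sequence) | !nzchar(catalog$sequence)
  if (any(noSeq))
    warning(sum(noSeq), " record(s) without sequence skipped")
  for (w in windows)
    catalog[[paste0("g4_w", w)]] <- NA_integer_
  catalog$g4_strand <- NA_character_
  for (i in which(!noSeq)) {
    s <- catalog$sequence[i]
    for (w in windows) {
      pw <- G4ScanParams(params@nTracts, params@tractMinG, w,
                         params@loopMin)
      catalog[[paste0("g4_w", w)]][i] <- countG4(s, pw)
    }
    p0 <- G4ScanParams(params@nTracts, params@tractMinG, windows[1L],
                       params@loopMin)
    both <- countG4(s, p0, strandMode = "both")
    catalog$g4_strand[i] <-
      if (both["given"] > 0L && both["reverse"] > 0L) "GC"
      else if (both["given"] > 0L) "G"
      else if (both["reverse"] > 0L) "C"
      else "none"
  }
  catalog
}
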