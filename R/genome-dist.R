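## Minisatellite catalog analysis on normalised chromosome-arm
## coordinates: positions, GC-rich classification, G4 stratification,
## terminal enrichment, and duplicate elimination.

#' Normalised chromosome-arm position of catalog records
#'
#' Maps each record's midpoint onto its chromosome arm, scaled so the
#' centromere is at 0 and the telomere at 1. Records whose midpoint
#' falls outside every annotated arm (e.g. inside a centromere gap, or
#' on an arm without annotation) get `NA` and are excluded from
#' downstream distributions, with a warning giving the count.
#'
#' @param catalog `data.frame` with `chrom`, `start`, `end` columns
#'   (1-based inclusive coordinates).
#' @param arms arm model `data.frame` with columns `chrom`, `arm`
#'   (`"p"`/`"q"`), `arm_start`, `arm_end` (1-based inclusive), and
#'   `centromere_side` (`"start"` or `"end"`: which end of the interval
#'   is centromeric). See [readArmModelTsv()] / [syntheticArmModel()].
#' @return numeric vector in \[0, 1\] (or `NA`), one per record.
#' @export
normalizedArmPosition <- function(catalog, arms) {
  stopifnot(all(c("chrom", "start", "end") %in% names(catalog)),
            all(c("chrom", "arm_start", "arm_end", "centromere_side")
                %in% names(arms)),
            all(arms$arm_end > arms$arm_start))
  mid <- (catalog$start + catalog$end) / 2
  pos <- rep(NA_real_, nrow(catalog))
  for (j in seq_len(nrow(arms))) {
    hit <- catalog$chrom == arms$chrom[j] &
      mid >= arms$arm_start[j] & mid <= arms$arm_end[j]
    len <- arms$arm_end[j] - arms$arm_start[j]
    d <- if (arms$centromere_side[j] == "start")
      mid - arms$arm_start[j] else arms$arm_end[j] - mid
    pos[hit] <- d[hit] / len
  }
  if (anyNA(pos))
    warning(sum(is.na(pos)), " record(s) outside all annotated arms excluded")
  pos
}

#' Terminal enrichment of a catalog subset
#'
#' Counts records with normalised arm position beyond `1 - f` and tests
#' enrichment over the uniform-along-arm expectation `f * total` with a
#' one-tailed chi-square ([chisqTerminalOneTailed()]); records are
#' assigned to the terminal bin by midpoint.
#'
#' @param positions numeric normalised positions (from
#'   [normalizedArmPosition()]); `NA`s are dropped.
#' @param f terminal fraction tested (0.10 or 0.05 in the genome-wide
#'   analysis).
#' @return a list with `fraction`, `observed`, `total`, `expected`,
#'   `proportion`, `chi2` and `p_one_tailed`.
#' @export
terminalEnrichment <- function(positions, f = 0.10) {
  positions <- positions[!is.na(positions)]
  total <- length(positions)
  if (total == 0L) stop("no records with a defined arm position")
  observed <- sum(positions > 1 - f)
  ct <- chisqTerminalOneTailed(observed, total, f)
  list(fraction = f, observed = observed, total = total,
       expected = ct$expected, proportion = observed / total,
       chi2 = ct$statistic, p_one_tailed = ct$p_value)
}

#' Terminal proportion stratified by G4 count
#'
#' For each threshold `t` in `minG4`, the proportion of records with at
#' least `t` non-overlapping G-quadruplex-forming sequences that lie in
#' the terminal fraction `f`, with the stratum's mean GC content (used
#' to check that G4 stratification does not covary with GC content).
#'
#' @param catalog `data.frame` with a G4-count column (default
#'   `g4_w30`) and a `gc_content` column.
#' @param positions normalised arm positions, parallel to `catalog`.
#' @param minG4 integer thresholds.
#' @param f terminal fraction.
#' @param g4Column name of the G4-count column.
#' @return a `data.frame` with columns `min_g4`, `n`,
#'   `terminal_proportion`, `mean_gc`; empty strata get `NA`
#'   proportions.
#' @export
stratifyByG4 <- function(catalog, positions, minG4 = 0:5, f = 0.10,
                         g4Column = "g4_w30") {
  stopifnot(g4Column %in% names(catalog),
            nrow(catalog) == length(positions))
  keep <- !is.na(positions)
  g4 <- catalog[[g4Column]][keep]
  gc <- catalog$gc_content[keep]
  pos <- positions[keep]
  rows <- lapply(minG4, function(t) {
    idx <- !is.na(g4) & g4 >= t
    n <- sum(idx)
    data.frame(min_g4 = t, n = n,
               terminal_proportion =
                 if (n) mean(pos[idx] > 1 - f) else NA_real_,
               mean_gc = if (n) mean(gc[idx]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Eliminate overlapping duplicate catalog records
#'
#' Tandem-repeat finders can report the same array more than once with
#' slightly shifted boundaries. Among records on the same chromosome
#' whose intervals overlap and that share the same motif size, only the
#' record with the longest array is kept (ties: leftmost). Overlapping
#' records with different motif sizes are different repeats and are all
#' kept. Idempotent.
#'
#' @param catalog `data.frame` with `chrom`, `start`, `end`,
#'   `motif_size` and `array_length` columns.
#' @return the deduplicated catalog, with attribute `removed` giving
#'   the number of records eliminated.
#' @export
dedupCatalog <- function(catalog) {
  need <- c("chrom", "start", "end", "motif_size", "array_length")
  stopifnot(all(need %in% names(catalog)))
  if (nrow(catalog) == 0L) return(structure(catalog, removed = 0L))
  keep <- logical(nrow(catalog))
  grp <- interaction(catalog$chrom, catalog$motif_size, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    ir <- IRanges::IRanges(catalog$start[idx], catalog$end[idx])
    cl <- S4Vectors::subjectHits(
      IRanges::findOverlaps(ir, IRanges::reduce(ir)))
    for (c0 in unique(cl)) {
      members <- idx[cl == c0]
      best <- members[order(-catalog$array_length[members],
                            catalog$start[members])][1L]
      keep[best] <- TRUE
    }
  }
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, removed = sum(!keep))
}

#' Classify catalog records as GC-rich or GC-poor
#'
#' GC-rich means GC content strictly greater than 0.5; the partition is
#' exhaustive and disjoint at the 50% threshold.
#'
#' @param catalog `data.frame` with a `gc_content` column (fractions).
#' @return character vector `"GC-rich"` / `"GC-poor"`.
#' @export
gcClass <- function(catalog) {
  ifelse(catalog$gc_content > 0.5, "GC-rich", "GC-poor")
}
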