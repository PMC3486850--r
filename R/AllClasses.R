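## S4 classes shared across the package.

#' TandemArray: a minisatellite motif repeated in tandem
#'
#' The unit all sequence-level operations act on: a motif (given as its
#' G-rich strand, 5'-3'), a copy number, and the chromosomal orientation
#' of the array relative to the distal telomere. In orientation `"G"` the
#' G-rich strand is co-oriented with the telomeric G-overhang; in
#' orientation `"C"` the array sequence is the reverse complement of the
#' orientation-`"G"` sequence. An explicit variant sequence (e.g. a
#' mutagenised array) may be supplied in place of the perfect
#' concatenation.
#'
#' @slot motif [Biostrings::DNAString] motif sequence, G-rich strand.
#' @slot motifName single character label.
#' @slot copies positive integer copy number.
#' @slot orientation `"G"` or `"C"`.
#' @slot variant [Biostrings::DNAString]; if non-empty, used as the array
#'   sequence instead of `rep(motif, copies)`.
#'
#' @examples
#' ta <- TandemArray(studyMotifs()[["CEB1"]], copies = 3, motifName = "CEB1")
#' arraySeq(ta)
#' @export
setClass("TandemArray",
  representation(
    motif = "DNAString",
    motifName = "character",
    copies = "integer",
    orientation = "character",
    variant = "DNAString"
  )
)

setValidity("TandemArray", function(object) {
  msg <- character()
  if (length(object@motif) < 1L) msg <- c(msg, "motif must be non-empty")
  if (!all(strsplit(as.character(object@motif), "")[[1]] %in%
             c("A", "C", "G", "T")))
    msg <- c(msg, "motif alphabet must be strictly {A,C,G,T}")
  if (length(object@copies) != 1L || is.na(object@copies) ||
        object@copies < 1L)
    msg <- c(msg, "copies must be a single positive integer")
  if (!object@orientation %in% c("G", "C"))
    msg <- c(msg, "orientation must be \"G\" or \"C\"")
  if (length(msg)) msg else TRUE
})

#' @param motif motif sequence ([Biostrings::DNAString] or character),
#'   G-rich strand 5'-3'.
#' @param copies positive integer number of tandem copies.
#' @param orientation `"G"` (default) or `"C"`.
#' @param motifName label for the motif.
#' @param variant optional explicit array sequence (e.g. carrying point
#'   mutations) overriding the perfect concatenation.
#' @return `TandemArray()` returns a [TandemArray-class] object.
#' @rdname TandemArray-class
#' @export
TandemArray <- function(motif, copies = 1L, orientation = c("G", "C"),
                        motifName = "motif", variant = NULL) {
  orientation <- match.arg(orientation)
  motif <- asDNAString(motif)
  L <- length(motif)
  if (L < 10L || L > 100L)
    warning("motif length ", L,
            " nt is outside the usual minisatellite range (10-100 nt)")
  variant <- if (is.null(variant)) Biostrings::DNAString("") else
    asDNAString(variant)
  new("TandemArray", motif = motif, motifName = motifName,
      copies = as.integer(copies), orientation = orientation,
      variant = variant)
}

#' G4ScanParams: rule set for the G-quadruplex-forming-sequence scanner
#'
#' The scanner looks for `nTracts` maximal runs of at least `tractMinG`
#' consecutive G whose tightest qualifying span fits in `windowMax`
#' nucleotides, with every inter-tract loop between `loopMin` and
#' `loopMax(params)` nucleotides. The maximal loop size is not a free
#' parameter: it is derived from the window as
#' `windowMax - nTracts * tractMinG - (nTracts - 1) * loopMin + loopMin`
#' (16 nt at the defaults of 4 tracts of 3 G in 30 nt with 1-nt minimal
#' loops).
#'
#' @slot nTracts integer number of G-tracts required (default 4).
#' @slot tractMinG integer minimum G-run length per tract (default 3).
#' @slot windowMax integer maximal window span in nt (default 30;
#'   catalog annotation also uses 40, 50 and 100).
#' @slot loopMin integer minimal loop length in nt (default 1).
#'
#' @examples
#' p <- G4ScanParams()
#' loopMax(p)  # 16 at defaults
#' @export
setClass("G4ScanParams",
  representation(
    nTracts = "integer",
    tractMinG = "integer",
    windowMax = "integer",
    loopMin = "integer"
  )
)

setValidity("G4ScanParams", function(object) {
  msg <- character()
  if (object@nTracts < 2L) msg <- c(msg, "nTracts must be >= 2")
  if (object@tractMinG < 1L) msg <- c(msg, "tractMinG must be >= 1")
  if (object@loopMin < 1L) msg <- c(msg, "loopMin must be >= 1")
  minWin <- object@nTracts * object@tractMinG +
    (object@nTracts - 1L) * object@loopMin
  if (object@windowMax < minWin)
    msg <- c(msg, sprintf(
      "windowMax (%d) cannot hold %d tracts of %d G with %d-nt loops (needs >= %d)",
      object@windowMax, object@nTracts, object@tractMinG, object@loopMin,
      minWin))
  if (length(msg)) msg else TRUE
})

#' @param nTracts,tractMinG,windowMax,loopMin see slots.
#' @return `G4ScanParams()` returns a [G4ScanParams-class] object.
#' @rdname G4ScanParams-class
#' @export
G4ScanParams <- function(nTracts = 4L, tractMinG = 3L, windowMax = 30L,
                         loopMin = 1L) {
  new("G4ScanParams", nTracts = as.integer(nTracts),
      tractMinG = as.integer(tractMinG), windowMax = as.integer(windowMax),
      loopMin = as.integer(loopMin))
}

#' FluctuationExperiment: one Luria-Delbruck fluctuation assay
#'
#' Per-culture resistant-colony counts `r` together with the number of
#' viable cells plated `Nt`. `Nt` is a single per-experiment value (the
#' mean of the permissive-plate counts); a vector of per-culture counts
#' is accepted and averaged with a warning. A plating fraction < 1
#' multiplies `Nt`.
#'
#' @slot r numeric vector of resistant colonies per culture (integer
#'   counts; fractional values are accepted with a warning).
#' @slot Nt numeric viable cells per culture (effective, after plating
#'   fraction).
#' @slot label condition name.
#'
#' @examples
#' fe <- FluctuationExperiment(r = c(0, 1, 1, 2, 3, 0, 1, 5, 2, 1),
#'                             Nt = 1e8, label = "example")
#' estimateRate(fe)
#' @export
setClass("FluctuationExperiment",
  representation(r = "numeric", Nt = "numeric", label = "character")
)

setValidity("FluctuationExperiment", function(object) {
  msg <- character()
  if (length(object@r) < 1L) msg <- c(msg, "need at least one culture")
  if (anyNA(object@r) || any(object@r < 0))
    msg <- c(msg, "all colony counts r must be non-negative")
  if (length(object@Nt) != 1L || is.na(object@Nt) || object@Nt <= 0)
    msg <- c(msg, "Nt must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @param r per-culture resistant colony counts (non-negative integers).
#' @param Nt viable cells per culture; a vector is averaged with a warning.
#' @param platingFraction fraction of each culture plated; multiplies `Nt`.
#' @param label condition name.
#' @return `FluctuationExperiment()` returns a
#'   [FluctuationExperiment-class] object.
#' @rdname FluctuationExperiment-class
#' @export
FluctuationExperiment <- function(r, Nt, platingFraction = 1,
                                  label = "experiment") {
  if (any(r != floor(r), na.rm = TRUE))
    warning("non-integer colony counts supplied; keeping them as given")
  if (length(Nt) > 1L) {
    warning("per-culture Nt supplied; using the mean across cultures")
    Nt <- mean(Nt)
  }
  if (length(r) < 10L)
    warning("only ", length(r),
            " cultures; at least 10 independent cultures are recommended")
  new("FluctuationExperiment", r = as.numeric(r),
      Nt = as.numeric(Nt) * platingFraction, label = label)
}

#' RateEstimate: a mutation-rate estimate from a fluctuation assay
#'
#' The expected number of mutations per culture `m` (Lea-Coulson method
#' of the median), the per-generation rate `M = m / Nt`, and Falcor-style
#' 95% confidence limits. When no mutants were observed (`median(r) = 0`)
#' the estimate is zero and flagged, with only the upper confidence limit
#' defined.
#'
#' @slot m expected mutations per culture.
#' @slot rate events per generation (`m / Nt`).
#' @slot ciLow,ciHigh 95% confidence limits on the rate.
#' @slot nCultures number of cultures used.
#' @slot medianR median resistant-colony count.
#' @slot label condition name.
#' @slot flag `""`, or `"no mutants observed"`.
#' @export
setClass("RateEstimate",
  representation(m = "numeric", rate = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", nCultures = "integer",
                 medianR = "numeric",
                 label = "character", flag = "character")
)

setValidity("RateEstimate", function(object) {
  msg <- character()
  if (object@m < 0 || object@rate < 0)
    msg <- c(msg, "m and rate must be non-negative")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
        !(object@ciLow <= object@rate && object@rate <= object@ciHigh))
    msg <- c(msg, "confidence interval must bracket the rate")
  if (length(msg)) msg else TRUE
})

## show methods ---------------------------------------------------------

setMethod("show", "TandemArray", function(object) {
  cat(sprintf("TandemArray: %s x %d copies, orientation %s (%d nt)\n",
              object@motifName, object@copies, object@orientation,
              length(arraySeq(object))))
  cat("  motif: ", as.character(object@motif), "\n", sep = "")
  if (length(object@variant) > 0L)
    cat("  carries an explicit variant sequence\n")
})

setMethod("show", "G4ScanParams", function(object) {
  cat(sprintf(
    "G4ScanParams: %d tracts of >=%d G, window <= %d nt, loops %d-%d nt\n",
    object@nTracts, object@tractMinG, object@windowMax, object@loopMin,
    loopMax(object)))
})

setMethod("show", "FluctuationExperiment", function(object) {
  cat(sprintf(
    "FluctuationExperiment '%s': %d cultures, Nt = %.3g, median r = %g\n",
    object@label, length(object@r), object@Nt, median(object@r)))
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate '%s': m = %.4g, rate = %.4g [%.4g, %.4g] (C = %d)\n",
              object@label, object@m, object@rate, object@ciLow,
              object@ciHigh, object@nCultures))
  if (nzchar(object@flag)) cat("  flag: ", object@flag, "\n", sep = "")
})
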