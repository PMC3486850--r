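## Generics and simple accessors.

#' Array sequence of a TandemArray
#'
#' Returns the full array sequence: the variant sequence if one was
#' supplied, otherwise the motif concatenated `copies` times; in
#' orientation `"C"` the reverse complement of the orientation-`"G"`
#' sequence.
#'
#' @param x a [TandemArray-class].
#' @return a [Biostrings::DNAString].
#' @export
setGeneric("arraySeq", function(x) standardGeneric("arraySeq"))

#' @rdname arraySeq
#' @export
setMethod("arraySeq", "TandemArray", function(x) {
  s <- if (length(x@variant) > 0L) x@variant else
    Biostrings::DNAString(strrep(as.character(x@motif), x@copies))
  if (x@orientation == "C") Biostrings::reverseComplement(s) else s
})

#' @describeIn TandemArray-class motif sequence accessor.
#' @param x a `TandemArray`.
#' @export
setGeneric("motifSeq", function(x) standardGeneric("motifSeq"))

#' @rdname TandemArray-class
#' @export
setMethod("motifSeq", "TandemArray", function(x) x@motif)

#' @describeIn TandemArray-class copy-number accessor.
#' @export
setGeneric("copies", function(x) standardGeneric("copies"))

#' @rdname TandemArray-class
#' @export
setMethod("copies", "TandemArray", function(x) x@copies)

#' @describeIn TandemArray-class orientation accessor.
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname TandemArray-class
#' @export
setMethod("orientation", "TandemArray", function(x) x@orientation)

#' Derived maximal loop length of a G4 scan rule set
#'
#' @param x a [G4ScanParams-class].
#' @return integer maximal loop length in nt.
#' @export
setGeneric("loopMax", function(x) standardGeneric("loopMax"))

#' @rdname loopMax
#' @export
setMethod("loopMax", "G4ScanParams", function(x) {
  x@windowMax - x@nTracts * x@tractMinG -
    (x@nTracts - 1L) * x@loopMin + x@loopMin
})

#' Estimate the mutation rate of a fluctuation experiment
#'
#' @param x a [FluctuationExperiment-class].
#' @param ... passed on to methods.
#' @return a [RateEstimate-class].
#' @export
setGeneric("estimateRate", function(x, ...) standardGeneric("estimateRate"))

#' Accessors for RateEstimate
#'
#' @param x a [RateEstimate-class].
#' @return `rateM()` the per-generation rate; `rateCI()` the 95%
#'   confidence limits as a named numeric of length 2.
#' @export
setGeneric("rateM", function(x) standardGeneric("rateM"))

#' @rdname rateM
#' @export
setMethod("rateM", "RateEstimate", function(x) x@rate)

#' @rdname rateM
#' @export
setGeneric("rateCI", function(x) standardGeneric("rateCI"))

#' @rdname rateM
#' @export
setMethod("rateCI", "RateEstimate", function(x)
  c(low = x@ciLow, high = x@ciHigh))
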