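## Built-in study motifs and shared sequence utilities.

#' The three subtelomeric human minisatellite motifs
#'
#' Consensus motifs of the CEB1 (39 nt, 2q37.3), CEB25 (52 nt, 10q26.3)
#' and HRAS1 (28 nt, 11p15.5) minisatellites, each given as the G-rich
#' strand 5'-3'. CEB1 and CEB25 can fold into G-quadruplexes; HRAS1
#' cannot (a single G-tract of >= 3 G). CEB25 additionally carries a
#' high-affinity Cdc13 consensus binding site.
#'
#' @return a [Biostrings::DNAStringSet] named `CEB1`, `CEB25`, `HRAS1`.
#' @examples
#' studyMotifs()
#' @export
studyMotifs <- function() {
  Biostrings::DNAStringSet(c(
    CEB1  = "GGGGGGAGGGAGGGTGGCCTGCGGAGGTCCCTGGGCTGA",
    CEB25 = "AAGGGTGGGTGTAAGTGTGGGTGGGTGTGAGTGTGGGTGTGGAGGTAGATGT",
    HRAS1 = "CCCCTGGAGAGAAGGGGGAGTGTGGCGT"
  ))
}

#' The high-affinity Cdc13 consensus binding site
#'
#' The 11-nt consensus `GTGTGGGTGTG` bound with high affinity by the
#' yeast telomeric ssDNA binding protein Cdc13; its first four
#' nucleotides (`GTGT`) are critical for binding.
#'
#' @return a single character string.
#' @export
cdc13Consensus <- function() "GTGTGGGTGTG"

#' Telomere model constants
#'
#' Constants used to interpret telomere-addition events: the yeast
#' telomeric repeat grammar (one or more `T` followed by 1-3 `G` on the
#' G-rich strand, see [isTelomericSeq()]), mean telomere lengths, and the
#' flanking-sequence sizes of the two chromosome V constructs.
#'
#' @param meanLengthWT mean telomere length in wild-type cells (bp).
#' @param meanLengthPif1 mean telomere length in pif1-deleted cells (bp).
#' @param flankBp flanking sequence in the CEB1 chromosome V construct (bp).
#' @param altFlankBp flanking sequence in the CEB25 construct (bp).
#' @return a list with class `"TelomereModel"`.
#' @examples
#' telomereModel()
#' @export
telomereModel <- function(meanLengthWT = 300, meanLengthPif1 = 400,
                          flankBp = 50, altFlankBp = 1800) {
  stopifnot(meanLengthWT > 0, meanLengthPif1 > 0, flankBp >= 0,
            altFlankBp >= 0)
  structure(list(meanLengthWT = meanLengthWT,
                 meanLengthPif1 = meanLengthPif1,
                 flankBp = flankBp, altFlankBp = altFlankBp),
            class = "TelomereModel")
}

## internal utilities ---------------------------------------------------

## Coerce to DNAString, uppercasing; reject anything outside {A,C,G,T}
## (including N): all metrics are exact-count based.
asDNAString <- function(x) {
  if (is(x, "DNAString")) x <- as.character(x)
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    x <- as.character(x[[1L]])
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  bad <- setdiff(unique(strsplit(x, "")[[1L]]), c("A", "C", "G", "T"))
  if (length(bad))
    stop("sequence contains characters outside {A,C,G,T}: ",
         paste(bad, collapse = ", "))
  Biostrings::DNAString(x)
}

## Character version of any accepted sequence input.
seqChar <- function(x) {
  if (is(x, "TandemArray")) return(as.character(arraySeq(x)))
  as.character(asDNAString(x))
}

## Integer percent, ties away from zero (76.9 -> 77; 0.5 -> 1).
pctRound <- function(frac) as.integer(floor(100 * frac + 0.5))

revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
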