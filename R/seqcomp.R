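## Sequence composition metrics: GC content, GC strand bias, and
## TG/GG/GT dinucleotide strand bias.

#' GC content of a sequence
#'
#' Fraction (#G + #C) / L on the given strand. Strand-symmetric:
#' identical for a sequence and its reverse complement.
#'
#' @param x sequence: character, [Biostrings::DNAString], or
#'   [TandemArray-class].
#' @return fraction in \[0, 1\].
#' @examples
#' gcContent(studyMotifs()[["CEB1"]])  # 30/39
#' @export
gcContent <- function(x) {
  s <- seqChar(x)
  if (nchar(s) == 0L) stop("empty sequence")
  n <- baseCounts(s)
  unname(n["G"] + n["C"]) / nchar(s)
}

#' GC strand bias of a sequence
#'
#' Fraction #G / (#G + #C) on the given strand: 0.5 for a strand-
#' symmetric sequence, 1 for a C-free G-rich strand. Complementary
#' strands satisfy `gcBias(s) + gcBias(revcomp(s)) == 1`.
#'
#' @inheritParams gcContent
#' @return fraction in \[0, 1\].
#' @examples
#' gcBias(studyMotifs()[["CEB25"]])  # 1: 29 G, no C
#' @export
gcBias <- function(x) {
  s <- seqChar(x)
  n <- baseCounts(s)
  if (n["G"] + n["C"] == 0) stop("undefined bias: no G or C")
  unname(n["G"] / (n["G"] + n["C"]))
}

#' TG/GG/GT dinucleotide strand bias
#'
#' Counts overlapping dinucleotides at positions 1..L-1 (linear, no
#' wraparound). The forward count is occurrences of TG, GG or GT on the
#' given strand -- the dinucleotides that can seed de novo telomere
#' addition; the reverse count is occurrences of CA, CC or AC on the
#' given strand, i.e. TG/GG/GT on the reverse complement. The bias is
#' forward / (forward + reverse); when neither strand carries a
#' qualifying dinucleotide the bias is undefined and returned as `NA`
#' (never 0 or 0.5).
#'
#' @inheritParams gcContent
#' @return a list with integer `forward` and `reverse` counts and the
#'   `bias` fraction (`NA` if undefined).
#' @examples
#' dinucBias(studyMotifs()[["CEB1"]])  # forward 20, reverse 3, bias 87%
#' @export
dinucBias <- function(x) {
  s <- seqChar(x)
  if (nchar(s) < 2L) stop("need at least 2 nt to count dinucleotides")
  d <- substring(s, seq_len(nchar(s) - 1L), 2:nchar(s))
  fwd <- sum(d %in% c("TG", "GG", "GT"))
  rev <- sum(d %in% c("CA", "CC", "AC"))
  bias <- if (fwd + rev == 0L) NA_real_ else fwd / (fwd + rev)
  list(forward = fwd, reverse = rev, bias = bias)
}

#' Full composition profile of a motif or tandem array
#'
#' Applies [gcContent()], [gcBias()] and [dinucBias()] to a sequence or
#' to the concatenated sequence of a [TandemArray-class]. For an
#' unmutated array the GC metrics equal the motif's; the dinucleotide
#' counts additionally pick up junction-spanning dinucleotides.
#'
#' @inheritParams gcContent
#' @return a one-row `data.frame` with columns `length`, `gc_content`,
#'   `gc_bias`, `dinuc_forward`, `dinuc_reverse`, `dinuc_bias` (unrounded
#'   fractions) plus the integer-percent display columns
#'   `gc_content_pct`, `gc_bias_pct`, `dinuc_bias_pct`.
#' @examples
#' compositionProfile(TandemArray(studyMotifs()[["CEB25"]], copies = 2))
#' @export
compositionProfile <- function(x) {
  s <- seqChar(x)
  gc <- gcContent(s)
  gb <- if (sum(baseCounts(s)[c("G", "C")]) > 0) gcBias(s) else NA_real_
  dn <- dinucBias(s)
  data.frame(
    length = nchar(s),
    gc_content = gc, gc_bias = gb,
    dinuc_forward = dn$forward, dinuc_reverse = dn$reverse,
    dinuc_bias = dn$bias,
    gc_content_pct = pctRound(gc),
    gc_bias_pct = if (is.na(gb)) NA_integer_ else pctRound(gb),
    dinuc_bias_pct = if (is.na(dn$bias)) NA_integer_ else pctRound(dn$bias)
  )
}

#' Composition table for a set of motifs
#'
#' @param motifs a named [Biostrings::DNAStringSet] (e.g. read with
#'   [readMotifFasta()]), or a named character vector.
#' @return a `data.frame`, one row per motif, with a `name` column
#'   followed by the [compositionProfile()] columns.
#' @examples
#' compositionTable(studyMotifs())
#' @export
compositionTable <- function(motifs) {
  if (is.character(motifs)) motifs <- Biostrings::DNAStringSet(motifs)
  nm <- names(motifs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(motifs))
  rows <- lapply(seq_along(motifs), function(i)
    compositionProfile(as.character(motifs[[i]])))
  cbind(name = nm, do.call(rbind, rows))
}

baseCounts <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  vapply(c(A = "A", C = "C", G = "G", T = "T"),
         function(b) sum(ch == b), integer(1))
}
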