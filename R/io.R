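## File-format plumbing: FASTA motifs/arrays/reads via Biostrings, and
## the tab-separated dialects used for minisatellite catalogs,
## chromosome-arm models and result tables. All TSV writers prepend a
## provenance header (tool version, date, seed and parameters) as `#`
## comment lines; all readers skip them. Coordinates are 1-based
## inclusive in files.

#' Read motifs, arrays or reads from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that validates
#' the alphabet (strictly A/C/G/T after uppercasing; metrics in this
#' package are exact-count based, so ambiguity codes are rejected).
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readMotifFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA: ", path)
  for (i in seq_along(x)) asDNAString(as.character(x[[i]]))  # validates
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write a result table as TSV with a provenance header
#'
#' @param df `data.frame` to write.
#' @param path output path.
#' @param seed seed recorded in the header (optional).
#' @param params named list of parameters recorded in the header.
#' @return invisibly, `path`.
#' @export
writeTsv <- function(df, path, seed = NULL, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("miniGCR"))
  writeLines(sprintf("# miniGCR %s", ver), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  for (nm in names(params))
    writeLines(sprintf("# %s: %s", nm,
                       paste(params[[nm]], collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minisatellite catalog TSV
#'
#' Reads the tab-separated catalog dialect used for genome-wide
#' tandem-repeat tables: one row per minisatellite with columns
#' `chrom`, `start`, `end` (1-based inclusive), `motif_size`,
#' `copy_number`, `array_length`, `gc_content`, `gc_bias`, optional
#' per-window G4 columns (`g4_w30` ... `g4_w100`, `g4_strand`) and an
#' optional `sequence` column. A header line is auto-detected; `#`
#' comment lines are skipped. A BED-like file (0-based half-open, no
#' header, columns chrom/start/end first) can be read with
#' `dialect = "bed"`; its coordinates are converted to 1-based
#' inclusive.
#'
#' @param path TSV path.
#' @param dialect `"catalog"` (default) or `"bed"`.
#' @return a catalog `data.frame`.
#' @export
readCatalogTsv <- function(path, dialect = c("catalog", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    d <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
    names(d)[1:3] <- c("chrom", "start", "end")
    d$start <- d$start + 1L   # 0-based half-open -> 1-based inclusive
    return(d)
  }
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")][1L]
  hasHeader <- grepl("chrom|start|motif", first, ignore.case = TRUE)
  d <- read.delim(path, header = hasHeader, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (!hasHeader)
    names(d)[seq_len(min(8L, ncol(d)))] <-
      c("chrom", "start", "end", "motif_size", "copy_number",
        "array_length", "gc_bias", "gc_content")[seq_len(min(8L, ncol(d)))]
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(d)))
    stop("catalog must contain columns: ", paste(need, collapse = ", "))
  d
}

#' Read a chromosome-arm model TSV
#'
#' Columns `chrom`, `arm`, `arm_start`, `arm_end`, `centromere_side`
#' (1-based inclusive coordinates; `centromere_side` in
#' `{"start", "end"}`). Alternatively the compact dialect `chrom`,
#' `p_start`, `p_end`, `centromere`, `q_end` is accepted and expanded
#' into the two arms (p arm centromeric at its end, q arm at its
#' start).
#'
#' @param path TSV path.
#' @return an arm-model `data.frame`.
#' @export
readArmModelTsv <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (all(c("chrom", "arm", "arm_start", "arm_end", "centromere_side")
          %in% names(d)))
    return(d)
  if (all(c("chrom", "p_start", "p_end", "centromere", "q_end")
          %in% names(d))) {
    return(do.call(rbind, lapply(seq_len(nrow(d)), function(i)
      data.frame(
        chrom = d$chrom[i], arm = c("p", "q"),
        arm_start = c(d$p_start[i], d$centromere[i] + 1),
        arm_end = c(d$p_end[i], d$q_end[i]),
        centromere_side = c("end", "start")))))
  }
  stop("unrecognised arm-model dialect")
}
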