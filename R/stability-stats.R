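## Hypothesis tests used throughout the study. All delegate to the
## exact/standard implementations in base R's stats package; the
## module's contribution is the study-specific surfaces (2x2
## rearrangement tables, position distributions, size-rate pairs,
## one-tailed terminal enrichment) and uniform TestResult reporting.

#' Two-tailed Fisher's exact test on a rearrangement table
#'
#' Exact hypergeometric two-sided p-value for a 2x2 table of
#' (rearranged, not rearranged) x (condition A, condition B), using the
#' point-probability rule (all tables with fixed margins whose
#' probability does not exceed the observed table's; no mid-p). The
#' p-value is symmetric under swapping rows or columns.
#'
#' @param tab 2x2 integer matrix, rows = conditions, columns =
#'   (rearranged, not rearranged); or a length-4 vector
#'   `c(a, b, c, d)` filled by row.
#' @return a list with `p_value`, `estimate` (odds ratio), `sidedness`,
#'   `method`.
#' @examples
#' ## WT untreated 3/192 vs Phen-DC3-treated 39/192
#' fisherRearrangement(c(3, 189, 39, 153))$p_value  # ~8.8e-10
#' @export
fisherRearrangement <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, nrow = 2, byrow = TRUE)
  stopifnot(dim(tab) == c(2L, 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin: test undefined, p = 1")
    return(list(p_value = 1, estimate = NA_real_, sidedness = "two",
                method = "Fisher's exact test (two-tailed)"))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(p_value = ft$p.value, estimate = unname(ft$estimate),
       sidedness = "two", method = "Fisher's exact test (two-tailed)")
}

#' Two-tailed Mann-Whitney-Wilcoxon test
#'
#' Used to compare distributions of telomere-addition positions (in
#' remaining-motif units) between conditions. Exact distribution when
#' both groups are small and untied; tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y numeric samples.
#' @return a list with `statistic` (U), `p_value`, `sidedness`,
#'   `method`.
#' @export
mannWhitneyPositions <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  hasTies <- anyDuplicated(c(x, y)) > 0L
  exact <- !hasTies && min(length(x), length(y)) <= 8L
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       sidedness = "two", method = "Mann-Whitney-Wilcoxon (two-tailed)")
}

#' Spearman rank correlation test
#'
#' Used for the motif-number versus GCR-rate relationship. Average
#' ranks for ties; exact null distribution for small untied samples,
#' t-approximation otherwise. A constant vector has no defined rank
#' correlation and returns `NA` with a flag.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return a list with `statistic` (rho), `p_value`, `sidedness`,
#'   `method`, and logical `flagged` (TRUE when rho is undefined).
#' @export
spearmanSizeRate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant vector: rho undefined")
    return(list(statistic = NA_real_, p_value = NA_real_,
                sidedness = "two", method = "Spearman rank correlation",
                flagged = TRUE))
  }
  hasTies <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman",
             exact = !hasTies && length(x) <= 9L))
  list(statistic = unname(ct$estimate), p_value = ct$p.value,
       sidedness = "two", method = "Spearman rank correlation",
       flagged = FALSE)
}

#' One-tailed chi-square test for terminal enrichment
#'
#' Tests whether `observed` of `total` trials exceed the expected
#' proportion `f` (1 df, no continuity correction). The one-tailed
#' p-value is half the two-tailed chi-square p when the observed count
#' exceeds expectation, and `1 - p_two/2` otherwise; an exactly
#' expected count gives p = 0.5.
#'
#' @param observed count of successes (e.g. minisatellites in the
#'   terminal fraction).
#' @param total number of trials (catalog size).
#' @param f expected proportion under the null.
#' @return a list with `statistic` (chi-square), `p_value` (one-tailed),
#'   `observed`, `expected`, `sidedness`, `method`.
#' @export
chisqTerminalOneTailed <- function(observed, total, f) {
  stopifnot(total > 0, observed >= 0, observed <= total, f > 0, f < 1)
  expected <- f * total
  chi2 <- if (observed == expected) 0 else
    suppressWarnings(
      chisq.test(c(observed, total - observed), p = c(f, 1 - f),
                 correct = FALSE)$statistic)
  pTwo <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p <- if (observed > expected) pTwo / 2 else 1 - pTwo / 2
  list(statistic = unname(chi2), p_value = unname(p),
       observed = observed, expected = expected,
       sidedness = "one", method = "one-tailed chi-square (1 df)")
}
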