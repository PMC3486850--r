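## Luria-Delbruck fluctuation analysis: Lea-Coulson method of the
## median, Falcor-style confidence intervals, fold changes, and a
## seeded simulator of the assay.

#' Lea-Coulson method-of-the-median estimate of m
#'
#' Solves `r0 / m - ln(m) = 1.24` for the expected number of mutation
#' events per culture `m`, where `r0` is the median resistant-colony
#' count, by bracketed root finding on `m` in (1e-6, 1e6) to a relative
#' tolerance of 1e-9. The median of an even number of cultures is the
#' midpoint of the two central order statistics. When the median count
#' is zero, `m = 0` is returned with the attribute
#' `flag = "no mutants observed"`.
#'
#' @param r non-negative integer resistant-colony counts, one per
#'   culture.
#' @return estimated `m` (numeric scalar, possibly with a `flag`
#'   attribute).
#' @examples
#' leaCoulsonM(c(1, 1.24, 2))        # median 1.24 -> m = 1
#' @export
leaCoulsonM <- function(r) {
  if (anyNA(r) || any(r < 0)) stop("counts must be non-negative")
  if (any(abs(r - round(r)) > 1e-9))
    warning("non-integer counts supplied; treating them as given")
  r0 <- median(r)
  if (r0 == 0)
    return(structure(0, flag = "no mutants observed"))
  f <- function(m) r0 / m - log(m) - 1.24
  uniroot(f, lower = 1e-6, upper = 1e6, tol = 1e-9 * max(1, r0))$root
}

#' Rate estimate with Falcor-style 95% confidence interval
#'
#' The per-generation rate is `M = m / Nt` with `m` from
#' [leaCoulsonM()]. The 95% confidence interval follows the
#' Rosche-Foster approximation used by the Falcor calculator:
#' `sigma_ln(m) = 1.225 * m^(-0.315) / sqrt(C)`, limits
#' `exp(ln(m) +/- 1.96 * sigma) / Nt`. With no mutants observed the
#' rate is 0 and only an upper limit is reported (from a single-culture
#' pseudo-count of one mutant at the median).
#'
#' @param x a [FluctuationExperiment-class].
#' @param ... unused.
#' @return a [RateEstimate-class].
#' @examples
#' fe <- FluctuationExperiment(r = c(0, 1, 1, 2, 3, 0, 1, 5, 2, 1),
#'                             Nt = 1e8)
#' estimateRate(fe)
#' @export
setMethod("estimateRate", "FluctuationExperiment", function(x, ...) {
  C <- length(x@r)
  m <- leaCoulsonM(x@r)
  flag <- attr(m, "flag")
  if (is.null(flag)) flag <- ""
  m <- as.numeric(m)
  if (m == 0) {
    ## one-sided upper bound: rate consistent with observing a zero
    ## median, taking m at the upper Lea-Coulson solution for r0 = 1
    mUp <- leaCoulsonM(rep(1, C))
    sig <- 1.225 * mUp^(-0.315) / sqrt(C)
    return(new("RateEstimate", m = 0, rate = 0, ciLow = 0,
               ciHigh = exp(log(mUp) + 1.96 * sig) / x@Nt,
               nCultures = as.integer(C), medianR = 0, label = x@label,
               flag = flag))
  }
  sig <- 1.225 * m^(-0.315) / sqrt(C)
  new("RateEstimate",
      m = m, rate = m / x@Nt,
      ciLow = exp(log(m) - 1.96 * sig) / x@Nt,
      ciHigh = exp(log(m) + 1.96 * sig) / x@Nt,
      nCultures = as.integer(C), medianR = as.numeric(median(x@r)),
      label = x@label, flag = flag)
})

#' Fold change between two rates
#'
#' Ratio of two per-generation rates, e.g. a minisatellite-bearing
#' strain over its no-minisatellite control. The unrounded ratio is
#' returned; `signif(x, 3)` gives the conventional 3-significant-figure
#' display.
#'
#' @param rateA,rateB rates in events per generation, or
#'   [RateEstimate-class] objects.
#' @return numeric ratio `rateA / rateB`.
#' @examples
#' foldChange(6.97e-7, 4.3e-10)  # ~1620: CEB1 over the hphMX control
#' @export
foldChange <- function(rateA, rateB) {
  if (is(rateA, "RateEstimate")) rateA <- rateM(rateA)
  if (is(rateB, "RateEstimate")) rateB <- rateM(rateB)
  if (rateB <= 0) stop("undefined fold: reference rate is zero")
  rateA / rateB
}

#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Per culture, the number of mutation events is Poisson with mean
#' `m = mu * Nt`; each event founds a clone whose final size is
#' `min(Nt, floor(1/u))` with `u ~ Uniform(0, 1)` -- the classical
#' heavy-tailed Luria-Delbruck clone-size law under exponential growth.
#' The resistant count of the culture is the sum of its clone sizes.
#' Deterministic under a fixed seed.
#'
#' @param mu mutation rate per cell per generation.
#' @param Nt final population size per culture.
#' @param C number of parallel cultures.
#' @param seed integer RNG seed.
#' @param label condition name.
#' @return a [FluctuationExperiment-class].
#' @examples
#' sim <- simulateLD(mu = 2e-8, Nt = 1e8, C = 50, seed = 1)
#' estimateRate(sim)
#' @export
simulateLD <- function(mu, Nt, C, seed = 1L, label = "simulated") {
  stopifnot(mu >= 0, mu < 1, Nt >= 1, C >= 1)
  withSeed(streamSeed(seed, "fluctuation"), {
    m <- mu * Nt
    k <- rpois(C, m)
    r <- vapply(k, function(ki) {
      if (ki == 0L) return(0)
      sum(pmin(Nt, floor(1 / runif(ki))))
    }, numeric(1))
  })
  suppressWarnings(
    FluctuationExperiment(r = r, Nt = Nt, label = label))
}

#' Read fluctuation-assay data from TSV
#'
#' One row per culture with columns `label`, `r`, `Nt` and optionally
#' `plating_fraction`. Lines starting with `#` are ignored. Returns one
#' [FluctuationExperiment-class] per label; per-culture `Nt` values are
#' averaged (with a warning if they differ).
#'
#' @param path TSV file path.
#' @return a named list of [FluctuationExperiment-class] objects.
#' @export
readFluctuationTsv <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "r", "Nt")
  if (!all(need %in% names(d)))
    stop("fluctuation TSV needs columns: ", paste(need, collapse = ", "))
  pf <- if ("plating_fraction" %in% names(d)) d$plating_fraction else
    rep(1, nrow(d))
  out <- lapply(split(seq_len(nrow(d)), d$label), function(idx) {
    NtVals <- d$Nt[idx] * pf[idx]
    Nt <- if (length(unique(NtVals)) > 1L) NtVals else NtVals[1L]
    suppressWarnings(
      FluctuationExperiment(r = d$r[idx], Nt = Nt,
                            label = d$label[idx][1L]))
  })
  out
}
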