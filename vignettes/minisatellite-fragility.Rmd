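---
title: "Minisatellite fragility analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minisatellite fragility analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miniGCR)
```

# Scope

`miniGCR` implements the computational layer of a minisatellite
fragility study in the yeast gross chromosomal rearrangement (GCR)
assay: sequence composition of GC-rich tandem repeats, prediction and
counting of G-quadruplex-forming sequences, Luria–Delbrück
fluctuation-assay rate estimation, the hypothesis tests applied to
rearrangement frequencies and telomere-addition positions, the
interpretation of array–telomere junctions, and positional statistics
of minisatellite catalogs along chromosome arms. This vignette explains
the models and their assumptions, the tunable parameters, the
synthetic-data generators, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# Sequence composition

Three metrics summarise a motif or array given as its G-rich strand
5'→3':

* **GC content**, (#G + #C)/L;
* **GC strand bias**, #G/(#G + #C), quantifying how asymmetrically the
  G and C are distributed between the two strands (1 means every G/C
  base is a G on the given strand);
* **TG/GG/GT dinucleotide bias**: overlapping dinucleotides are counted
  at positions 1..L−1, linearly, with no wraparound across the tandem
  junction. The forward count is occurrences of TG, GG or GT — the
  2-nt homologies to the yeast telomeric repeat that suffice to seed de
  novo telomere addition — and the reverse count is occurrences of CA,
  CC or AC (the same dinucleotides on the reverse complement). The bias
  is forward/(forward + reverse).

Linear (non-circular) counting is used because it is the natural
definition for a printed consensus motif; at the array level the
junction dinucleotides are captured automatically by profiling the
concatenated sequence, which is what `compositionProfile()` on a
`TandemArray` does. Display percentages round to the nearest integer
with ties away from zero (76.9 % → 77 %); unrounded fractions are
always returned alongside so downstream code never consumes a rounded
value. Undefined quantities — GC bias of an AT-only sequence, the
dinucleotide bias when neither strand has a qualifying dinucleotide —
are errors or flagged `NA`, never silently 0 or 0.5. Input is
uppercased; characters outside A/C/G/T, including ambiguity codes, are
rejected, because every metric is an exact count.

# The G-quadruplex scanner

A G-quadruplex-forming sequence is modelled, as in the genome-wide
minisatellite annotation this package mirrors, as `nTracts = 4` maximal
runs of at least `tractMinG = 3` consecutive G within a window of at
most `windowMax = 30` nt, with a minimal loop of `loopMin = 1` nt
between consecutive tracts. The maximal loop length is **derived**, not
set: `windowMax − nTracts·tractMinG − (nTracts−1)·loopMin + loopMin`,
which is 16 nt at the defaults. Catalog annotation repeats the scan at
windows of 30, 40, 50 and 100 nt; counts are necessarily non-decreasing
in the window.

Three rules pin down corner cases:

* **Tracts are maximal G-runs.** A run of 6 G is one tract, never two
  tracts of 3 (splitting would create a zero-length loop, excluded by
  `loopMin = 1`).
* **The window test uses the tightest qualifying span**: when a
  boundary tract is longer than 3 G, only the trailing (first tract) or
  leading (last tract) 3 G need to fit in the window. Without this
  rule, a motif prefixed by a long G-run would be disqualified even
  though it contains a sequence identical to a qualifying one. The
  reported hit interval still covers the full maximal tracts.
* **Greedy non-overlapping counting**: hits are taken leftmost-first
  and the scan resumes strictly after the last tract of a hit, so a
  G-run consumed by one hit cannot seed the next. Because candidate
  windows built from consecutive tracts have ends that increase with
  their starts, this greedy count equals the maximum number of pairwise
  disjoint valid windows; the test suite verifies this against a
  brute-force dynamic-programming oracle on hundreds of random and
  tandem sequences.

On the study motifs this yields the expected structure: HRAS1 has a
single qualifying G-tract and can never form a quadruplex; a CEB25
monomer contains one G4-forming sequence and an array of k copies
contains k (a "pearl-necklace"); a CEB1 monomer contains none — its
four G-tracts span 35 nt with an 18-nt loop — but every junction
between two CEB1 copies brings four tracts within 21 nt, so a k-copy
array counts k − 1.

Coordinates are 1-based inclusive throughout the R interface (the
convention of tandem-repeat tables); file writers keep that convention,
and the BED-dialect reader converts from 0-based half-open.

# Fluctuation analysis

The GCR rate is estimated from parallel cultures by the Lea–Coulson
method of the median: with r₀ the median number of resistant colonies
per culture, the expected number of mutation events per culture m
solves r₀/m − ln m = 1.24. The root is found by bracketed bisection
(`uniroot`) on m ∈ (10⁻⁶, 10⁶) to a relative tolerance of 10⁻⁹; the
equation's left side is strictly decreasing in m, so the root is unique
and the estimator strictly increasing in r₀. The rate per generation is
M = m/Nt, with Nt the viable cells per culture, taken as a single
per-experiment value (a vector of per-culture counts is averaged with a
warning, matching how the assay reports a common plating count); a
plating fraction multiplies Nt rather than entering the estimator. The
95 % confidence interval follows the Rosche–Foster approximation used
by the Falcor calculator: σ_ln m = 1.225·m^(−0.315)/√C and limits
exp(ln m ± 1.96 σ)/Nt. This CI formula is a convention adopted
explicitly, since the study names only the tool it used. A median of
zero returns m = 0 with a flag and a one-sided upper limit. No
maximum-likelihood (MSS) estimator, differential-fitness or
phenotypic-lag correction is provided: the median method is the one the
assay used, and those refinements are out of scope.

The simulator draws, per culture, a Poisson(m) number of mutation
events and gives each event a descendant clone of size
min(Nt, ⌊1/u⌋), u ~ Uniform(0,1) — the classical heavy-tailed
Luria–Delbrück clone-size law under exponential growth (a mutation
arising when the population has size Nt·u leaves ≈ 1/u descendants).
It reproduces the two signatures the tests assert: a Poisson zero class
P(r = 0) = e^(−m), and a variance far exceeding the mean. It does not
model plating efficiency, death, or post-plating growth.

Fold changes are plain ratios of rates. Published fold inductions were
computed from unrounded rates, so ratios of printed (rounded) rates can
differ from printed folds by a few percent; `foldChange()` therefore
returns the unrounded ratio and leaves display rounding to the caller.

# Hypothesis tests

The study's four tests are exposed with study-shaped interfaces and
delegate to the exact implementations in base R: two-tailed Fisher's
exact test with the point-probability rule (`fisher.test`; the suite
cross-checks it against a full enumeration over all tables with the
observed margins), two-tailed Mann–Whitney–Wilcoxon with exact small-
sample distribution and tie-corrected normal approximation otherwise,
Spearman correlation with average ranks and exact small-n null, and a
one-tailed χ² (1 df, no continuity correction) for terminal enrichment
whose one-tailed p is half the two-tailed p in the enrichment
direction and 1 − p/2 otherwise, giving p = 0.5 at exact expectation.
The choice of the point-probability rule for the two-sided Fisher test
is verifiable: it reproduces the printed 3.55×10⁻³ for the 3/192 vs
16/192 comparison, which the doubled-one-tail rule does not.

Type-I calibration of the two rank tests is checked at n = 8 per group
over 2,000 null replicates. n = 8 was chosen because the exact null
distributions there are fine-grained enough (8! rank permutations) that
test discreteness does not depress the achievable level below the
0.04–0.06 band being asserted; much smaller n would make any exact test
conservative by construction.

# Junction analysis

The yeast telomeric repeat on the G-rich strand is irregular; it is
modelled by the minimal grammar (T G₁₋₃)⁺ — one or more repeats of a T
followed by one to three G. Whole-string acceptance requires complete
repeats; suffix parsing at junctions additionally allows a partial
leading repeat (up to three bare G, the tail of a repeat cut by the
junction) and a trailing bare T. The grammar is a deliberate
simplification: real TG₁₋₃ tracts show longer-range irregularities the
package does not model.

A junction read is an array-templated prefix followed by a telomeric
suffix. `annotateJunction()` reports the junction at the end of the
maximal motif-templated prefix — the **rightmost** motif-compatible
position, resolving the inherent ambiguity in the direction that
mirrors how shared nucleotides are conventionally drawn as belonging to
both sequences — and the shared span as the maximal interval whose
nucleotides simultaneously extend the motif and parse under the
grammar. The prefix match tolerates `maxMismatches` mismatches
(default 0) so that reads carrying SNVs near the junction can still be
indexed; mismatches in a 30-nt window before the junction are reported
as candidate SNVs, and `supportedSNVs()` applies the ≥ 3 supporting
reads rule across a read set. The G-quadruplex-forming region of the
CEB1 motif is a configuration value, not a constant, defaulting to
nt 1–17 — the G-rich 5' block, the unique contiguous choice consistent
with 12 of the 20 telomere-seed dinucleotides (60 %) overlapping it.

Telomere-addition positions measured on Southern blots are converted to
remaining motif counts by (fragment − flank − mean telomere)/motif
length, with the construct constants held in `telomereModel()`:
50 bp flank and 300 bp mean telomere in wild-type (400 bp without
Pif1), 1.8 kb flank for the CEB25 construct. The Cdc13 site search has
an exact mode (the 11-mer GTGTGGGTGTG) and a relaxed
`critical_prefix` mode (GTGT starting an 11-nt window with ≥ 9 of 11
bases in {T,G}), because the count of "Cdc13 binding sites" in a
tandem context depends on whether near-consensus and junction-spanning
sites are admitted; providing both modes makes that criterion explicit
rather than baked in.

# Catalog statistics

Records are placed on a normalised arm coordinate (centromere 0,
telomere 1) by their midpoint; a record whose midpoint falls outside
every annotated arm is excluded with a warning rather than guessed.
GC-rich means strictly > 50 % GC. Terminal enrichment compares the
count beyond 1 − f with f·n by the one-tailed χ²; records are assigned
to the terminal bin by midpoint. Duplicate elimination keeps, among
same-chromosome overlapping records with the same motif size, the one
with the longest array (ties: leftmost) — one defensible reading of
"overlapping duplicates eliminated", isolated in `dedupCatalog()` so a
different rule can be swapped in; overlapping records with different
motif sizes are distinct repeats and are kept.

The published genome-wide numbers for the hg19 catalog (353,460
minisatellites, 85,222 GC-rich, 18,906 with a G4-forming sequence, 504
with ≥ 30, of which 313 terminal) require the hg19 assembly and the
original Tandem Repeat Finder run; they are intentionally not
reproduced. The package's responsibility is the catalog dialect parsers
and the statistics, exercised on synthetic catalogs with known truth.

# Synthetic data

Every generator is a pure function of its parameters and a seed, and
each derives an independent stream from (seed, generator name), so
adding a generator never shifts another's output.

* `genCatalog()` draws arm positions from the density ∝ 1 + βx on
  [0, 1] (β = 0 uniform; the terminal-f mass has the closed form
  `terminalMassBeta()`, used by the recovery tests). The linear density
  was chosen precisely because its integrals are closed-form; the
  empirical shape of the real terminal bias is unknown and not claimed.
  GC content is a two-component truncated-normal mixture (24 % GC-rich
  by default, matching the published GC-rich share of the catalog), and
  G4 counts are Poisson with a class-dependent mean.
* `genArray()` concatenates motif copies with independent per-base
  point mutations and records the mutated positions as truth.
* `genJunctionReads()` cuts an array at a breakpoint and appends a
  TG₁₋₃ tract whose length is normal around 300 bp (SD 75 bp, the
  wild-type telomere-size dispersion scale); the truth columns record
  the breakpoint and the analytically derived junction index and
  shared span, computed from the definitions at generation time, so
  recovery tests never re-derive randomness.
* `genFluctuation()` wraps the Luria–Delbrück simulator.

What passing tests on these generators shows — and does not show: the
analysis code is exact on inputs that obey the stated models (tandem
arrays with point variation, clean junction reads, catalogs with
linear positional bias). Real sequencing reads with indels, real
telomere irregularity, and real catalog artefacts are outside the
generators' vocabulary, and no claim is made about them.

# Problem sizes and numerical choices

The test suite and acceptance script use problem sizes chosen to give
stable statistics in seconds to a couple of minutes on one CPU: 1,000
random sequences for the dinucleotide oracle, 500 sequences up to 2 kb
for the G4 scanner oracle, 200 simulated experiments of 50 cultures
(plus one 10,000-culture run for the zero class) for estimator
recovery, 500 uniform catalogs of 400 records for enrichment
calibration, 2,000 null replicates for rank-test calibration, and
1,000 junction reads for the round-trip. Root finding tolerances,
rounding rules and tie-breaks are stated where each function is
documented.

# Known limitations

* The Lea–Coulson median estimator is less efficient than MSS maximum
  likelihood and has no plating-efficiency correction.
* The TG₁₋₃ grammar is a minimal model of yeast telomeric irregularity.
* The terminal-bias density of real minisatellite catalogs is not
  linear; β is a test dial, not a biological estimate.
* Junction annotation assumes reads start in phase with the motif
  (configurable via `phase`) and handles substitutions but not indels.
* Genome-wide hg19 counts are not desk-reproducible (no genome
  download, no Tandem Repeat Finder re-run).
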