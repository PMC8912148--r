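---
title: "Dual-marker diet metabarcoding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-marker diet metabarcoding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietbarcoder)
```

`dietbarcoder` turns paired-end *rbcL* and ITS2 amplicon reads from
fecal samples into per-sample food-plant taxon sets and
incidence-based diversity summaries. This vignette explains the
models behind each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design
decisions that were genuinely open.

## The read-processing model

Reads are truncated positionally (forward 200 nt, reverse 250 nt, the
lengths chosen from mate-specific quality profiles in the protocol
this pipeline follows) and pairs shorter than their target are
discarded. Merging reverse-complements the reverse mate and takes the
*largest* overlap of at least 12 nt with at most 0 mismatches;
failures are counted, not fatal. On an overlap conflict (only
possible when mismatches are tolerated) the forward base is kept — a
safe rule here because the generator emits flat quality strings, so
there is no quality evidence to prefer either mate.

Denoising is deliberately simpler than a learned-error-model ASV
algorithm, but preserves its defining property: single-nucleotide
resolution. A unique sequence is absorbed into another unique of the
same length at Hamming distance ≤ 1 only when the neighbour is at
least `parent_ratio = 10` times more abundant, iterated to a fixed
point (smallest sequences considered first; the largest admissible
parent wins, ties broken lexicographically). A genuine one-base
variant at comparable abundance therefore survives as its own ASV,
while the cloud of singleton error reads around a true template is
absorbed. Reads with two or more errors are left as singletons by
design — they fall to the 1 % relative-abundance filter, which is the
stage actually responsible for cleaning the low-frequency tail.

Bimera removal implements the two-parent chimera model directly: an
ASV is removed when two distinct ASVs, each at least twice as
abundant, can be spliced at a breakpoint at least 20 nt from both
ends to reproduce it exactly. The 2× parent ratio and the 20 nt
flanks are the conventional de novo settings; exact matching is
appropriate because candidates are compared *after* denoising.

Rarefaction draws exactly 1,000 reads per sample and marker without
replacement (`vegan::rrarefy`, seeded). Samples that cannot reach the
depth at either marker are excluded entirely by default
(`require_both_markers`), mirroring the rule that only samples
amplifying at both loci are analyzed; the pipeline does not attempt
to rescue single-marker samples, though the switch is exposed.

## The assignment model

Each ASV is aligned against every reference by affine-gap local
(Smith–Waterman) alignment on both strands, via
`Biostrings::pairwiseAlignment`. Scoring is the classic nucleotide
scheme (match +2, mismatch −3, a gap of length *k* costing 5 + 2*k*),
and raw scores are converted to bitscores with λ = 0.625, K = 0.41 so
that the familiar 300-bit threshold keeps its conventional meaning.
Hits need ≥ 98 % identity *and* ≥ 300 bits; identity is measured over
the optimal local alignment's columns (the span convention), not over
the full query.

Arbitration between databases is the part of the design that was
genuinely open, and three decisions deserve explicit notes here:

* **"Homology score" is operationalized as bitscore, identity as
  tie-break.** The two filters pair an identity with a bitscore;
  between alignments of unequal length only the bitscore compares
  fairly, while identity arbitrates between equal-score hits.
* **The flora restriction is applied to global hits before best-hit
  selection, not after.** Otherwise a non-flora top hit would mask a
  valid flora hit of slightly lower score and the ASV would be lost
  entirely rather than assigned to the regional species.
* **Full ties go to the local database.** The curated regional
  database is the higher-trust source; this also makes assignments
  sourced `local` invariant to deleting the global database (a
  property the tests check).

Equal-score candidate sets collapse to their lowest common ancestor
in a strict three-level taxonomy (family → genus → species;
infraspecific epithets live inside the species string). Groups of
congeners with identical barcodes therefore surface as genus-rank
calls, confamilial ties as family-rank calls, and cross-family ties
as "unresolved". Per sample, the two markers' sets are merged by
union, after which any taxon that is a strict ancestor of another
retained taxon is dropped — one marker's family-level call gives way
to the other's species-level call. Unresolved entries are dropped
whenever any resolved taxon remains in the merged set; the operation
receives plain taxon sets, so a finer per-ASV pairing of unresolved
evidence is out of reach at this interface and the coarser rule is
the documented behaviour. Ancestor removal applies within one
sample's merged set only; a study-level table may legitimately
contain both a genus-rank group and congeneric species detected in
other samples.

## Incidence statistics

All diversity statistics work on incidence frequencies Y_i (number of
sampling units containing taxon *i*), with T units, U = ΣY_i total
incidences, and Q1/Q2 the taxa seen in exactly one/two units.

* Sample coverage: Ĉ = 1 − (Q1/U)·[(T−1)Q1/((T−1)Q1 + 2Q2)], the
  Chao incidence-data estimator; Ĉ = 1 when Q1 = 0.
* Observed Hill–Shannon diversity: exp of the Shannon entropy of
  Y_i/U — an effective number of equally frequent taxa.
* Asymptotic Hill–Shannon: the Chao–Jost incidence estimator (see
  `?hill_shannon_asym` for the exact form). Note that with Q1 = Q2 =
  0 the unseen-taxon correction vanishes but the entropy term remains
  bias-corrected, so the estimate equals the observed value only in
  the saturated case (every taxon in every unit).
* Sample-based rarefaction: the exact hypergeometric expectation
  E[S_t] = Σ_i [1 − C(T−Y_i, t)/C(T, t)]; extrapolation beyond T is
  intentionally not implemented.

Report tables round percentages half-up to one decimal; computations
are always done unrounded and rounding is applied only at the report
boundary.

The bundled fixture `diet_incidence_fixture()` carries the published
per-period detection counts of 53 food-plant taxa over 105 fecal
samples; the acceptance checks reproduce all six printed coverage
percentages and the printed Shannon diversities from it. One printed
row total is internally inconsistent with its period counts; the
fixture keeps the period counts, recomputes totals, and flags the row
in an attribute rather than silently repairing it.

For comparing per-sample taxon counts across assignment schemes the
package provides the asymptotic Steel–Dwass all-pairs test: pooled
mid-ranks per pair, tie-corrected variance, and the studentized range
with infinite degrees of freedom as reference
(`stats::ptukey(sqrt(2)|z|, k, Inf)`). A label-permutation oracle
(max-statistic null distribution) validates it: at a dozen
observations per group the suite checks agreement to within 0.02 in
p. At very small group sizes the asymptotic approximation degrades,
as asymptotic rank tests generally do — the test is meant for
moderate group sizes.

## What the generator emulates — and what it does not

`sim_config()` defines a synthetic study whose defaults are the
conditions exercised throughout the tests: a 20-species flora in 8
genera and 4 families; amplicons of 420 nt (*rbcL*) and 350 nt
(ITS2); 5 % interspecific divergence (congeners sit near 95 %
identity, safely below the 98 % admission threshold); two
identical-sequence species groups per marker, each occupying its own
genus; five non-flora distractor species present only in the global
database; 5,000 read pairs per sample and marker; a 0.2 % per-base
substitution error; 5 % chimeric reads spliced at a uniform interior
breakpoint (≥ 20 nt from either end, matching the detector's
validity region); and 2 % contaminant reads from non-flora taxa.

Sequence evolution is the simplest model that controls identity
levels: one random ancestor per genus and marker, species derived by
i.i.d. substitutions at half the divergence, and no indels by
default, so identity thresholds are exercised without alignment-gap
interactions. A 420 nt *rbcL* amplicon is used rather than a longer
one because the fixed 200 + 250 truncation must leave at least the
12 nt merge overlap; longer amplicons would make merging impossible
by construction, not by data quality. Quality strings are constant
(Q37) because trimming is positional.

Deliberately not modelled: PCR amplification bias, instrument error
spectra and quality decay along the read, indel errors, length
variation between congeners, and multi-copy ITS2 heterogeneity
within a species. Passing the end-to-end tests therefore shows the
pipeline's logic is correct under substitution noise, chimeras and
contamination at realistic rates — it does not certify performance
against real MiSeq error structure, which is the usual gap any
simulation-based validation leaves.

Every read carries its source label and chimera flag, so end-to-end
recovery is scored exactly: each truth species at ≥ 5 % of a sample's
mixture must be recovered at species rank when its sequences are
unique, and at its genus when it belongs to an identical-sequence
group; non-flora taxa must never be called at species rank from the
global database.

## Numerical and degenerate-input conventions

* ASV tables are canonically ordered (count descending, sequence
  lexicographic), making every stage invariant to input read order.
* Denoiser ties: largest parent, then lexicographically smaller
  sequence.
* Bitscore comparisons use an absolute 1e−9 tolerance; threshold
  boundaries are inclusive (identity 98.0 and 300 bits are kept).
* Empty merged read sets, empty compositions, empty taxon groups and
  zero-incidence vectors raise errors; merge failures, truncation
  discards and sub-depth samples are counted outcomes.
* All randomness flows from explicit integer seeds: the generator
  from `sim_config(seed)`, rarefaction from `run_config(seed)` (one
  derived seed per sample), the permutation oracle from its own
  argument.

## Problem sizes used by the test-suite

The suite validates against printed values on the bundled 53 × 5
fixture (instantaneous); the end-to-end noisy study uses 6 samples ×
2 markers × 5,000 read pairs (about a minute); the Steel–Dwass
permutation oracle uses 100,000 draws and the null calibration 2,000
simulated datasets of 3 × 20 counts; Monte-Carlo rarefaction checks
use 4,000–10,000 resamples. These sizes give Monte-Carlo standard
errors comfortably inside the asserted tolerances while keeping a
full run of the suite within a few minutes.

## Known limitations

* The three-level taxonomy has no ranks between family and genus or
  below species; infraspecific names are opaque strings.
* The global database is a bundled FASTA, not a live service; no
  taxonomy synonym resolution is attempted.
* The denoiser is not a statistical error model; abundance-ratio
  absorption can in principle swallow a genuine variant rarer than
  one tenth of its neighbour.
* Asymptotic Steel–Dwass p-values are unreliable below ~8
  observations per group; use the permutation reference there.
* Extrapolated rarefaction/coverage curves (beyond the observed
  number of sampling units) are out of scope.
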