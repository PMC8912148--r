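# dietbarcoder

Herbivore diets can be read from feces: chloroplast *rbcL* and nuclear
ITS2 amplicons surviving digestion are sequenced, denoised into exact
sequence variants, and matched against reference databases of the
plants growing where the animal lives. `dietbarcoder` implements that
workflow end to end for dual-marker, dual-database designs — the
setting where a small curated *local* database of regional plants is
used alongside a large *global* (NCBI-style) database — together with
the incidence-based statistics used to judge how completely a fecal
survey has sampled the available food plants. It is aimed at
molecular ecologists running plant-diet metabarcoding studies, and at
methodologists who want a fully seeded synthetic testbed for such
pipelines.

## What it computes

**Read processing.** Paired reads are truncated to fixed lengths
(forward 200 nt, reverse 250 nt), merged on their overlap, and
dereplicated. Denoising uses an abundance-ratio rule with
single-nucleotide resolution: a unique sequence is absorbed into a
Hamming-distance-1 neighbour only when that neighbour is at least 10×
more abundant. Two-parent chimeras (bimeras) are removed by exact
prefix/suffix splicing against more abundant variants, low-frequency
ASVs (< 1 % of the sample) are discarded, and each sample × marker
table is rarefied to 1,000 reads (multivariate hypergeometric,
seeded).

**Taxonomic assignment.** Each ASV is aligned (affine-gap
Smith–Waterman, both strands) against the local and global databases.
Hits need ≥ 98 % identity and ≥ 300 bits, with the bitscore
B = (λS − ln K)/ln 2 under standard nucleotide scoring (match +2,
mismatch −3, gap 5 + 2k; λ = 0.625, K = 0.41). Global hits are first
restricted to a regional flora list; the best local and global hits
are then compared by bitscore (identity as tie-break, local database
wins full ties). Equal-score ties collapse to their lowest common
ancestor, so species sharing an identical barcode are called at genus
or family. Finally the two markers' per-sample calls are merged at
the lowest resolved rank.

**Diversity statistics.** From per-sample taxon sets the package
builds sample × taxon incidence matrices and computes, per collection
period: detection frequencies 100·Y_i/T; the incidence-based Chao
sample coverage Ĉ = 1 − (Q1/U)·[(T−1)Q1/((T−1)Q1 + 2Q2)]; observed
Hill–Shannon diversity exp(−Σ p_i ln p_i) with p_i = Y_i/U; the
Chao–Jost asymptotic Hill–Shannon estimator; and exact hypergeometric
sample-based rarefaction. Per-sample taxon counts across assignment
schemes are compared with the asymptotic Steel–Dwass all-pairs test
(studentized-range reference, mid-ranks, tie-corrected variance),
validated against a permutation oracle.

**Synthetic studies.** `sim_config()` / `simulate_study()` generate a
seeded flora, local and global databases with engineered
identical-sequence species groups and non-flora distractors, and
per-sample paired reads with substitution errors, chimeras and
contaminants — every read labelled with its true source, so recovery
can be scored exactly.

## Worked example

The package bundles the per-period detection counts of the 53 food
plant taxa found in 105 ptarmigan fecal samples from an alpine study
area (five collection periods, July–October):

```r
library(dietbarcoder)
tab <- diet_incidence_fixture()
ns  <- attr(tab, "n_samples")
diversity_summary(as.matrix(tab[, names(ns)]), ns)
#>      period n_samples richness shannon_obs shannon_est coverage_pct
#> 1 jul_early        31       31        16.6        20.1         90.9
#> 2  jul_late        18       23        15.2        21.0         87.0
#> 3       aug        31       36        20.6        25.7         90.7
#> 4       sep        17       15        11.6        12.8         97.5
#> 5       oct         8       16        12.1        14.4         89.5
#> 6     Total       105       53        23.1        25.0         96.4
```

Coverage above 96 % for the pooled data says the survey detected
nearly all food-plant taxa available in the area; the asymptotic
Shannon diversity (an effective number of taxa) shows the July–August
diet was roughly twice as diverse as the September–October one. The
dominant food plants and the identification accuracy:

```r
freq <- detection_frequency(tab$total, n_units = sum(ns))
names(freq) <- tab$taxon
head(sort(freq, decreasing = TRUE), 5)
#> Vaccinium ovalifolium var. ovalifolium         Empetrum nigrum var. japonicum
#>                                   69.5                                   68.6
#>                      Kalmia procumbens                     Tilingia ajanensis
#>                                   42.9                                   34.3
#>    Vaccinium uliginosum var. japonicum
#>                                   34.3

rank_summary(tab$rank)
#>         rank  n  pct
#> 1    species 49 92.5
#> 2      genus  3  5.7
#> 3     family  1  1.9
#> 4 unresolved  0  0.0
```

A fully synthetic study, processed end to end:

```r
cfg   <- sim_config(per_sample_depth = 2000, seed = 1)
study <- simulate_study(cfg, n_samples = 3)
res   <- run_pipeline(study, run_config(rarefy_depth = 500, seed = 1))
head(res$assignments[, c("sample", "marker", "count", "species",
                         "genus", "rank", "source", "identity")])
#>   sample marker count           species   genus    rank source identity
#> 1    S01   rbcL   223                   Genus01   genus  local      100
#> 2    S01   rbcL   122                   Genus02   genus  local      100
#> 3    S01   rbcL    91 Genus04 species01 Genus04 species  local      100
#> 4    S01   rbcL    37 Genus03 species02 Genus03 species  local      100
#> 5    S01   rbcL    27 Genus04 species02 Genus04 species  local      100
#> 6    S01   ITS2   213                   Genus01   genus  local      100
score_recovery(res, study)$recovery_rate
#> [1] 1
```

Species in the two engineered identical-sequence groups (`Genus01`,
`Genus02`) are called at genus rank — exactly what shared barcodes
force — and every major diet component with a unique sequence is
recovered at species rank.

A thin command-line front end over the same functions lives at
`inst/cli/dietbarcoder.R` (`simulate`, `run` and `diversity`
subcommands).

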