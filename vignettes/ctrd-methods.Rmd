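---
title: "Quantifying co-translational mRNA decay from 5'P degradome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying co-translational mRNA decay from 5'P degradome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrdseq)
```

## The model

5'Pseq sequences 5'-monophosphate mRNA fragments, the intermediates of
5'→3' exonucleolytic decay. When decay is co-translational, the
exoribonuclease advances behind the last translating ribosome and its
stall positions inherit the ribosome's geometry: 5'P ends fall
preferentially on one position per codon (a 3-nt lattice over the CDS),
and they pile up where the ribosome dwells longest — at termination,
which places the protected boundary 16–17 nt upstream of the first
stop-codon nucleotide. `ctrdseq` treats these two signatures as the
observable of interest and everything else (library size, positional
background) as nuisance.

Throughout, coordinates are 1-based and closed, transcript position 1 is
the 5'-most nucleotide of the mature mRNA on its own strand, and relative
position r = 0 is the **first nucleotide of the stop codon**; "16–17 nt
upstream" therefore means r ∈ {−17, −16}. A read's biological 5' end is
the leftmost aligned base for plus-strand alignments and the rightmost
for minus-strand ones. When a 5' end falls in exons of several
same-strand isoforms, every isoform is incremented — the TSI is a ratio
within one transcript, so double counting cancels; users wanting
single-isoform counts should pre-filter their models to one isoform per
gene before counting.

## The Terminational Stalling Index

For one transcript in one library,

$$\mathrm{TSI} \;=\; \frac{\sum_{r \in \{-17,-16\}} c_r}
{\overline{c}_{\mathrm{flank}}},\qquad
\mathrm{flank} = [-67,-18] \cup [-15,+34],$$

where $c_r$ is the 5'P end count at relative position $r$ and the flank
mean is per position over its 100 positions. Two deliberate conventions:

* **Boundary sum over flank mean.** The definition reads as "the number
  of ends at the boundary" against "the mean number of ends in the
  flank", and we take it literally. Consequence: uniform data has an
  expected TSI of 2 (two boundary positions each matching the flank's
  per-position mean). The target threshold of 3 is therefore 1.5× the
  uniform background, not 3×. `tsi_params(boundary_stat = "mean")`
  switches to a mean/mean ratio for users who prefer TSI = 1 background.
* **Flank geometry.** "Flanking 100 nt" is implemented as 50 positions
  on each side of the boundary, excluding the boundary itself (and hence
  the positions it separates, −15 to −18 are split across the two flank
  arms). A symmetric two-sided flank avoids loading the index with the
  3'UTR-only or CDS-only background, and excluding the boundary keeps
  numerator and denominator disjoint. Other geometries are reachable
  through `tsi_params()`.

Records are undefined (NA, never an exception) when the flank mean is 0,
when the transcript carries fewer than `min_total_reads = 10` reads, when
the full window does not fit inside the transcript (transcripts with a
3'UTR shorter than 34 nt are excluded by default for cross-genotype
comparability; `truncate_flank = TRUE` averages over the available
positions instead), or when the annotated CDS length is not a multiple
of 3. No pseudocounts are used anywhere: undefined values are excluded,
not imputed.

Replicates are aggregated per genotype as the mean over defined TSIs,
requiring at least two defined replicates. Target rules follow the
published thresholds: reference mean TSI **strictly** greater than 3
defines transcripts under active CTRD; among those, reference/mutant mean
TSI ≥ 2 calls a mutant target (mutant mean 0 ⇒ infinite fold, called; NA
⇒ call flagged NA). Fold changes use genotype mean TSI rather than
per-replicate calls — the replicate means are what the distributions in a
three-replicate design estimate — and a per-replicate view is available
by running the caller on single-library "genotypes".

## Statistics around the index

* **Distribution shifts**: Wilcoxon, paired by default on the common
  transcript set (the same transcripts are measured in every genotype;
  pairing removes the large between-transcript variance). Zero
  differences are dropped; exact null for n ≤ 25 without ties, normal
  approximation with continuity correction otherwise; two-sided.
* **Set overlaps**: upper-tail hypergeometric,
  $p = P(X \ge k)$, $X \sim \mathrm{Hyper}(N, |A|, |B|)$. When an
  analysis intersects the TSI table with an external list (e.g. an
  independently determined NAD⁺-capped set), the default universe is the
  intersected list itself, since that is the population actually scored;
  any other universe can be passed explicitly.
* **Half-lives**: per replicate, ordinary least squares on
  $\ln A(t) = \ln A_0 - \lambda t$ over the time grid (0, 30, 60, 120 min
  by default), $t_{1/2} = \ln 2/\lambda$, summarised as mean ± SD across
  replicates and compared between treatments with Welch's t-test.
  Log-linear least squares is the stable, convention-standard choice for
  4 time points × 3 replicates; fitting per replicate and then averaging
  (rather than pooling points) keeps the replicate as the unit of
  biological variation, which is also what the t-test consumes.
  Non-positive abundances are dropped with a warning; replicates with
  fewer than 3 usable points, or a non-positive fitted rate
  ("non-decaying"), have undefined half-lives. R² is computed directly
  from residuals, with noiseless input recovered exactly.
* **Replicate concordance**: PCA of the log-scaled, centred count or TSI
  matrix (top two axes with variance explained), as a quick structural
  check that replicates cluster by genotype and organ.

## The synthetic degradome generator

`sim_config()` fixes the study conditions the tests run under; its
defaults are the generator's statement of "realistic":

| parameter | default | meaning |
|---|---|---|
| `n_transcripts` | 500 | transcripts per simulated annotation |
| `cds_length_range` | 300–1500 nt | uniform, rounded to codons |
| `utr5_length`, `utr3_length` | 50, 60 nt | fixed UTRs; 3'UTR ≥ 40 nt is enforced so the TSI window always fits |
| `expression_mean` | 500 reads | per transcript per library; log-normal across transcripts (`sdlog` 0.5) |
| `ctrd_fraction` (φ) | 0.4 | share of 5'P ends from the ribosome-tracked component |
| `stall_weight` (s) | 10 | termination dwell in units of one elongation step |
| `frame_bias` | 0.8 | concentration of tracked ends on the codon lattice |
| `dispersion` | 20 | negative-binomial size for library totals |
| `n_replicates` | 3 | biological replicates per genotype |

Per transcript the positional law is
$(1-\varphi)\,\mathrm{Uniform}(L) + \varphi\, w$, where $w$ mixes a
uniform-over-CDS floor (weight $1-\mathrm{frame\_bias}$) with the codon
lattice (weight `frame_bias`) and adds, at r = −17/−16 (split 50/50 by
default), `stall_weight` times the weight of one lattice position. Read
totals are negative binomial, positions multinomial; genotypes act only
through multipliers on φ and s, so an *xrn4*-like mutant is
`c(phi = 0.5, stall = 0.25)`. Everything is a deterministic function of
`(seed, genotype, replicate)`.

These defaults put the expected reference TSI near 25–40 (termination
dwell ~10 elongation steps against a background of ~0.6 uniform mass over
~1100 positions) and the mutant near 5, i.e. ~6-fold — comfortably inside
the TSI > 3 / 2-fold calling rules, while keeping the −17/−16 peak within
the range real metagenes show rather than an arbitrarily tall spike.
The analytic ground truth (`simulation_ground_truth()`) evaluates the TSI
of the exact positional law — depth cancels from the ratio — and derives
the true target flags from it.

What the generator does **not** emulate: batch effects between sequencing
runs (batches are represented only as separate sample sheets), positional
overdispersion beyond the multinomial, nucleotide-composition and ligation
biases, overlapping isoforms, codon-specific elongation pauses, and
alignment artefacts. Passing tests therefore demonstrate correctness of
the estimators under the stated sampling model, not robustness to every
failure mode of real libraries.

## Numerical choices and tie-breaks

* Metagene windows anchor at r = 0 with defaults ±100 nt; transcripts
  contribute only in-bounds positions; per-transcript normalisation
  (each window divided by its own sum before averaging) is off by
  default because the raw sum is conserved and auditable, while the
  normalised mode answers the abundance-bias question.
* The periodicity score pools CDS positions (stop codon excluded) up to
  the shortest included CDS, so every pooled position has full transcript
  support. The dominant period is the smallest lag in 2–10 nt whose
  mean-subtracted autocorrelation is within 10% of the maximum: harmonics
  of a 3-nt lattice (6, 9 nt) tie with the fundamental to within noise,
  and the fundamental is the quantity of interest. Constant pooled
  profiles have an undefined period.
* Metagene peak ties break toward the most upstream position
  (`which.max`); with two boundary positions sharing the stall mass this
  only matters on ties, which the stochastic draws make rare.
* Strict inequalities follow the published wording: TSI > 3, fold ≥ 2.
* `percent_called()` returns unrounded percentages; rounding is left to
  presentation.

## Problem sizes

The test suite and acceptance script run entirely on generated data:
oracle-equivalence sweeps use 200 random profiles (TSI), all universes
N ≤ 12 (hypergeometric vs subset enumeration) and n ≤ 10 (signed-rank vs
full sign enumeration); the metagene/periodicity and target-recovery
checks use 500-transcript experiments (the recovery run at
`expression_mean = 3000`, giving ≥ 50 expected boundary reads per
transcript as the recovery property assumes); half-life recovery uses 500
simulated time courses at log-normal noise SD 0.1. A full
`devtools::test()` pass takes well under a minute on one core.

## Limitations

The TSI flank geometry in the wider literature is not uniquely specified;
the 50 + 50 layout here is a declared default, and cross-study TSI values
should only be compared under identical `tsi_params()`. Multi-mapped 5'
ends across isoforms are double counted by design (documented above).
The pipeline consumes aligned 5' ends; trimming, alignment and
deduplication are upstream concerns, and GO-term enrichment against
external databases is out of scope.
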