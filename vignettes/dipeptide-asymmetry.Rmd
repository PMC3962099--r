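---
title: "Measuring dipeptide/antidipeptide asymmetry with dipasym"
author: "dipasym authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dipeptide/antidipeptide asymmetry with dipasym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipasym)
```

## The question

Proteins are written in a 20-letter alphabet, and every ordered pair of
adjacent residues — a *dipeptide* AB — has a mirror image BA, its
*antidipeptide*. Nothing in amino-acid composition alone forces the two
orientations to occur equally often: the single-residue frequencies of A
and B are identical in AB and BA. Yet large sequence surveys have found
that some orientations are strongly preferred — glutamate–proline versus
proline–glutamate being the classic example. `dipasym` implements the
statistics used to quantify that anisotropy, the subsampling procedure
used to show it is not a small-sample artifact, and a gene-level
mutagenesis simulation probing one candidate explanation. Because the
original sequence snapshots behind such surveys are generally not
redistributable, the package also ships a generative model with *known*
asymmetry, so every stage of the pipeline can be validated against exact
ground truth.

## The statistics

For an unordered pair of distinct residues $\{A, B\}$ with ordered counts
$n_{AB}$ and $n_{BA}$, the asymmetry statistic is

$$C_{190} = 100 \cdot \frac{\lvert n_{AB} - n_{BA}\rvert}{(n_{AB} + n_{BA})/2},$$

the absolute count difference relative to the mean count, on a $\times
100$ scale (the convention used in published tables of this quantity).
There are $\binom{20}{2} = 190$ such values — hence the name — because
same-residue dipeptides have no mirror image. $C_{190}$ ranges from 0
(perfect symmetry) to 200 (one orientation never observed). The *signed*
variant drops the absolute value and is reported in the alphabetical
orientation of the pair, so its sign tells which orientation dominates.
Both are invariant under rescaling of the counts, which makes values
comparable across sets of very different size.

The complementary, probability-flavoured measure is the propensity of a
residue B to precede a residue J:

$$P(BJ) = \frac{n_{BJ}/n_{XJ}}{n_{BX}/n_{XX}},$$

where X stands for "any residue": the observed share of B among the
predecessors of J, divided by B's overall share of first positions. 1
means no preference. The identity
$\sum_B P(BJ)\, n_{BX}/n_{XX} = 1$ holds for every J with $n_{XJ} > 0$;
the test suite asserts it to $10^{-9}$ on random tables.

Both statistics are undefined when their denominators vanish; `dipasym`
flags such entries (`NA`, `defined = FALSE`) and excludes them from
averages and rankings rather than silently zeroing them.

## Counting conventions

`count_pairs()` slides a window of step 1, so a sequence of length $L$
with no excluded letters contributes $L - 1 - g$ ordered pairs at gap
$g$ ("AAA" contributes 2 to the AA cell). Decisions a user should know
about:

* **Non-standard letters.** B, J, O, U, X, Z are tolerated in input
  sequences but never counted, neither as first nor as second element of
  a pair. Dropping only the affected windows (rather than whole
  sequences) wastes the least data. At $g > 0$ only the two *endpoints*
  must be standard: the intervening residues may be of any type, which
  matches the "any residue" reading of a gapped pair A(X)$_n$B.
* **The `*` separator.** Stop characters produced by translation act as
  hard separators: no window may cross one, at any gap. Sequence
  boundaries behave identically.
* **Initiator methionine.** Databases often retain the N-terminal Met,
  which inflates MX counts relative to XM. `skip_initial_met = TRUE`
  removes a leading M before counting; the default is `FALSE` (observe,
  don't correct), so the Met bias is visible rather than hidden.
* **Gapped counting.** The gap default used for "contact-free" analyses
  is 5 intervening residues — far enough that the endpoints cannot touch
  even across an α-helical turn, close enough to keep counts large.

## Sampling sufficiency: FPPP

An observed $C_{190}$ of 30 means little if recomputing it on half the
data gives 10. `fppp_analysis()` implements a fragmented
prediction-performance-plot check: a seeded random permutation of the
set is cut into $\lfloor N/s \rfloor$ non-overlapping subsets of exactly
$s$ sequences for each requested size $s$, the 190 values are computed
per subset, and the per-pair mean and standard error (sample SD over
subsets divided by $\sqrt{n}$) are reported. If the means are flat in
$s$ relative to their SEs, the full-set values are trustworthy. The
randomized partition (rather than input-order chunking) avoids artifacts
from database ordering; the seed makes it reproducible. Classic usage on
proteome-scale sets takes sizes 1000/3000/6000/12000; any size list is
accepted, and the package's own validation uses 100/300/600 on
synthetic sets of 2400 sequences.

`bootstrap_c190()` offers the complementary uncertainty estimate for
selected pairs, resampling whole sequences with replacement — the
sequence, not the residue, is the exchangeable unit.

## The synthetic generator

A first-order Markov chain over the 20 residues is the minimal model in
which adjacent-pair structure is controllable and analytically solvable:
at stationarity the expected number of ordered (A, B) pairs at gap $g$
per sequence of length $L$ is $(L - 1 - g)\,\pi_A (T^{g+1})_{AB}$, so
the population $C_{190}$ of every pair at every gap is a closed-form
function of the transition matrix (`analytic_c190()`).

Two presets ship with the package:

* `"symmetric"` — the uniform chain; every pair's analytic $C_{190}$ is
  exactly 0. Eight control pairs (AR, CD, DV, EY, FT, HT, PR, ST) are
  recorded with it as a null fixture.
* `"table3_asymmetric"` — starts from the uniform chain and perturbs
  the transitions of the seven most anisotropic pairs reported for
  natural proteins (EP ≈ 34, PW ≈ 24, MW ≈ 24, GP ≈ 23, AM ≈ 22,
  IP ≈ 21, CP ≈ 21, with the empirically dominant orientations PE, PW,
  WM, PG, MA, IP, CP). For each pair, $T_{XY}$ is scaled by $(1+\delta)$
  and $T_{YX}$ by $(1-\delta)$ with row renormalization, and $\delta$ is
  found by one-dimensional root search against the target; because pairs
  share residues (five involve proline), three sequential sweeps are run,
  after which every achieved value sits within 0.02 of its target. The
  *achieved* analytic values are stored in the preset and are the ground
  truth the recovery tests use.

What the generator deliberately does **not** emulate: realistic
amino-acid composition (rows stay near-uniform), higher-order or
position-specific dependence, length variation, and domain or repeat
structure. Passing recovery tests therefore demonstrates that the
*pipeline* measures pairwise asymmetry correctly, not that real
proteomes are first-order Markovian.

Because the chain mixes almost completely in one step ($T$ is a small
perturbation of the rank-one uniform matrix), the analytic $C_{190}$ at
gap 5 is orders of magnitude below its gap-0 value for every engineered
pair — a built-in, exact counterpart of the empirical observation that
dipeptide anisotropy is a short-range, contact-scale phenomenon.

`reverse_translate()` turns generated proteins into coding sequences by
sampling one synonymous codon per residue, uniformly by default or from
user-supplied codon-usage weights; frame-1 translation inverts it
exactly for stop-free proteins.

## The mutagenesis experiment

`mutation_experiment()` asks whether random gene-level events reshape
dipeptide statistics. Per gene and spec it generates mutants (uniform
random base deletions or substitutions; a substitution always changes
the base, uniformly over the three alternatives), translates everything
in frame 1 under the standard genetic code — stop codons emit `*` and
translation continues to the end of the sequence — and pools all mutant
translations of a spec before computing the tables, mirroring how the
statistics are computed on any sequence set. The classic four-spec
preset is 1 or 5 deletions and 10 or 50 substitutions per mutant, 100
mutants per gene (configurable; the package's own tests use 20).

The package's validation runs this experiment on 500 synthetic genes of
900 bases derived from the asymmetric preset. The outcome is
instructive and is worth stating plainly. Substitution mutants, which
preserve the reading frame, leave all 190 $C_{190}$ values statistically
unchanged. Deletion mutants do **not**: a single deletion shifts the
frame of, on average, half of each gene, and the out-of-frame portion
both dilutes the engineered protein-level asymmetry and introduces new
pair asymmetries of its own, inherited from codon structure. The
corresponding invariance check in the test suite is therefore expected
to fail for the deletion specs on this fixture, and it does. The
general lesson: invariance of dipeptide statistics under frameshifting
mutations is only possible when the asymmetry is carried by nucleotide
statistics that survive a change of reading frame — a property a
protein-level generative model cannot have by construction. For real
proteomes the question is empirical; the experiment here provides the
machinery to ask it of any coding-sequence set.

## Numerical and design choices

* All internal arithmetic is full precision; reports round to 2
  decimals (configurable), matching the conventional presentation of
  these statistics.
* Zero denominators flag a value undefined; per-residue averages and
  FPPP means reduce their divisor accordingly, a residue or pair with a
  single contributing value reports SE 0, and one with none reports
  `NA`.
* `rank_pairs()` breaks ties alphabetically by pair label, so rankings
  are total and reproducible.
* Stationary distributions come from the dominant left eigenvector
  (base `eigen()`), with a numerical irreducibility/aperiodicity check
  on the second eigenvalue modulus; a power-iteration oracle confirms
  agreement to $10^{-10}$ in the tests.
* Partitions, generators, bootstraps and the mutation experiment all
  take explicit integer seeds and restore the caller's RNG state, so
  identical calls are bit-identical and independent of surrounding
  code.
* Problem sizes used by the validation suite — 2000–2400 sequences of
  500 residues for recovery and FPPP checks, 200 replicate sets of
  40 × 200 for the symmetric null, 500 genes × 20 mutants for
  mutagenesis — were chosen so that engineered effects exceed their
  standard errors severalfold while the whole suite runs in about a
  minute on a single core.

## Known limitations

* The generator validates the pipeline, not biology: conclusions about
  real proteomes require real FASTA input (the package reads any).
* Redundancy reduction (e.g. clustering to 40 % identity) and database
  retrieval are out of scope; feed the package the set you consider
  clean.
* Translation is forward-strand, frame-1 only, standard code — the
  behaviour of the classic command-line translators in their default
  mode; organellar or non-standard codes are not supported.
* Significance testing of individual pair asymmetries is intentionally
  absent; the package reports magnitudes with resampling-based
  uncertainties instead.
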