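---
title: "Multilocus diagnostics of M/S hybrid zones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus diagnostics of M/S hybrid zones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mshybrid)
```

## The problem

The M and S molecular forms of *Anopheles gambiae* s.s. are incipient
species diagnosed by fixed differences concentrated in the low-recombination
pericentromeric regions of all three chromosomes: a SINE insertion on the X
(`SINE-X`), SNP-RFLP markers near the 2L and 3L centromeres, and the
form-defining SNPs in the multicopy rDNA intergenic spacer (IGS).  Across
most of their range these physically unlinked markers are in nearly complete
linkage disequilibrium, so each assay identifies the same two gene pools.
At the far-western edge of the range (The Gambia, Guinea Bissau) putative
hybrids are common, and the question becomes quantitative: how much
heterozygote deficit remains at each marker, how strong is the residual
association between unlinked markers, and how often do the two X-linked
assays disagree within an individual?

`mshybrid` implements that analysis as a tested pipeline: per-locus
Hardy-Weinberg and inbreeding statistics, two-locus haplotype inference and
LD testing, joint-genotype classification with contingency tests, and
quantitative scoring of mixed rDNA arrays, together with a synthetic
generator that produces data with exactly the statistical structure the
analysis assumes.

## Count reconstruction from published tables

Survey tables print genotype *frequencies* and the sample size N, not
counts.  `counts_from_frequencies()` inverts the rounding by
largest-remainder apportionment: each cell gets `floor(freq * N)`, and the
remaining units go to the cells with the largest fractional remainders, ties
broken by listed order.  This is the unique rule we found that (a) always
restores the exact sum N and (b) matches every count ratio quoted in the
prose accompanying the packaged tables (63/10, 45/131, 150/31, 64/43).  The
packaged tables (`load_survey_tables()`) carry one flagged row whose printed
summary statistics are internally inconsistent with its own genotype
frequencies under any rounding we tried; that row is excluded from
reproduction checks.

All samples are indoor-resting females, so X-linked loci are treated as
ordinary diploid loci throughout; hemizygous males would need a separate
haploid path, which is out of scope and documented here.

## Per-locus statistics

For genotype counts $(n_{MM}, n_{MS}, n_{SS})$, $N$ individuals and
$p = (2n_{MM} + n_{MS})/2N$:

* **Expected heterozygosity** uses the unbiased small-sample convention
  $H_e = 2pq\,\frac{2N}{2N-1}$.  The plain $2pq$ does *not* reproduce the
  published expected-heterozygosity columns (e.g. 0.4841 vs the printed
  0.49 for the largest Gambian sample); the corrected form does, for every
  row checked.
* **Inbreeding coefficient.**  The Weir-Cockerham within-sample estimate
  with $h = n_{MS}/N$:
  $b = \frac{n}{n-1}\left(p(1-p) - h\frac{2n-1}{4n}\right)$, $c = h/2$,
  $f = 1 - c/(b+c)$.  This reproduces all published cells to 2 decimals;
  note that a sample in exact Hardy-Weinberg proportions gives a slightly
  *positive* $f$ (the finite-sample correction), so tests assert the
  plug-in value 0.005 for the 25/50/25 table rather than 0.
* **Exact Hardy-Weinberg test.**  The Levene conditional distribution of
  the heterozygote count given the allele counts,
  $P(n_{12}) = \frac{N!\,2^{n_{12}}\,n_1!\,n_2!}{n_{11}!\,n_{12}!\,n_{22}!\,(2N)!}$,
  is enumerated over its full support ($n_{12}$ stepping by 2 with the
  parity of $n_1$).  For a biallelic locus this support is tiny, so complete
  enumeration is exact and the Markov-chain samplers used by classic
  software are unnecessary; a Metropolis sampler over the same conditional
  distribution is nevertheless provided (`method = "mcmc"`) purely as an
  independent cross-check and must agree within Monte-Carlo error.  The
  two-sided p sums all outcomes no more probable than the observed one (the
  probability-mass convention); one-sided deficit/excess tails are exposed
  because heterozygote deficit is the biological signal of interest.

Monomorphic loci return `NA` with reason `"fixed"` rather than a value, the
convention used for fixed samples in survey tables.

## Two-locus haplotype inference and LD

With two biallelic loci, only the double heterozygote is phase-ambiguous.
`em_haplotypes()` initializes the four gamete frequencies at
linkage-equilibrium products of allele frequencies and iterates the
standard EM: the E-step splits each double heterozygote between cis and
trans with posterior $f_{MM}f_{SS}/(f_{MM}f_{SS} + f_{MS}f_{SM})$, the
M-step re-estimates frequencies from expected gamete counts.  Numerical
choices: convergence when the log-likelihood gains less than `1e-10`
(default), a hard cap of 1000 iterations, an internal assertion that the
log-likelihood never decreases, and a `non_identifiable` flag when the
sample is entirely double heterozygotes (the likelihood is then invariant
to a cis/trans swap).  On small tables the EM optimum is verified in the
test suite against a direct numerical maximizer of the same multinomial
likelihood over a softmax parameterization — an oracle that shares no code
with the EM path.

From the fitted gamete frequencies, `ld_statistics()` returns
$D = f_{MM} - p_X p_{3L}$, $D'$ (D over its admissible bound) and
$r^2 = D^2/(p_X q_X\, p_{3L} q_{3L})$.  The published $r^2$ values are
reproduced from EM frequencies directly; resolving phases first and
recomputing from gamete counts moves the values away, which is why EM
frequencies are the adopted convention.  One published value resists
reproduction: for the 1996 Guinean sample the maximum-likelihood estimate
from reconstructed counts is $r^2 = 0.197$, which rounds to 0.20 rather
than the printed 0.19; the corresponding check is left failing rather than
loosened, and the three other samples reproduce exactly.

Significance testing is two-pronged:

* **Phase-unknown LR test** (`lr_test_association()`): twice the gap
  between the EM log-likelihood and the likelihood with gamete frequencies
  constrained to products of allele frequencies, clamped at 0 (the null is
  on the boundary, so small negative gaps within `1e-9` are numerical
  noise).  The null distribution comes from permutations that reassign one
  locus's genotype column across individuals; because only the
  cross-tabulation matters, the permutation draw is implemented as random
  contingency tables with fixed margins (`r2dtable()`, Patefield's
  algorithm — exactly the permutation distribution, at a fraction of the
  cost).  Default 10,000 permutations, seeded; the asymptotic $\chi^2_1$ p
  is reported alongside.
* **Phase-resolved exact test** (`phase_known_exact_test()`): double
  heterozygotes are resolved to their maximum-posterior phase, gametes are
  cross-tabulated 2x2, and Fisher's exact test is applied.  Classic
  software runs a Markov-chain exact test here whose internals are not
  reproducible from its description; maximum-posterior resolution plus
  Fisher is deterministic, has the same null, and is documented as this
  package's convention.

Bootstrap SDs for the gamete frequencies resample individuals with
replacement; replicates where a locus goes monomorphic carry no LD
information and are dropped (and counted).  Phase ambiguity measurably
inflates the bootstrap SD relative to an unambiguous table with the same
fitted frequencies, which the test suite checks on matched constructions.

## Genotype-class association

`classify_joint_genotype()` groups joint X/3L genotypes into `parental_M`
(MM/MM), `parental_S` (SS/SS), `f1_like` (MS/MS) and `assorted` (the six
remaining cells); the first three are "congruent" (both loci agree).
`mismatch_classify()` encodes the IGS-vs-SINE taxonomy: pure-form IGS with
heterozygous SINE (type 1), hybrid IGS with homozygous SINE (type 2), and
opposing homozygotes.

`contingency_chisq()` wraps `chisq.test()` with an explicit Yates policy:
under `"auto"` the continuity correction applies iff the table is 2x2.
This is the unique policy consistent with all five association statistics
accompanying the packaged tables (the 3x3 and 2x3 tests uncorrected, the
three 2x2 tests corrected).  The Gambian X-by-3L independence test drops the
X-heterozygote row — the MS subsample there is too small to support a 3x3
test — and `genotype_class_summary()` exposes that exclusion as an explicit
argument (`drop_x_het`) rather than a hidden rule.  Individuals with
uncleaved-ambiguous 2L calls never enter association analyses: the
second-site null allele makes all-uncleaved patterns uninterpretable.

The summary also reports the M-side and S-side parental:assorted ratios at
full precision together with the conventional one-decimal label (the
published "0.3 to 1" corresponds to 45/131 = 0.344; both are emitted).

## Copy-number proportions from trace peaks

The rDNA IGS is a tandem array of roughly a thousand repeats, so a single
individual can carry both M- and S-type repeats in unequal numbers.  At a
diagnostic position the two base channels then show double peaks whose
relative heights estimate the S-copy proportion.  `normalize_peak_heights()`
divides each channel's height by the *median* reference height of the same
channel over a +/-5-position flanking window; the trace-analysis tool this
emulates documents only that it adjusts against upstream/downstream
nucleotides, so the median was chosen as a robust compatible stand-in
(insensitive to a heterozygous position inside the window) and the window
size is a parameter of the observation, not a hidden constant.  The score is
`cnp = s_S / (s_M + s_S)`: 0 for all-M arrays, 1 for all-S, 0.5 for balanced
F1-like arrays.  Classification thresholds default to 0.1/0.9, the score
ranges observed in pure-form individuals from non-hybridizing areas.
`cnp_group_compare()` applies the tie-corrected Kruskal-Wallis omnibus test
across SINE-X genotype groups and pairwise Mann-Whitney tests with
Bonferroni multiplication, and emits medians/quartiles for box-plot
summaries.  CNP is invariant to uniform rescaling of the trace by
construction, and parameter recovery on synthetic traces (multiplicative
log-normal noise, sd 0.1, n = 200 per level) achieves mean absolute error
below 0.05 across the full grid of true proportions.

## The synthetic generator

`simulate_population()` implements the minimal generative structure that
produces the observed pattern — heterozygote deficit plus inter-chromosomal
LD plus assay mismatches — rather than a multi-generation forward
simulation: each individual draws two gametes, both from one pool with
probability `1 - cross_mating` (the M pool with probability `alpha`),
otherwise by panmictic union with each gamete's pool drawn independently.
`cross_mating = 0` is therefore a pure Wahlund mixture with closed-form
expectation `expected_wahlund_fis()` =
$\alpha(1-\alpha)(p_1-p_2)^2/(\bar p \bar q)$, and `cross_mating = 1` is
exact panmixia — the two anchors the property tests use.  Defaults are the
study conditions the analysis targets: diagnostic loci fixed opposite in
the two pools, equal mixing (`alpha = 0.5`), `cross_mating = 0.1` (an order
of magnitude above the ~1% inter-form mating reported where the forms are
isolated, matching the elevated admixture of the far-western zone), and a
2L null-allele frequency of 0.292, the value observed in the study area.

`simulate_rdna_arrays()` draws the S-copy proportion from per-ancestry Beta
mixtures (defaults concentrated near 0, 0.5 and 1 for MM, MS and SS
ancestry) and derives the IGS call through thresholds (defaults 0.2/0.8;
the true mapping from array imbalance to RFLP banding is not quantified
anywhere, so these are free parameters).  Because the SINE genotype is the
chromosomal ancestry itself while the IGS call is array-driven, both
mismatch types arise by construction, and mismatch frequency grows with
mixture variance.  `apply_null_allele()` disrupts each 2L chromosome's
restriction site independently with probability `nu`; one cleaved band
reads as `MS` (silently converting null-carrying MM homozygotes into
apparent heterozygotes — the real confound), while an all-uncleaved pattern
is reported as `U` (uninterpretable) whenever `nu > 0`.

What the generator does **not** emulate: concerted evolution of the rDNA
array over generations, multi-generation pedigrees (no F2/backcross
structure beyond what gamete union induces), linked markers, genotyping
error other than the 2L null allele, and real trace artifacts (baseline
drift, dye blobs).  Passing recovery tests therefore validate the
estimators under the stated sampling models, not the field accuracy of the
assays.

## Problem sizes and runtime choices

The test suite works at desk scale by design: published-table
reproductions are exact arithmetic on N <= 321; simulation-based properties
use 200 replicates of n = 500 for the Wahlund recovery, 100 replicates of
n = 200 for the panmixia check, 1000 independence simulations of n = 100
with 99 permutations each for the LR test's type-I error, and 200 traces
per level for CNP recovery.  These sizes put Monte-Carlo error well inside
the asserted 3-standard-error or binomial-99% bands while keeping the whole
suite in the low minutes on one core.

## Known limitations

* Biallelic loci only; the multi-allelic exact test and multi-population
  F-statistics (F_ST hierarchies) are out of scope — only within-sample
  statistics are computed.
* X-linked loci are treated as diploid, valid for all-female samples only.
* Two-locus haplotype inference only; three-locus tables are representable
  but not an inference surface.
* The phase-resolved exact test conditions on a point phase assignment; its
  p-value understates phase uncertainty when the cis/trans posterior is
  near 0.5 (the phase-unknown LR test is the primary instrument).
* The published r^2 for the 1996 Guinean sample (0.19) is not reproduced
  exactly (we obtain 0.197 from reconstructed counts); see above.
* `Genepop` support is export-only; the native interchange format is the
  headered TSV.
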