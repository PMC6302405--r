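---
title: "Merging paired-end reads with empirical quality-score profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging paired-end reads with empirical quality-score profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairstitch)
```

## The problem

Illumina paired-end reads from short DNA fragments overlap at their 3'
ends; when the fragment is shorter than the read length the reads run
past each other into adapter sequence ("dovetailed" pairs).  Merging a
pair into a single read that spans the fragment corrects sequencing
errors (two observations of every overlap base) and removes adapter
contamination -- but only if the merged base's *quality score* honestly
reflects its error probability.  The Phred convention defines

$$Q = -10 \log_{10} P(\text{base wrong}),$$

so a Q40 base should be wrong once in $10^4$.  Popular merging schemes
for agreeing overlap bases either keep the higher of the two scores
(conservative) or add them ($Q_1 + Q_2$), the latter following from the
assumption that the two reads err *independently*.  That assumption
fails in practice: an error made during first-strand synthesis on the
flow cell, before cluster amplification, is copied into **both** reads
at full quality.  Summed scores like Q80 then claim error rates
($10^{-8}$) that are orders of magnitude below what the data can
support.  `pairstitch` implements the merging algorithm, the empirical
profile-training pipeline that measures what combined scores are really
worth, and a read simulator with correlated first-strand errors that
makes the whole chain testable without any external data.

## Alignment model

`find_best_alignment()` scores **every** gapless placement of the
reverse-complemented R2 against R1 (`enumerate_offsets()`), an
exhaustive scan rather than a seeded heuristic.  A placement is valid if
its geometric overlap is at least `min_overlap` (default 20 bp) and its
mismatch fraction at most `max_mismatch_frac` (default 0.1); among valid
placements the lowest mismatch fraction wins.  Ambiguous bases (`N`)
count as neither matches nor mismatches: they are excluded from the
mismatch-fraction denominator, while the overlap-length test stays
geometric (a run of `N`s still occupies overlap columns).  Dovetailed
placements -- negative offsets, or an R1 3' overhang past R2's 5' end --
are searched only when requested (`allow_dovetail`, always on in
adapter-removal mode).

Choices the model itself does not dictate, fixed here for determinism:

* **Tie-breaking** between placements with equal mismatch fraction:
  prefer the larger overlap (the physically longer explanation), then
  the smaller absolute offset, then the non-negative offset.
* Offsets are 0-based; intervals are half-open internally.
* The mismatch-fraction test uses exact integer cross-multiplication,
  so ties are ties and not floating-point accidents.

The scan is implemented in C++ (`src/align.cpp`); the test suite
verifies it pair-by-pair against an independent plain-R exhaustive
scorer on simulated data covering normal, contained and dovetailed
geometries.

## Merging rules

For one overlap column with bases $(b_1, b_2)$ and qualities
$(q_1, q_2)$ (`resolve_position()`):

* agreeing bases keep the base, with the *match* model quality;
* disagreeing bases keep the higher-quality base, with the *mismatch*
  model quality;
* a lone `N` is replaced by its mate's base at that base's own quality
  (an "N corrected");
* two `N`s remain `N` at quality 0;
* disagreeing bases of **equal** quality give `N` with the mismatch
  quality: there is no evidence for either base, and inventing one
  would misrepresent the data.  (The difference scheme assigns such
  columns $|q_1-q_2| = 0$ anyway.)

Resolved real bases are floored at Q2 -- scores 0/1 are reserved in
Phred+33 practice.  Non-overlap columns are copied verbatim, and
dovetail overhangs (adapter) are never included in the merged read.
Quality models (`quality_model()`):

| kind        | match                  | mismatch       | default cap |
|-------------|------------------------|----------------|-------------|
| `fastqjoin` | $\max(q_1,q_2)$        | $|q_1-q_2|$    | 40          |
| `sum`       | $q_1+q_2$              | $\max(q_1,q_2)$| 80          |
| `matrix`    | trained table lookup   | table lookup   | 40          |

The `sum` kind's mismatch rule is an approximation for comparison
purposes: sum-style mergers do not reduce mismatch qualities, but
publish no exact mismatch formula.  The package default is `fastqjoin`
(conservative across most of the score range).  The shipped matrix pair
(`synthetic_profile_model()`) was trained on this package's own
simulator output and is labelled synthetic; it demonstrates the file
format and code path, not any instrument.

## Profile training

`train_quality_profile()` reproduces the empirical-calibration recipe:

1. **Tally** (`tally_from_truth()`): every overlap column of stitched
   reads whose alignment matches the truth geometry is classified
   (match/mismatch by input bases; correct/error by comparing the merged
   base to the true fragment) into a 3-d table over $(q_1, q_2)$.  `N`
   columns and equal-quality ties (merged base `N`) are excluded.
2. **Rates**: cells with zero errors get a pseudo-error count of 0.5
   (rate $0.5/n$); match cells with fewer than 1000 observations and
   mismatch cells with fewer than 100 are masked
   (`filter_cells()`) and filled only by smoothing.
3. **Baseline** (`fit_baseline()`): a local regression of
   $\log_{10}(\text{rate})$ on the claimed per-read quality score, made
   invertible by an isotonic (non-increasing) projection.  Outside the
   fitted range the inverse continues the terminal slope linearly.
4. **Matrices** (`build_matrices()`): a two-dimensional local regression
   of $\log_{10}(\text{rate})$ over $(q_1, q_2)$ per class; smoothed
   rates are mapped through the inverse baseline back onto the
   instrument's own quality scale, floored at 2, capped at `qual_max`,
   and rounded.  The match matrix is symmetrised (the two reads are
   physically exchangeable); the mismatch matrix is not, because
   $(q_1, q_2)$ encodes which read's base won.

Numerical choices: the smoother bandwidth is a knob (`span`, default 0.3
of the points, degree-1 local fit, direct surface so the full grid can
be predicted); monotonicity of the baseline is enforced by isotonic
projection because invertibility is required and local regression alone
does not guarantee it; below 10 unmasked cells the 2-d smoother
degrades to a weighted-mean constant surface with a warning, and a fully
masked table is an error.  Matrix entries are rounded once, at training
time, not at lookup time.

## The simulator

`simulate_pairs()` generates the ground truth every other module is
tested against.  Defaults describe a 2 x 100 bp run over a
short-fragment control library: fragment lengths truncated-normal(150,
30) on [70, 400] -- most pairs overlap, and a small tail is shorter than
the read length, producing dovetails with standard TruSeq adapter
read-through; per-cycle declining qualities (38 at the first cycle to 30
at the last, Gaussian noise sd 2, clamped to [2, 40]); independent
substitution errors drawn per base at exactly the Phred-implied rate
$10^{-q/10}$, choosing uniformly among the three alternative bases;
occasional `N` masking (3 x 10^-4 per base, matching the few-in-10^4
prevalence of ambiguous bases in real overlap data).  First-strand
errors are modelled by mutating the fragment copy that *both* reads are
synthesised from, at `shared_error_rate` per fragment base, leaving the
assigned quality scores untouched -- the defining signature of
non-independent paired errors.  A single seed drives a per-pair stream
split, so enlarging `n_pairs` never reshuffles earlier pairs and the
same seed is byte-reproducible.

What the simulator does *not* emulate -- indels, optical duplicates,
per-tile artefacts, context-dependent miscall spectra, PCR duplication
-- bounds what passing tests show: they validate the algorithmic
contracts and the statistical machinery, not instrument realism.

One consequence of the uniform-substitution choice deserves a note.
When both reads err independently at the same column, they agree on the
wrong base only a third of the time, so the analytic match-class error
rate is $e_1 e_2 / 3$, i.e. $q_1 + q_2 + 10\log_{10}3 \approx
q_1+q_2+4.8$ on the quality scale -- slightly *above* the naive additive
prediction.  At desk scale this distinction is academic: a cell needs
$\gtrsim 3 \times 10^{(q_1+q_2)/10}$ observations before real errors
outweigh the 0.5 pseudo-count, which for $q_1+q_2 \ge 40$ exceeds what
$10^6$-column training runs provide.  Well-observed cells are therefore
pseudo-count- and cap-limited, and trained match entries equal
$\min(q_1+q_2, 40)$ under the default cap -- which is also the honest
statement about what such data can support.  The additive-recovery
property of the smoothing/back-transform chain itself is tested
separately on tally tables built directly from the independence product
$10^{-(q_1+q_2)/10}$ at $10^9$ counts per cell, where entries come back
within +/-3 of $\min(q_1+q_2, 80)$.

With shared errors at rho = $10^{-3}$ the match-class error rate at
high-quality cells sits near rho instead of below $10^{-5}$: combined
confidence stops rising with the claimed scores, which is the mechanism
behind capping empirical profiles near 40.  When rho is comparable to
the per-read error rate the baseline profile itself flattens and its
inverse becomes ill-conditioned at the high end, so the package asserts
this regime at the tally level rather than through back-transformed
scores.

## Error statistics and the control-genome utility

`count_errors_by_quality()` walks mapped SAM/BAM records (properly
paired when the paired flag is set), compares aligned bases to the
reference and tallies bases and errors per quality score; insertions
and soft-clips are skipped and deletions are not base errors (an indel
has no single quality).  Given a merge event log and the original read
lengths it additionally splits merged-read overlap columns into
match/mismatch/`N` classes.  Producing the alignments themselves
(aligner, pileup, variant caller) is out of scope -- those are standard
tools, not part of this method; the module consumes their SAM output or
simulator truth.  In the unmerged baseline calculation, overlapping mate
bases are both counted (the deduplication choice is unstated in the
original recipe; counting both is documented here).

`apply_variants()` and `circular_extend()` build the corrected control
reference: the five observed PhiX variants (587 G>A, 833 G>A, 2731 A>G,
2811 C>T, 3133 C>T; `phix_variants()`) are substituted with
reference-base verification, and the first kilobase is appended so
alignments across the circular origin are representable, giving a
6386-bp reference from the 5386-bp genome.  Because this package is
built and tested fully offline, it ships `synthetic_phix_genome()`, a
deterministic 5386-bp stand-in with the correct reference bases at the
five edited positions -- clearly labelled synthetic; substitute the real
accession's FASTA for genuine control-read analyses.  Real-data
calibration figures (an effective quality of 38.6 at claimed Q40, 96.7%
of overlap bases matching, post-merge error rates of order $10^{-4}$
for sum-style mergers at Q80) are instrument-and-dataset properties
quoted here as context only; nothing in this package computes them
without such data.

## Problem sizes used by the test suite

The suite's statistical checks were sized as the smallest runs whose
assertions are stable across seeds: oracle equivalence on 1000
mixed-geometry pairs; error-correction direction and `N`-correction on
50,000 pairs at mean Q30; profile training on 100,000 pairs (~4.8
million overlap columns) per condition, where match cells reach the
10,000-count regime and the mismatch table retains a handful of cells
at its 100-count threshold; independence checks on ~5 x 10^5 overlap
columns.  The full suite runs in a few minutes on one CPU.

## Limitations

* Gapless alignment only; an indel in the overlap fails the pair.
* Matrix models refuse lookups outside their trained range rather than
  extrapolating.
* The shipped matrices are simulator-trained placeholders; training on
  instrument control reads is the intended use.
* Equal-quality mismatches become `N`; pipelines that must emit a base
  at every position should pre-filter or accept the ambiguity.
* Profiles trained on one instrument family do not necessarily
  transfer to platforms with different error chemistry.
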