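# pairstitch

Merging of overlapping Illumina paired-end reads with quality scores
that mean what they say.

When a DNA fragment is shorter than twice the read length, its R1 and
R2 reads overlap at their 3' ends; when it is shorter than one read
length, each read runs past the other's start into adapter sequence
(a *dovetailed* pair).  `pairstitch`:

* finds the optimal **gapless alignment** of each pair by exhaustively
  scoring every relative placement, including dovetailed ones
  (minimum overlap 20 bp, at most 10% mismatches among non-`N` overlap
  columns, lowest mismatch fraction wins);
* **stitches** each aligned pair into one read spanning the fragment
  (agreeing bases kept; disagreements resolved toward the
  higher-quality base; lone `N`s corrected from the mate), or in
  **adapter-removal** mode just clips the 3' overhangs;
* assigns merged-base qualities from pluggable models built on the
  Phred relation `Q = -10 log10(P(base wrong))`: the conservative
  difference scheme (`max(q1,q2)` on a match, `|q1-q2|` on a
  mismatch), the additive independence scheme (`q1+q2` on a match),
  or **empirical match/mismatch matrices**;
* **trains** those matrices from truth-annotated reads: 3-d error
  tallies over `(q1, q2, match/mismatch)`, 0.5 pseudo-errors for
  zero-count cells, 1000/100-count masking, local regression of
  `log10(rate)`, and back-transformation through a smoothed baseline
  quality/error-rate profile;
* computes **per-quality-score error rates** from SAM/BAM alignments,
  and builds the variant-corrected, circularly-extended PhiX control
  reference (6386 bp) used for such calibrations;
* ships a **paired-read simulator** with quality-dependent independent
  errors and correlated first-strand errors (copied into both reads at
  full quality), so every stage is testable offline with known truth.

The practical point of the empirical profiles: paired-read errors are
*not* independent — a first-strand synthesis error is propagated to the
whole cluster and appears in both reads at undiminished quality — so
additive schemes that assign Q80 to two agreeing Q40 bases overstate
the evidence by orders of magnitude.  Trained profiles measure what
combined scores are actually worth.

## Worked example

```r
library(pairstitch)

sim <- simulate_pairs(sim_config(n_pairs = 2000, seed = 42))
res <- merge_pairs(sim$r1, sim$r2,
                   align_params(allow_dovetail = TRUE), events = "all")
str(res$stats)
#> List of 4
#>  $ pairs       : int 2000
#>  $ merged      : int 1688
#>  $ failed      : int 312
#>  $ ns_corrected: int 63
```

2000 simulated pairs (2 x 100 bp, fragments ~N(150, 30)): 1688 merge
(the rest overlap by less than 20 bp), 87 of them dovetailed, and all
63 lone `N`s in overlaps are replaced by the mate's base.  Merging is
error-correcting — comparing overlap bases to the known fragments:

```r
#> overlap error rate before merging: 9.25e-04  after: 4.50e-04
```

Quality schemes at a glance:

```r
merged_quality(quality_model("fastqjoin"), 40, 40, TRUE)  # 40
merged_quality(quality_model("sum"), 40, 40, TRUE)        # 80
qual_to_error(40)                                         # 1e-04
qual_to_error(80)                                         # 1e-08
```

Training an empirical profile on simulated truth and using it:

```r
tr <- train_quality_profile(simulate_pairs(sim_config(n_pairs = 1e5)))
tr$model$match_matrix["30", "30"]   # what two agreeing Q30s are worth
res2 <- merge_pairs(sim$r1, sim$r2, model = tr$model)
```

A command-line front end covering the same operations is installed at
`exec/pairstitch` (subcommands `stitch`, `adapter`, `profile`,
`simulate`, `errstats`; flags `-1/-2/-o/-m/-p/-d/-j/-b/-w/-x/-u`).

The PhiX reference utility:

```r
ref <- circular_extend(apply_variants(synthetic_phix_genome()))
nchar(ref)  # 6386
```

`synthetic_phix_genome()` is a deterministic stand-in (same length,
correct reference bases at the five variant positions); use the real
NC_001422.1 FASTA via `read_fasta_seq()` for genuine control-read
analyses.

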