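---
title: "Cross-platform content mapping and sense:antisense discovery: methods"
author: "SASpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform content mapping and sense:antisense discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SASpipe)
```

# Scope

SASpipe compares a generic genome-based microarray with a
disease-specific transcriptome-based array at the probe level and mines
the disease-specific content for natural antisense transcripts (NATs) and
sense:antisense (SAS) pairs. This vignette documents the models and
procedures, the parameters that matter, the numerical conventions, and
what the synthetic-data generator does and does not emulate. MAS5
preprocessing itself is out of scope throughout: expression values and
Present/Marginal/Absent (P/M/A) flag calls are *inputs* to this pipeline,
produced upstream on real data and synthetically here.

# Content mapping

## The rule

A probeset (typically 11 probes of 25 nt) is *common* to both platforms
when at least 6 of its probes occur with 100% identity over their entire
length in a **single** full-length sequence of the other platform.
Classification is bidirectional: disease-specific probesets are matched
against the generic platform's full-length sequences first; the generic
platform's probesets are then matched against the full-length sequences
that represent the disease-specific probesets still unclassified, and a
second-pass hit marks both sides common. The remainder on each side is
*unique*, so per platform `total = common + unique` — the partition law
every run is checked against.

## Why exact matching, and other commitments

Because the rule demands perfect identity over the whole probe, exact
substring indexing (Biostrings dictionary matching) is equivalent to a
heuristic aligner on this task while being deterministic and free of
e-value tuning. Commitments where the rule as stated leaves room:

* **Both strands count.** A probe hits a sequence if it occurs in it
  directly or as a reverse complement. Antisense probesets genuinely
  interrogate the opposite strand of sense content, and a strand-blind
  aligner would report those alignments; the recorded `strand` column
  keeps the information. The classifier is invariant to
  reverse-complementing every target (tested).
* **No pooling.** Probes matching *different* sequences never add up;
  the >= 6 count is per single target sequence.
* **Probesets with fewer than 6 probes can never be common** (the
  threshold is absolute, not proportional).
* **Ties** between equally good targets break to the lexicographically
  smallest sequence id, making the reported best target deterministic.
* **One sequence, many probesets.** When a full-length sequence backs
  several probesets (generic platforms are redundant), a hit on the
  sequence marks all of its probesets common.
* **Missing sequence records** exclude the affected probeset from the
  partition with a warning and a report (`excluded` slot) rather than a
  silent drop.

# Filter cascades

## Detection

In vitro, a probeset is detected in a condition when its flag is P or M
in **all** replicates of that condition — with a single replicate, one
P/M call suffices (degenerate but well-defined). Clinically, detection
requires P/M calls in **strictly** more than half of all samples: with
28 samples, 15 pass and 14 do not. The boundary is asserted in the test
suite.

## Differential expression

Between two replicated conditions, for probesets detected in both:

* **Fold change** on linear-scale replicate means,
  `max(m2/m1, m1/m2)`, with the direction recorded separately. The
  threshold (default 1.3) is **inclusive**: a probeset at exactly
  1.3-fold passes. The boundary had to be fixed somewhere; "at
  1.3-fold" reads most naturally as inclusive, and the choice is
  documented and tested.
* **Student's pooled-variance two-sample t-test on log2 intensities**,
  two-sided, `p <` threshold (default 0.05), strict. With three arrays
  per group a pooled equal-variance t is the era-standard choice;
  whether the original test ran on the log or linear scale is not
  recorded anywhere we could verify, so the scale is an explicit design
  decision here — log2 stabilises array variance and is the
  conventional scale for fold-change statistics.
* **No multiple-testing correction.** The cascade deliberately mirrors
  raw-p filtering; this is fidelity to the analysis style being
  reimplemented, not a statistical recommendation. FDR control can be
  layered on the reported p values by the user.
* **Degenerate variance.** Zero pooled variance with equal means is a
  constant probeset: fold 1, never passes, p undefined (`NA`). Zero
  pooled variance with unequal means would have an infinite t statistic;
  it is flagged `degenerate`, treated as p = 0, and reported rather than
  dropped.

The t statistics are computed vectorised from the closed form (the suite
cross-checks them against `stats::t.test` to 1e-12 and against the t CDF
to 1e-10); `t.test` itself errors on the degenerate branches above.

The clinical cascade applies no statistical test: after majority-call
detection, each response group (CR/PR/SD/PD) is contrasted against the
mean of all other samples on the linear scale, and a probeset passes at
`>= 1.5`-fold (inclusive) in at least one group. The reference for "in
at least one condition" is not specified in the design being emulated —
one-vs-rest is this package's choice (the plausible alternatives,
group-vs-group or group-vs-overall-mean, would need n(n-1)/2 or n
contrasts with less interpretable nesting); the per-probeset table
records which group won and in which direction.

# Pathway over-representation

For a platform whose annotated genes form the universe (size `N`), a
pathway with `K` genes in the universe, `n` selected
(differentially expressed) genes and `k` of them in the pathway:

$$P(X \ge k) = \sum_{i=k}^{\min(K,n)}
  \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}$$

computed by summing log-scale terms (`lchoose` + log-sum-exp), exact for
`k = 0` (probability 1). The suite verifies agreement with exhaustive
enumeration of all draws for every parameter combination with
`N <= 12`, and with `stats::phyper` at large counts to 1e-12.

Decisions:

* **Universe = annotated genes on the platform under test**, not the
  genome: the platform comparison is the point, and a genome universe
  would reward platforms for content they do not carry. Whether the
  original universe was all array genes or all detected genes is not
  recorded; the function takes the universe explicitly so either is a
  one-line change.
* **The genes-per-pathway cutoff applies to the DE overlap count `k`**
  and is **strict** (`k > minGenes`): the full-scale convention is
  "greater than 15" (sensitive) and "greater than 10" (resistant) genes
  per pathway, with the cutoff chosen relative to the experiment's gene
  count. `runFullPipeline()` accordingly defaults to cutoffs scaled to
  the synthetic experiment size (5 and 3); `enrichPathways()` itself
  defaults to 15.
* **Raw p values**, no correction, matching the filter cascades.
* Probesets collapse to unique gene ids before testing
  (`collapseToGenes()`), since redundant probesets would otherwise count
  one gene several times; unannotated probesets are dropped and counted.

# Sense:antisense discovery

Probesets are deduplicated to gene ids per orientation
(`dedupeByGene()`); SAS pairs are the genes present in both orientation
sets, so `|pairs| <= min(n_sense, n_antisense)` always. Gene
identifiers are opaque keys — any consistent annotation works.
Orientation-unassigned probesets are not eligible for pairing (their
strand relationship to anything is unknown); they are tallied in the
orientation breakdown instead.

When one representative probeset per orientation is needed (for
expression comparison), the probeset with the highest mean intensity
wins — deterministic, and it favours the measurable signal; without
intensities the alphabetically first is taken.

## cis-NAT overlap categories

For a pair of opposite-strand loci at one locus, with 5'/3' ends derived
from the strand:

* `fully_overlapping` — one interval contains the other. Containment
  satisfies both end conditions below, so it takes precedence.
* `head_to_head` — the overlap interval contains both 5' ends.
* `tail_to_tail` — the overlap interval contains both 3' ends.
* `non_overlapping` — disjoint intervals.

The classifier is exhaustive and mutually exclusive over opposite-strand
pairs (property-tested against an independent interval-arithmetic
re-derivation), and errors on same-strand input. Internally coordinates
are GRanges (1-based, closed) — the R ecosystem's convention; the BED
boundary (0-based half-open) is handled by rtracklayer on export/import.

## Concordance of pair expression

"Similar versus differential intensities" needs a fixed cutoff to be
testable: a pair is *discordant* when sense and antisense mean
intensities differ by strictly more than `tau = 1` on the log2 scale
(i.e. beyond 2-fold; exactly 2-fold is concordant). `tau` is an argument
everywhere it is used.

# Array-versus-qPCR concordance

Signed fold-change ratios map through `sign(x) * log2(|x|)` — the sign
convention for down-regulation must be fixed before a correlation is
meaningful, and the log base cancels in r. Pearson's r is reported with
r² and a two-sided p from `t = r * sqrt((n-2)/(1-r²))` on `n - 2`
degrees of freedom. Whether signed or absolute fold changes were
correlated in the original validation is not recorded; SASpipe
correlates **signed** values (a validation should penalise direction
disagreement). The suite checks the hand formula, the reference
implementation (`cor.test`), affine invariance, and the analytic
attenuation of r under added noise.

# The synthetic-study generator

`syntheticConfig()` fixes the study conditions; `simulateStudy()` runs
three stages — transcriptome, platform design, expression — each on its
own RNG stream derived from the master seed, so a stage can be
regenerated without replaying the others. Identical configurations give
byte-identical outputs.

## What it emulates

* **Loci with real cis-NAT geometry.** Every gene gets a sense
  transcript at its own genomic window; `natFraction` (default 0.2,
  the commonly cited share of protein-coding genes with an antisense
  partner) of genes also get an opposite-strand transcript whose overlap
  follows its assigned category, drawn from `overlapWeights` (default
  0.3 / 0.5 / 0.2 head-to-head / tail-to-tail / fully overlapping;
  tail-to-tail is generally reported as the most common cis-NAT class).
  Transcript sequences are cut from one random genomic sequence per
  locus, so overlapping transcripts are exact reverse complements over
  their overlap — probe matching across orientations behaves as at a
  real locus.
* **Two platform designs.** `sharedFraction` (default 0.55, matching
  the roughly half-shared content of the platform pair being emulated)
  of genes appear on both platforms. The generic platform is sense-only
  with `redundancyGeneric` (default 1.8) probesets per gene
  (1 + Poisson); the disease-specific platform carries sense and
  antisense probesets plus an orientation-unassigned stratum sized to
  `unassignedFraction` (default 0.09, mirroring the observed ~8.7%
  share) of its specific content. Probes are verbatim substrings: 11
  probes of 25 nt per probeset at random positions.
* **Replicated designs.** Four in-vitro conditions
  (parental/resistant, untreated/5-FU) in triplicate, and a 28-sample
  clinical cohort with CR/PR/SD/PD response groups (7 each — the real
  cohort's split is not published).
* **Expression with planted effects.** Log2 intensity = per-transcript
  baseline (Normal(8, 1.2) by default) + planted effect
  (`effectLog2`, default 1, for `deFraction` = 0.05 of transcripts per
  comparison, sign random) + Normal(0, `noiseSdLog2` = 0.25) replicate
  noise. The emulated study reports no effect or noise magnitudes, so
  these defaults are stand-ins: a 2-fold planted effect with 0.25 log2
  replicate noise is a clean but not trivial array signal. At these
  values the pooled t-test's analytic power at n = 3 and alpha = 0.05
  is 0.948 (noncentral t), which is what the recovery checks test
  against, with binomial tolerance.
* **Flags coupled to expression.** P above `detectP` (default 100
  linear-intensity units), M between `detectM` (default 50) and
  `detectP`, A below — thresholding the linear intensity, then
  corrupting calls at `flagFlipRate` (default 0.01). Flags are *not*
  produced by reimplementing the MAS5 detection call: the pipeline
  consumes flags, it does not define them, and a threshold-plus-noise
  model preserves exactly the property the filters rely on (detection
  tracks expression level, with occasional errors).

## Ground truth without circularity

The generator records which probesets are *truly* backed by shared
content geometrically: a probe "matches" a transcript on the other
platform when its genomic footprint lies inside that transcript's locus
(sequences at one locus derive from the same genomic sequence, so
footprint containment and exact sequence matching coincide — up to
4^-25-probability random collisions). These geometric counts are pushed
through the same bidirectional two-pass cascade as the sequence
classifier, so recovering the truth from sequences alone is a genuine
cross-check of the matching machinery, not a tautology. The same record
carries the planted differential-expression sets per comparison, the
genes with both orientations on the disease-specific platform, and each
pair's overlap category.

## What it does not emulate

Probe thermodynamics, cross-hybridisation, GC effects, batch and
spatial artefacts, trans-NATs, alternative splicing, and CEL-level data.
Sequences are uniform ACGT — composition is irrelevant to exact
matching. Consequently, passing the recovery tests shows the *pipeline
logic* is correct under clean signal; it does not certify performance on
real arrays, where probe-level noise and annotation error dominate.

# Numerical conventions

* **Rounding is half-up** everywhere a table is printed
  (`roundHalfUp()`, `percentBreakdown()`), at 2 decimals for orientation
  breakdowns and 1 for clinical percentages. One published value
  (11320/23089 printed as 49.02%) disagrees with its own counts under
  any consistent rounding (half-up gives 49.03%); this package rounds
  consistently and does not chase it.
* Hypergeometric tails are evaluated in log space; p values are clipped
  to [0, 1].
* Orientation percentages sum to 100 within 0.02 after rounding.
* All randomness flows from the configuration seed through per-stage
  streams; derived seeds stay below 2^31.

# Problem sizes

The test suite exercises generation at up to 1000 genes (binomial checks
on planted rates), content-mapping recovery at 500 genes (~1200
probesets, zero tolerated errors), SAS/category recovery at 300 genes,
and the power/null check at 1000 planted plus 1000 null transcripts —
sizes chosen so the whole suite stays fast while each stochastic
assertion retains a tight binomial band. `scripts/acceptance.R`
recomputes the same quantities from scratch at the same sizes.

# Known limitations

* The clinical cascade's one-vs-rest reference and the t-test scale are
  explicit choices where the emulated analysis is silent (see above).
* Raw p values throughout mirror the emulated analysis; treat reported
  significance accordingly.
* Exact matching cannot represent near-identical cross-platform content
  (SNPs, sequencing errors); on real platforms the common set is
  therefore a lower bound relative to a mismatch-tolerant aligner.
* The generator's effect/noise defaults are stand-ins, not estimates
  from real arrays.
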