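---
title: "Methods: the MYB family census and screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MYB family census and screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mybscan)
```

This vignette is the package's own account of its methods: the models,
the tunable parameters and why they default as they do, what the
synthetic generators emulate (and do not), and the numerical and design
choices made where the procedure left room.

# The repeat model and the scanner

MYB repeats are short (50–53 aa), tightly length-constrained
helix–turn–helix units with three regularly spaced tryptophans.
`mybscan` models the repeat as an **ungapped position-specific
log-odds profile** rather than a full profile HMM with insert/delete
states: with so narrow a length distribution, gap states buy little,
and an ungapped scanner has an exactly enumerable null model, which is
what makes honest E-value calibration possible in-package.  Users with
real HMMER runs can bypass the scanner entirely —
`hitsFromDomtblout()` maps a `--domtblout` table (envelope coordinates,
conditional E-values) onto the same downstream contract, and the test
suite checks that classification is identical through either path.

`buildProfile()` turns a seed alignment into scores
`log2(f_j(a) / q(a))` with `f_j(a) = (c_j(a) + λ q(a)) / (n_j + λ)`
(pseudocount `λ = 1` by default).  The unknown residue `X` always
scores 0, so unsequenced stretches neither help nor hurt a window.
The three canonical tryptophan columns are the W-enriched columns
(frequency ≥ 0.5) with the highest W frequency, constrained to be
pairwise ≥ 15 columns apart — the "regular spacing" of the domain
definition made operational.

The **seed alignment shipped with the package is a synthetic
stand-in** (`extdata/myb_seed_alignment_synthetic.fasta`): 30 instances
of a 52-column repeat with full-height tryptophans at columns 9/28/47
and ~70% column-wise conservation elsewhere.  It reproduces the
architecture of a curated repeat alignment without shipping one; all
package results should be read as statements about the pipeline's
machinery, not about any curated domain model.

## E-value calibration

`calibrateEvalue()` draws `nNull = 10000` i.i.d. background sequences
(composition = the seed alignment's marginal), scores them, and models
`P(score ≥ S)` as:

* the **empirical survival function** up to a tail knot (the 98th
  percentile), which makes E-values exact where data are plentiful,
  and
* a **Gumbel tail fitted by censored maximum likelihood** beyond the
  knot (tail scores enter the likelihood exactly; the bulk enters as a
  censored mass), rescaled to the empirical tail mass so the survival
  function stays continuous and monotone.

A single full-sample Gumbel ML fit was rejected: window scores are
sums of 52 bounded column scores, so their bulk is near-normal and the
extreme tail decays faster than exponential; a fit dominated by the
bulk misestimates the tail severely.  The hybrid keeps both regimes
honest, which the suite verifies by scanning fresh background at
thresholds inside the calibrated region and comparing observed hit
counts with the thresholds themselves (an E-value threshold *t* is, by
construction, the expected number of background hits).  Beyond the
deepest calibrated quantile the Gumbel continuation is an
extrapolation and tends to the conservative side; at the actual
screening threshold of 1e-5 this only makes false positives rarer.

Null sequences default to exactly one window (`nullLength` = profile
length), which keeps `E(S, N) = N · P(window ≥ S)` self-consistent
with the calibration sample.  Scanning itself is deterministic; the
calibration seed is the only stochastic input.

## Overlap resolution

Candidate windows below the E-value threshold are resolved per
transcript greedily by descending score (ties: smaller start).  True
repeats are non-overlapping by construction, so dynamic programming
would change nothing on signal and only re-rank shadows of the same
repeat; the greedy rule is simple and deterministic.

# Identification and classification rules

A detected repeat carries a **conserved tryptophan** when a W sits at
a canonical tryptophan column ± 1.  The tolerance absorbs the
off-by-one alignment jitter an ungapped envelope can introduce; it is
configurable, and ± 1 was chosen (not 0, not 2) because a zero
tolerance misses genuine repeats whose envelope slid one column, while
± 2 starts accepting background tryptophans.  A gene whose every
repeat fails the rule is not a member and never reaches the output.

**De-duplication** maps transcripts to genes via the GFF
(`mRNA`/`transcript` features; a transcript without a `Parent` is its
own gene) and keeps one representative isoform per gene: most passing
repeats, then longest transcript, then lexicographically smallest id.
The underlying convention ("count genes, not isoforms") does not
specify the representative; this rule is a declared stand-in, chosen
so that a truncated isoform can never mask a full-length architecture.

**Subfamilies** follow the repeat count (1R, 2R, 3R, 4R, 5R) with one
spacing rule, applied exactly as stated for the two-repeat case: the
gap between the two envelopes — `start₂ − end₁ − 1`, i.e. residues
strictly between them — may be at most 10 aa for 2R; gap 10 stays 2R,
gap 11 demotes to the R-R type of 1R.  Because "apart" could also be
read start-to-start, the choice of end-to-start distance is explicit
here and in the function documentation.  The rule is applied **only**
to the two-repeat case; adjacency gaps in 3R+ members are
unconstrained, since the source convention states no rule there.
More than five repeats raises an error flagged for manual review
rather than silently extending the label set.

`tabulateFamily()` reports the census in the field's shape: R-R-type
inside the 1R column, 5R members inside the 4R column with a separate
flag (the "1 *" convention).  Totals are invariants of the S4 class,
not re-derived quantities.

# Synthetic data: what it emulates, what it does not

`generateProteome()` plants repeats **emitted column-by-column from
the profile's own per-column distributions**, so scanner sensitivity
is a measured property, not a string match.  Defaults (chosen once as
a plausible plant-proteome caricature, and kept): 200 genes; repeat
counts 0/1/2/3/4/5 with probabilities .40/.20/.22/.08/.06/.04 (decoys
in the plurality, 1R+2R dominating members, 3R+ rare); inter-repeat
gaps 2–10 aa; 30% of two-repeat genes made R-R-type by construction
(gap 13–40 aa); 5% tryptophan dropout (every canonical W and its ± 1
neighbourhood replaced); 1–2 isoforms per gene, extra isoforms
optionally truncated by one repeat to exercise de-duplication.  The
truth table records actual emitted properties (intervals, per-repeat
tryptophan presence) and the label the classification rules imply —
computed by the same `assignSubfamily()` the pipeline uses, so
generator and classifier can never drift apart silently.

`generateCounts()` draws NB counts with `Var = μ + α μ²`
(`rnbinom(size = 1/α)`; α = 0 degrades to Poisson), log-normal
baseline means (meanlog = log 200, sdlog = 1), α = 0.1, a 3 + 3
drought/control design, 10% DE genes with |log2FC| uniform in
[1.5, 3].  All randomness flows from one seed through per-gene
substreams (a seed vector drawn once from the master seed), so
regeneration is stable and byte-identical.

What the generators do **not** emulate — hence what green tests do not
show about real data: sequence homology between repeats and the rest
of a real proteome (decoys are i.i.d. background, so the false-positive
landscape is cleaner than reality); domain-length variation beyond the
profile span; alternative splicing more intricate than last-repeat
truncation; library-composition artefacts, batch effects, or
count-level outliers in the RNA-seq arm.

# The DE screen

Size factors are median-of-ratios over genes with nonzero counts in
every sample, rescaled to geometric mean 1; the suite cross-checks
them against an independent implementation of the same estimator.
Normalised group means get a pseudo-count of 0.5 before the fold
change `log2(μ_drought / μ_control)` — zero-inflated genes then yield
finite, shrunken-toward-0 fold changes instead of infinities.

Dispersion is per-gene within-group method of moments, no shrinkage:
`α = max((pooled within-group variance − pooled mean) / pooled
mean-square, 1e-8)`, where the pooled mean-square averages the
*squared group means* (df-weighted).  Dividing instead by the square
of the grand mean would inflate α for genes with a genuine fold change
(for a 4-fold gene, by ~36%), taxing power exactly where it matters;
the group-aware form is unbiased under the NB model and identical for
null genes.

The Wald statistic divides the fold change by its delta-method
standard error, `SE² = [(1/μ_d + α)/n_d + (1/μ_c + α)/n_c] / ln²2`,
and is referred to a **t distribution with `n_d + n_c − 2` degrees of
freedom** rather than a normal.  With three replicates per group the
plug-in dispersion is noisy, and a normal reference is anticonservative
by more than a factor of two at the 5% level; the t reference restores
nominal calibration, which the acceptance suite measures directly on a
5,000-gene null simulation.  Screening applies the stated criteria
verbatim and strictly: raw p < 0.05 (no multiple-testing adjustment —
a BH option exists but is off by default) and |log2FC| > 1, boundary
values excluded.  Because the screen re-implements the test
transparently (no dispersion shrinkage, no independent filtering, no
LFC moderation), per-gene calls on real data can differ from pipelines
built on moderated estimators.

One behaviour worth knowing: median-of-ratios assumes most genes are
not differentially expressed.  If a large fraction shifts in one
direction, normalisation absorbs part of the fold change (planting
log2FC = 2 in half the genes costs the estimate about one unit).  The
power analyses therefore plant effects in a 10% minority, which is
also the realistic regime.

# Phylogeny

Members of the deep subfamilies (3R/4R/5R) are aligned
**profile-anchored**: each repeat occupies one profile-length block of
columns, members with fewer repeats are padded with gap blocks, and
distances use pairwise deletion so padding never contributes.  This
replaces an external aligner with a deterministic construction that is
exact where it matters (repeats are already column-aligned by the
scanner).  Distances default to the Poisson correction
`−ln(1 − p)` (a common default for proteins), with the raw
p-distance available by flag; saturated pairs (p ≥ 1) are an error
rather than an infinity.

`neighborJoining()` is the canonical agglomerative algorithm:
Q-matrix minimisation, ties broken by the lexicographically smallest
pair (taxa are sorted on entry, so the first minimal pair in scan
order is that pair — and the same matrix always yields the same
tree regardless of input order).  Negative branch estimates are
clamped to zero with the length moved to the sibling so path lengths
are preserved; the count of clamped branches rides along as an
attribute.  On additive matrices the algorithm recovers the
generating topology and branch lengths exactly (checked to 1e-9 on
random 4–8 taxon trees), and on non-additive matrices it agrees
topologically with an independent implementation.

Bootstrap support resamples alignment columns, rebuilds the tree, and
scores each internal bipartition of the full-data tree by its
replicate frequency (0–100).  The default of 1000 replicates follows
the standard practice for this analysis; replicates whose resample
produces a degenerate distance matrix are dropped from the
denominator.

# Problem sizes and determinism

The shipped test suite runs everything at desk scale: 10,000 null
windows for calibration, 10,000 background sequences for the honesty
check, 200-gene proteomes for recovery, 100 + 50 random matrices for
the NJ oracles, 5,000-gene null and 3,000-gene planted simulations for
the screen.  These sizes put Monte-Carlo error comfortably inside the
tolerances being asserted while keeping a full run in tens of seconds.
Every stochastic stage takes an explicit seed; given one config the
pipeline's written outputs are byte-identical across reruns, which the
suite asserts literally.

# Known limitations

* The scanner is ungapped; repeats with internal indels relative to
  the profile lose score linearly and can drop below threshold.  Real
  HMMER results can be ingested instead.
* The synthetic seed alignment means absolute E-values and bit scores
  are not comparable to PF00249-based numbers; only the machinery is.
* The spacing rule's ± 1 tryptophan tolerance and the
  representative-isoform rule are declared conventions, not
  discoveries; alternatives (start-to-start gaps, longest-isoform
  representatives) would change individual labels.
* The DE screen's raw-p criterion is deliberately faithful to the
  stated screening rule; at 5% per gene it implies a known
  false-positive load across thousands of genes, and the BH flag
  exists for users who want control of the FDR instead.
* 12-species census arithmetic is exercised from a transcribed
  reference table; reproducing such a census from scratch requires the
  genome downloads themselves, which are out of scope here.
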