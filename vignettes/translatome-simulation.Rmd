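---
title: "Models and design choices behind translatomeSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind translatomeSim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models the package implements, why the defaults
are what they are, and what the simulations can and cannot say about real
data.

## Ribosome association and the gradient model

Each gene's per-molecule ribosome load is a normal law clamped at zero,
`max(N(μ, σ), 0)`. Clamping (rather than resampling) keeps the sub-polysome
probability mass that strong translational inhibition creates: a gene driven
to μ = 1 ribosome deposits a substantial fraction of its molecules at zero
ribosomes (free mRNPs), which is exactly the biology a heavy shift to
sub-polysomal fractions represents. Truly sub-80S behaviour cannot be
expressed by a normal law at all, which is why the inhibited state is pinned
at a mean of one ribosome throughout.

Sedimentation in a 5–50% sucrose gradient is modelled as a power law
`d(n) = (n / n_max)^α` on a normalised [0, 1] axis, rescaled piecewise so
the 80S monosome sits at `monosome_position` (default 0.25) and `n_max`
(default 20) ribosomes reach the gradient bottom. Sedimentation coefficients
grow sublinearly with particle mass; α = 0.6 approximates that scaling, and
all three parameters are user-visible (`gradient:` block of the run config).
The exact empirical ribosome-to-distance curve of any particular gradient
rig is unknowable from first principles, so the form is an explicit,
configurable model, not a fitted constant.

`simulate_absorbance_trace()` renders a distribution as an A254-like
tracing: molecules are binned at integer ribosome counts, each bin becomes a
narrow Gaussian peak (width `peak_sd = 0.015` of the gradient length) at its
mapped position, noise is added, and the curve is normalised to unit area so
absorbance units never matter. `fit_ribosome_distribution()` inverts this
with a deterministic coarse-to-fine grid search on (mean, sd) — two
refinement passes ending at a 0.005-ribosome step — chosen over a gradient
optimiser so that repeated fits are bit-identical and free of starting-point
sensitivity. The fit assumes the same peak width used for rendering; on
noiseless traces it recovers planted parameters essentially exactly, and the
tests require 5% (mean) / 10% (sd) even near the sub-polysome regime.
Diffusion, fraction mixing and the 40S/60S peaks are deliberately not
modelled.

## The two profiling estimators

For a gene with molecule loads `x₁…x_m`:

* polysome-profiling readout: `mean(x_i > 3)` — the conventional "more than
  three ribosomes" definition of efficient translation. Sampling `m`
  molecules per replicate makes the replicate-level estimate Binomial(m, p)/m,
  so counting noise is built in.
* ribosome-profiling readout: one draw from a counting distribution
  (Poisson by default, negative binomial optionally) with expectation
  `mean(x) × abundance × depth_factor` — footprints scale with both load and
  copy number.

Per-gene differential calls use the fold change of geometric means and a
Welch t-test on log2 estimates across replicates. The package does not claim
this is the only defensible test; the bias phenomena below are driven by the
estimators, not the test. Pseudocounts are applied by the experiment driver
before testing: half a read for counts, half a molecule (0.5/m) for
proportions — a fixed 0.5 added to a quantity bounded by 1 would drown the
signal. Two numerical edge cases are pinned down: identical degenerate
replicates give p = 1, and zero-variance groups with different means
(perfect separation, which saturated proportions can produce) give the
smallest representable double so p stays in (0, 1] and ranking ties resolve
lexicographically by gene id.

## Why the shift-grid experiment behaves as it does

The shift experiment draws six equal gene classes with control means
{6, 8, 10, 12, 14, 16} ribosomes, all collapsing to mean 1 (sd 1.5) under
treatment, 200 molecules per gene per replicate, 4 replicates, log-normal
abundance (median 2, sdlog 1), and selects the top 10% of genes per ranking.
Two properties of the estimators drive the headline result:

* The polysome proportion saturates: every control mean in the grid puts
  `P(load > 3)` between 0.95 and 1, so the *size* of a shift barely changes
  the readout — the estimator reports that a gene moved, not how far. With
  p-value ranking the selection is therefore nearly class-blind, and the
  residual bias sum (~7–12 points) matches the multinomial noise floor of an
  unbiased draw of 300 genes from 3000.
* Footprint counts are low (tens of reads for the median gene) and scale
  with the shift, so both the ribosome-profiling fold change and its
  statistical power order by shift size; selection over-represents large
  shifts under either ranking.

Control means below ~5 would break the first property — a gene whose
control state straddles the three-ribosome boundary is not an "efficiently
translated mRNA shifting out of polysomes", and its proportion estimator
becomes shift-size sensitive. That is why the grid starts at 6. Class count
(500 genes per class) was sized so the ribo-vs-poly bias ordering is stable
in every individual simulation, not just on average; with 4 replicated
simulations the per-class polysome deviation concentrates well under 5
percentage points.

Seeding: a master seed spawns per-(simulation, replicate, gene) streams via
an integer hash, so enlarging the gene set never perturbs existing genes'
draws. The population sweeps below use per-(simulation, sweep-point,
replicate) streams with vectorised sampling instead, trading stream
granularity for tractable runtimes.

## Absolute vs relative quantification in the population sweeps

The population model has three classes: TOP mRNAs (3.5% of genes, 8× the
baseline abundance, control mean 6 → treated 1), non-TOP MTOR-sensitive
mRNAs (16.5%, control 5 → treated 3.5, the "intermediate-heavy to light"
shift), and nonmovers (80%, mean 5 in both conditions).

"Relative" quantification means different operations for the two readouts,
and this asymmetry is the substance of the comparison:

* Ribosome-profiling counts come out of a fixed sequencing budget. The
  package scales every replicate (both conditions jointly) to the grand mean
  total — ordinary library-size normalisation. This weights genes by their
  share of footprints, which the abundant, heavily loaded TOP class
  dominates: when TOP translation collapses, every other gene's relative
  count inflates in the treated libraries, attenuating measured
  control/treated fold changes transcriptome-wide.
* Polysome proportions are internally normalised per gene, so the natural
  "relative" operation is `global_center()`: dividing fold changes by their
  geometric median, making the median log2 fold change exactly zero. With
  80% nonmovers the median gene is a nonmover and centring is nearly
  inert.

An unweighted median centring applied identically to both technologies
would, by construction, remove any library-wide factor and erase the
difference between them; the attenuation that pushes non-TOP fold changes
below twofold under ribosome-profiling exists precisely because count data
are normalised by a count-weighted total. The package therefore reports the
median-log2-zero invariant for the polysome relative mode only. "Absolute"
mode is the spike-in idealisation: a fixed `depth_factor` in both
conditions, under which measured fold changes match the simulated truth up
to counting noise.

The TOP-fraction sweep rebuilds the population at each point so that a
fraction f of all genes are TOP mRNAs undergoing their full shift (nonmovers
absorb the remainder; non-TOP genes always shift). The reduction sweep
multiplies only the nonmover treated means by each factor, per the narrower
reading of "a reduction in translation for nonmover mRNAs"; reducing all
classes proportionally is an easy configuration change but is not the
default.

## The zero-shift null

Type-I calibration is checked at the nonmover regime (control = treated =
5 ribosomes). At saturated means (≥ 6) the polysome proportion is exactly 1
in every replicate, the t statistic is undefined, and no p-value
distribution exists — a null check there would be meaningless rather than
failed. At mean 5 both estimators have genuine sampling variance; the tests
require Kolmogorov–Smirnov uniformity (p > 0.01 at 1000 genes) and median
fold changes within 10% of 1 for both readouts.

## The synthetic nanoCAGE generator and its limits

`make_toy_transcriptome()` lays transcripts at 2 kb spacing on one synthetic
chromosome per strand, with planted TSSs, start codons, UTR length classes
(short < 30 nt), TOP motifs (cap C plus a sampled 4–15 pyrimidine run) and
TISU elements (`SAASATGGCGGC` across the AUG). Planting is rejected and
resampled until every flag round-trips through the package's own
classifiers, so label-recovery tests measure the pipeline, not generator
luck. A transcript carrying both motifs needs ≥ 9 nt of UTR so the
pyrimidine run ends before the TISU's upstream half; impossible requests
(e.g. a TISU in a 3-nt UTR) raise a generation error. A configurable 30% of
transcripts get a RefSeq-style reference TSS annotating a 2.2× longer UTR,
which is what the reference-comparison summary (fraction of UTRs at half the
reference length or shorter) recovers.

`simulate_ctss()` scatters per-transcript tag totals (negative binomial,
dispersion 0.1, scaled by a log-normal abundance with sdlog 0.4 around 200
tags per transcript) as discretised Gaussian jitter (sd 2 nt) around the
TSS, clipped so no signal tag lands downstream of the start codon, plus
uniform background. At these depths the empirical mode of ~200 jittered
tags identifies the TSS to within ±1 nt for ≥ 95% of supported transcripts
(> 50 assigned reads); transcripts sequenced much shallower would not meet
that bar, which mirrors why the real protocol was sequenced to a plateau.
The generator has no sequencing-error, PCR-duplicate or UMI model, no
template-switching artifacts, and its background is uniform — so passing
recovery tests demonstrate the downstream arithmetic, not robustness to
every nanoCAGE artifact.

Peak calling clusters per-position tags within `max_gap = 20` nt (the read
thresholds ">5" and ">50" are strict inequalities as conventionally
printed; the gap itself is a free parameter). Peak summits take the leftmost
maximum within a cluster; per-transcript peak lengths break count ties
toward the start codon. Peaks are assigned to the nearest transcript whose
start codon lies within 1 kb downstream of the summit. TOP runs longer than
15 pyrimidines still classify as TOP — the 4–15 range is read as observed
variation, not an exclusion rule — and the TISU mismatch budget defaults to
0 with the AUG invariant. Enrichment testing is a one-sided exact
hypergeometric tail with the background excluding the query set by default.

## Problem sizes and runtime

Defaults were sized for a laptop-class single core: the shift experiment
(4 simulations × 3000 genes × 4 replicates × 2 conditions × 200 molecules)
runs in about half a minute; each sweep (7 or 6 points × 4 simulations ×
2000 genes) in 15–30 s; the full pipeline and the acceptance script in
about two minutes each. All sizes are configuration values, and the test
suite exercises reduced configurations of the same models.

## Known limitations

* The ribosome→distance power law and the per-class shift magnitudes are
  stated models, not fitted to any particular gradient or cell line.
* The simulator works at per-mRNA ribosome counts; there is no
  nucleotide-resolution footprint model (no codon dwell, no P-site offsets).
* Polysome-profiling is idealised as an exact per-molecule threshold;
  fraction pooling, gradient mixing and RT-qPCR/library noise between
  fractions are not modelled beyond molecule sampling.
* Conclusions about which technology "wins" are conditional on the
  population structure (abundance gap, shift sizes, nonmover share); all of
  these are exposed in `population_config()` precisely so they can be
  varied.
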