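# translatomeSim

Tools for studying why polysome-profiling and ribosome-profiling can disagree
about which mRNAs change translation when MTOR is inhibited, together with a
nanoCAGE-downstream pipeline that derives 5′ UTR features (TSS peaks, UTR
lengths, 5′ TOP motifs, TISU elements) from 5′-end tag counts.

## The problem

The two standard translatome readouts measure different things:

* **Polysome-profiling** separates mRNAs on a sucrose gradient and scores a
  gene by the *proportion of its molecules associated with more than three
  ribosomes* — a per-gene, saturating quantity.
* **Ribosome-profiling** sequences ribosome-protected fragments and scores a
  gene by its *footprint count*, proportional to (mean ribosome load) ×
  (mRNA abundance) and embedded in a fixed sequencing budget.

Model per-gene ribosome association as a normal law clamped at zero,
`max(N(μ, σ), 0)`, with MTOR inhibition collapsing every regulated gene to
μ = 1 ribosome from class-specific control means. Both readouts are then
simulated over replicates, tested gene by gene (Welch t on log2 estimates;
fold change as the ratio of geometric means), ranked, and the top fraction
selected. Because the polysome estimator saturates for well-translated
mRNAs, its ranking is nearly independent of shift size, while footprint
counts — low for most genes and proportional to the shift — make
ribosome-profiling favour large shifts and abundant mRNAs. The package
quantifies this as a per-shift-class selection **bias**
(observed − expected selection percentages, and their absolute sum).

A second axis contrasts **absolute vs relative quantification** for
populations of TOP mRNAs (abundant, large shifts), non-TOP MTOR-sensitive
mRNAs (moderate shifts) and nonmovers: for count data, relative
quantification is library-size normalisation, which is dominated by the
abundant TOP class; for per-gene polysome ratios it is geometric-median
centring. The sweeps show how a shrinking read budget share pushes measured
non-TOP fold changes below the conventional twofold threshold under
ribosome-profiling.

The `utr` functions implement the nanoCAGE downstream stack on 0-based,
strand-aware coordinates: gap-based CTSS clustering with "more than five
reads" peaks, peak and weighted-mean 5′ UTR lengths, TOP classification
(cap C + ≥4 pyrimidines), TISU matching (`SAASATGGCGGC` across the AUG),
reference-annotation length ratios, and exact hypergeometric enrichment.
Every input the pipeline consumes can be generated synthetically with
planted, machine-readable ground truth.

## Worked example

```r
library(translatomeSim)

# polysome readout of four molecules with 1..4 ribosomes
estimate_polyprof(c(1, 2, 3, 4))
#> [1] 0.25

# TOP motif and TISU element calls
classify_top("CTTTCAGG")        # C + 4 pyrimidines -> TRUE
detect_tisu("CAAGATGGCGGC")     # matches SAASATGGCGGC -> TRUE

# selection bias of the two technologies across a grid of shift sizes
ex <- run_shift_experiment(simulation_config(), seed = 1)
ex
#> <shift_experiment> 4 simulations, 3000 genes each
#>  method     ranking bias_sum_mean bias_sum_sd
#>    poly fold_change     14.500000    2.202692
#>    ribo fold_change     88.500000    5.288002
#>    poly      pvalue      7.333333    2.828427
#>    ribo      pvalue     25.333333    3.355482
```

With p-value ranking, polysome-profiling selects almost exactly the expected
share of every shift class (bias sum ≈ 7 percentage points, within selection
noise), while ribosome-profiling over-selects the largest shifts (≈ 25).
With fold-change ranking both are biased, but polysome-profiling remains
far less so (≈ 15 vs ≈ 89).

```r
# centred (relative) fold changes when 3.5% of mRNAs are shifting TOP mRNAs
sw <- sweep_top_changing_fraction(population_config(), seed = 2)
subset(sw$sweep, sweep_value == 0.035 & class == "NONTOP" &
                 quantification == "relative")
#>    sweep_value  class method quantification fold_change
#> 52       0.035 NONTOP   poly       relative    1.433950
#> 72       0.035 NONTOP   ribo       relative    1.112024
```

The true simulated non-TOP shift is ≈ 1.43-fold; under ribosome-profiling's
library-size-relative counts it is further attenuated to ≈ 1.11 — well below
the conventional twofold threshold.

The full pipeline (generators → gradient fit → simulations → sweeps → UTR
annotation → diagnostics) runs with

```r
run_pipeline(default_run_config(), seed = 1, out_dir = "run")
```

or from a shell via `inst/scripts/translatome-sim.R run --seed 1 --out run`,
writing TSV/JSON outputs and a checksummed manifest; identical seeds
reproduce identical files.

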