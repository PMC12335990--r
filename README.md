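# ThermoBench

A statistical workbench for thermal proteome profiling (TPP/CETSA)
experiments with TMT labeling. TPP detects protein–drug interactions by
heating treated and vehicle samples across a temperature ladder and
quantifying how much of each protein stays soluble; an interaction shows up
as a shift between the two melting profiles. ThermoBench is for proteomics
analysts and methodologists who need to (a) process reporter-ion
quantification tables into comparable protein profiles, (b) run the
competing per-protein statistical models side by side, and (c) measure
calibration, power, and design trade-offs on simulated ground truth before
committing to an experimental layout.

## What is implemented

**Processing.** Both community protocols: the reference-ratio protocol
(per-profile ratios to the reference channel, a "NormSet" of canonically
melting proteins, and sigmoid-derived per-temperature factors
*Q<sub>t</sub>*), and the summarization protocol (log2 transform, feature
filters, left-censored AFT imputation, Tukey median polish, and
reference-channel alignment across plexes), plus global median
normalization for pooled ("OnePot") group-comparison designs.

**Models.** For each protein:

* sigmoid melting curves
  *f(T) = (1 − p)/(1 + e^(b − a/T)) + p* with the replicate-level
  ΔT<sub>m</sub> decision rule;
* natural-spline fits (df = 5) compared full versus reduced by
  *F = ((RSS₀ − RSS₁)/d₁)/(RSS₁/d₂)* with empirical-Bayes moderation of
  the denominator, reference *F(d₁, d₀ + d₂)*;
* NPARC: the same F on per-condition sigmoid fits, an *R² > 0.8* /
  plateau < 0.3 quality filter, and empirically rescaled degrees of
  freedom from scaled-χ² fits to the across-protein RSS distributions;
* a monotone shape-constrained additive model (k = 5) with replicate
  intercepts and a Wald test on the difference in means (DIM);
* a mixed-effects cell-means model
  *Y<sub>crt</sub> = μ<sub>ct</sub> + b<sub>cr</sub> + ε<sub>crt</sub>*
  testing the treated-minus-vehicle contrast averaged over a
  pre-specified temperature subset (default indices {6,7,8}), with both
  variance components estimated from all temperatures and Satterthwaite
  degrees of freedom; OnePot designs reduce to a one-way ANOVA.

All models end with Benjamini–Hochberg adjustment and an FDR 0.05 decision.

**Simulator.** Ground-truth strong/weak/null interaction templates over the
ladder 37.3–67 °C, two variance components (σ²<sub>error</sub> = 0.267;
σ²<sub>bio</sub> = 0.014 or 0.178, i.e. ICC 5% or 40%), OnePot pooling by
unlog–average–relog, and a catalog of thermal and OnePot designs trading
temperatures for biological replicates.

## Worked example

Intra-class correlation of the two simulated variance settings:

```r
library(ThermoBench)
round(100 * c(icc(0.014, 0.267), icc(0.178, 0.267)))
#> [1]  5 40
```

Simulate the three interaction templates at ICC 40% under two designs —
`T-F` (2 replicates, 10 temperatures, null hypothesis on the subset
{6,7,8}) and `T-G` (10 replicates, 2 temperatures, 4 plexes) — and measure
the proportion of p-values below 0.05:

```r
study <- runSimulationStudy(templates = c("strong", "weak", "null"),
                            designs = c("T-F", "T-G"),
                            sigma_bio_sq = 0.178,
                            n_instances = 200, seed = 42)
subset(study$power, cutoff == 0.05)
#>    template design icc cutoff   n proportion
#> 2    strong    T-F 0.4   0.05 200      0.200
#> 4      weak    T-F 0.4   0.05 200      0.070
#> 6      null    T-F 0.4   0.05 200      0.075
#> 8    strong    T-G 0.4   0.05 200      0.940
#> 10     weak    T-G 0.4   0.05 200      0.215
#> 12     null    T-G 0.4   0.05 200      0.045
```

Reading the table: for interacting templates (`strong`, `weak`) the
proportion is the power; for the non-interacting template (`null`) it is
the empirical type-I error, which should sit near 0.05. Trading
temperatures for biological replicates (design `T-G`) lifts power for the
strong interactor from 20% to 94% at the same per-condition cost, without
inflating the false-positive rate. `study$calibration` carries the
20-bin p-value histograms, Kolmogorov–Smirnov distances, and 99% binomial
bands used to judge the null cells.

## Methods

The model equations, default parameters and their rationale, the simulator's
study conditions, numerical tolerances, and known limitations are documented
in `vignettes/thermal-profiling-methods.Rmd`.
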