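---
title: "Statistical methods for thermal proteome profiling in ThermoBench"
author: "ThermoBench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for thermal proteome profiling in ThermoBench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThermoBench)
```

## The problem

Thermal proteome profiling (TPP, the mass-spectrometry descendant of CETSA)
detects protein-drug interactions by heating treated and vehicle samples to a
ladder of temperatures, quantifying the protein left in solution at each
temperature with TMT reporter ions, and asking whether the melting behavior
shifts with treatment. The statistical step is harder than it looks: the
treatment effect is a shift between two noisy, nonlinearly decaying curves;
biological replicates and within-run measurement error contribute variance on
different levels; and several reasonable-looking analysis pipelines give
substantially different answers on the same data.

ThermoBench implements, side by side, the data-processing protocols and the
four per-protein models in common use, plus a ground-truth simulator, so that
calibration (type-I error of non-interactors) and sensitivity (power for
interactors) can be measured under controlled conditions and competing
experimental designs can be compared before any sample is spent.

## Data model

The central objects are long-format tables keyed by protein, condition
(vehicle/treated), biological replicate, and temperature index
$t = 0, \dots, T$, where $t = 0$ is the reference channel when present,
otherwise the lowest temperature. `StudyDesign` maps TMT channels of each
plex to those keys and carries the channel role; carrier and empty channels
are dropped at read time and never enter any table. Missing feature
intensities are explicit `NA` records rather than absent rows, so
missingness rules can be applied deterministically.

## Processing protocols

**Reference-ratio protocol** (used upstream of the sigmoid, spline, and
NPARC models): each profile is divided by its reference-channel abundance;
a normalization set of canonically melting proteins is selected by requiring
the ratios at temperature indices 6, 8 and 9 to fall inside configured
bounds in every condition-replicate group; a sigmoid is fit to the median
ratio profile of each group, the group with the best $R^2$ wins, and the
per-temperature factors $Q_t = \text{fitted}_t / \text{median}_t$ (with
$Q_0 = 1$, so the reference column is never rescaled) multiply all ratios.
No canonical numeric bounds for the normalization set exist, so the defaults
(ratio $\le 0.6$ at index 6, $\le 0.3$ at index 8, $\le 0.2$ at index 9,
all $\ge 0$) encode the intent — exclude thermostable proteins — and are
deliberately exposed in `processingConfig()`.

**Summarization protocol** (used upstream of the mixed model, and of SCAM on
the log scale): log2 transform; removal of features shared between protein
groups, of feature-plex blocks with more than three missing channel
intensities (a block with exactly three is kept), and of proteins left with
a single feature, in that order; imputation of remaining missing channels by
a left-censored Gaussian location-scale regression with additive feature and
channel effects, censored at the block minimum (when that censored fit does
not converge — e.g. on degenerate, noise-free blocks — an additive
least-squares prediction capped at the censoring threshold is used instead);
Tukey median polish per protein and plex (rows first, convergence when the
total absolute residual changes by less than 1e-6, at most 100 sweeps), the
channel summary being overall plus column effect; and additive alignment of
each plex to the cross-plex median reference value. Global median
normalization across channels is available but off by default for thermal
designs, where abundance is expected to fall with temperature; it is turned
on for OnePot group-comparison designs.

## The four models

**Sigmoid (early TPP).** $f(T) = (1-p)/(1+e^{\,b - a/T}) + p$ fit by
bounded Levenberg-Marquardt least squares ($p \in [0, 1.5]$), multi-started
from five deterministic initializations spanning the observed temperature
range, with a final polish refit; ties in RSS go to the earliest start, so
fits are reproducible. $T_m = a/b$ is where the curve crosses midway
between 1 and $p$. The replicate-level decision rule calls an interactor
only when the $\Delta T_m$ signs agree, every replicate has $p < 0.05$, at
least one has $R^2 > 0.8$, and all lower plateaus are below 0.3 — strict
inequalities, so boundary values fail.

**Natural-spline F-test (current TPP).** Natural cubic splines with $d = 5$
degrees of freedom (the analysis setting; $d = 4$ is the economical
alternative), fit per condition (full) and shared (reduced), compared by
$F = \frac{(RSS_0 - RSS_1)/d_1}{RSS_1/d_2}$ and moderated empirical-Bayes
style: the denominator becomes
$\tilde s^2 = (d_0 s_0^2 + d_2 s^2)/(d_0 + d_2)$ with $(d_0, s_0^2)$
estimated across proteins by moment-matching of log variances against a
scaled F prior, and the reference distribution is $F(d_1, d_0 + d_2)$.
Estimates of $d_0$ above 1e6 are treated as infinite, where the denominator
collapses to $s_0^2$.

**NPARC.** The same F statistic on per-condition versus shared sigmoid fits
(replicates pooled within condition), preceded by the quality filter
($R^2 > 0.8$ and plateau $< 0.3$; by default both conditions must pass —
the alternative of requiring one is a documented option because usage
varies), and followed by empirical rescaling: the across-protein
distributions of $RSS_0 - RSS_1$ and $RSS_1$ are each approximated as
$\sigma_0^2\,\chi^2(d)$ with a shared scale, estimated by joint maximum
likelihood from method-of-moments starts, and each protein's F is referred
to $F(d_1^{\text{eff}}, d_2^{\text{eff}})$. Scaling both collections by a
common factor leaves all p-values unchanged.

**Shape-constrained additive model.** Per-condition monotone-decreasing
smooths built from $k = 5$ B-spline basis functions whose coefficients are
cumulative sums of non-positive increments (a non-increasing coefficient
sequence yields a non-increasing B-spline), with knots at quantiles of the
observed temperatures, a ridge of 1e-6 on the increments for
identifiability, and sum-to-zero replicate intercepts. The constrained
least-squares problem is solved by a box-constrained quasi-Newton pass
followed by exact re-solution on the inactive set, so solutions are
deterministic to machine precision. The test statistic is the difference in
means (DIM) between the condition smooths averaged over the observed
temperatures, divided by a standard error obtained from the exact variance
of that linear functional under the two-component error model; it is
referred to the standard normal.

**Mixed-effects cell means.** $Y_{crt} = \mu_{ct} + b_{cr} +
\varepsilon_{crt}$, with one fixed mean per condition-temperature cell, a
biological replicate intercept $b_{cr} \sim N(0, \sigma^2_{bio})$ (vehicle
and treated replicates are distinct biological samples, so effects are
drawn per condition-replicate), and residual noise. The reference channel
is discarded before fitting experimental data. The null hypothesis is a
contrast: the treated-minus-vehicle difference averaged over a
pre-specified temperature subset $S$ (default indices $\{6, 7, 8\}$ — the
7th to 9th temperatures, where melting curves separate most), while both
variance components are estimated from **all** fitted temperatures.

### Why the contrast variance comes from mean squares

For balanced complete data the REML estimates coincide with the classical
ANOVA decomposition into a between-replicate mean square ($E[MS_{rep}] =
\sigma^2_{error} + T\sigma^2_{bio}$, $2(R-1)$ df) and a residual mean
square ($2(R-1)(T-1)$ df). The contrast variance is the positive
combination

$$\hat V = \frac{2}{RT} MS_{rep} + \frac{2}{R}\Big(\frac{1}{|S|} -
\frac{1}{T}\Big) MS_{err},$$

with Satterthwaite degrees of freedom over the two independent mean
squares, floored at 1. This form was chosen deliberately over plugging the
truncated REML components into the same formula: with two replicates,
roughly one balanced fit in seven estimates $\hat\sigma^2_{bio} = 0$ at
the boundary, and conditioning on that event the truncated plug-in test
has a measured type-I error near 24% at ICC 40%. The mean-square form
never truncates, is exactly a Student $t$ with $2(R-1)$ df whenever
$S$ equals the fitted temperatures (and exactly the pooled two-sample
$t$-test when a single temperature is both fitted and tested), and keeps
the overall empirical size close to nominal. Unbalanced or incomplete
profiles fall back to lme4/lmerTest with the standard Satterthwaite
machinery; the fit records which route was taken.

**OnePot designs** pool the heated aliquots of one replicate into a single
channel, reducing the experiment to a group comparison; inference is then a
per-protein fixed-effects one-way model with pooled residual variance,
testing each dose against vehicle. All models end with Benjamini-Hochberg
adjustment across proteins and an FDR cutoff of 0.05.

## The simulator and its study conditions

Templates are condition-by-temperature surfaces of log2 means over the
ten-temperature ladder 37.3-67 °C. The published template surfaces (model
fits to three reference proteins) are not printed anywhere recoverable, so
the package uses parametric surrogates and documents them as such: a
soluble-fraction sigmoid $p + (1-p)/(1 + e^{(T - T_m)/s})$ on top of a
log2 baseline of 15, with lower plateau $p = 0.05$ (near-complete
aggregation at the top of the ladder), vehicle midpoint 52 °C (central in
the ladder), and steepness $s = 2$ °C, giving a 10-90% transition of about
9 °C — typical of protein melting transitions. Strong and weak
interactions shift the treated midpoint by +3 °C and +1 °C; the null
template averages the two curves and duplicates the average. Under these
choices the strong/weak separation at the two-temperature subset
$\{6, 7\}$ (57 and 61.8 °C), where the curves separate most, is cleanly
ordered — which is what the design-comparison claims require of a
surrogate.

Noise follows the two-component model: one biological effect per
condition-replicate with $\sigma^2_{bio} \in \{0.014, 0.178\}$
(intra-class correlations of 5% and 40%, the representative quantiles of
the experimental datasets) and i.i.d. technological noise with
$\sigma^2_{error} = 0.267$ (the median residual variance of the reference
fit); between-plex variation is taken as negligible and no plex effect is
simulated. OnePot instances pool the simulated noisy values by
unlog-average-relog, reflecting physical pooling before labeling. Instance
$k$ draws from a deterministic substream of the global seed (a
multiplicative spread keeps substreams of different seeds disjoint), so
instance $k$ is identical regardless of batch size and any run is exactly
reproducible from its seed.

What the simulator does **not** emulate: feature-level data and
missingness (simulated instances are already protein-level), plex batch
effects, non-Gaussian heavy tails, and correlation between replicates of
different conditions. Passing the simulation-based checks therefore
demonstrates correct behavior of the statistical machinery under the
stated error model, not robustness to every artifact of real spectra.

The design catalog encodes the studied layouts: thermal designs with 2
replicates and all ten temperatures (testing all, or only the subset
$\{6,7,8\}$), a two-temperature variant, and a 10-replicate
two-temperature variant allocated to four plexes; OnePot designs with 10,
5, or 2 replicates pooling temperatures $\{6, 7\}$.

## Numerical choices

* Sigmoid fits: bounds $p \in [0, 1.5]$, $a, b > 0$; five deterministic
  starts; LM tolerances 1e-12 with a 1e-15 polish; flat profiles (zero
  total sum of squares or non-positive $R^2$) are flagged unconverged
  rather than reported as fits.
* Negative $RSS_0 - RSS_1$ from numerical noise is clipped to zero
  (p-value 1); a zero full-model RSS yields an infinite statistic, p-value
  0, flagged.
* Median polish: rows-first sweeps, absolute-change tolerance 1e-6,
  100-sweep cap; missing cells are excluded from each median when
  imputation is disabled.
* Moderation: $d_0$ capped at 1e6 and then treated as infinite;
  empirical-Bayes chi-square fits use log-parameterized BFGS with
  method-of-moments starts and fall back to the moment estimates on
  divergence (recorded in the result).
* SCAM: ridge 1e-6; active-set polish iterated at most 20 times;
  monotonicity is verified in tests on 1000-point grids at tolerance 1e-8.
* Ties in the normalization-set sigmoid selection break by condition then
  replicate order; ties in sigmoid multi-start by the earliest start.

The test suite and the reproduction script size their simulations to run on
one CPU in minutes: 1000 instances per calibration cell, 500 per power
cell, 200 refits for variance-component recovery, and 2000 instances for
the moment checks. These sizes give Monte-Carlo standard errors well below
the margins they are checked against (e.g. ±0.7% on a 5% proportion at
n = 1000).

## Known limitations

* With two replicates per condition the between-replicate variance carries
  only 2 degrees of freedom, and any Satterthwaite-type subset contrast is
  mildly liberal at high ICC: the empirical size at the 0.05 level and ICC
  40% is about 0.06-0.07 rather than 0.05. The effect shrinks quickly with
  more replicates and vanishes when the tested subset equals the fitted
  temperatures (the exact-t case). Histogram-level uniformity — the
  practical calibration standard — holds throughout.
* The surrogate templates are stylized; absolute power numbers depend on
  them, while design *orderings* (more replicates beat more temperatures;
  pooled designs hold their own) are the robust conclusions.
* The NormSet ratio bounds are conventions, not estimated quantities;
  results of the ratio protocol can be sensitive to them on thermostable
  proteomes.
* The SCAM standard error treats the active constraint set as fixed, the
  usual approximation for shape-constrained estimators; its test is known
  to be less well calibrated than the mixed-model contrast, and the
  package reports it as one model among four rather than a recommendation.
* 2D (temperature x concentration) surfaces and spectral preprocessing are
  out of scope; inputs are quantification tables.
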