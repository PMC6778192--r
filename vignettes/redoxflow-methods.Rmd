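---
title: "Optical redox ratio analysis of two-photon metabolic images: methods and design"
author: "redoxflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical redox ratio analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxflow)
```

## The measurement and the model

Cells carry two endogenous fluorophores that report on metabolism: NADH
(excited near 755 nm, emitting around 460 nm) and FAD (excited near 860 nm,
emitting around 525 nm). The **optical redox ratio** of a pixel is

$$r = \frac{F}{F + N},$$

where $F$ and $N$ are the FAD and NADH fluorescence intensities after
normalization. High ratios associate with oxidative stress and
glutaminolysis; low ratios with glycolysis and fatty-acid metabolism. In 3D
silk-scaffold tumor constructs the scaffold itself autofluoresces, so a
fluorescence-lifetime filter is needed to restrict the analysis to cellular
pixels.

The pipeline implemented here takes raw two-channel fields (plus an
optional TCSPC decay stack per field) through five stages:

1. **Normalization.** Each channel is divided by $P^k G$ with excitation
   power $P$, detector gain $G$ and exponent $k = 2$ by default. Two-photon
   excited fluorescence scales with the *square* of excitation power, so
   the quadratic convention makes the generator's power scaling exactly
   invertible; the exponent is exposed for instruments calibrated
   differently.
2. **Co-registration.** The two channels are acquired sequentially and can
   be misaligned by a few pixels. `registerChannels()` searches all integer
   shifts within `max_shift` (default 20 px, about 2% of a 1024-px field)
   and maximizes Pearson correlation on the overlap. Integer shifts only:
   no interpolation is applied to count data, and the ratio-of-sums
   statistic is robust to sub-pixel residuals. The NADH channel is held
   fixed and FAD is moved (a convention, stated once in the IO coordinate
   rules: x = column, y = row, origin top-left, shifts `(dx, dy)` act on
   FAD).
3. **Silk masking.** The decay stack is projected into phasor space,
   $g = \sum_t I(t)\cos\omega t / \sum_t I(t)$,
   $s = \sum_t I(t)\sin\omega t / \sum_t I(t)$, with $t$ at bin centers and
   $\omega = 2\pi \times 80\ \mathrm{MHz}$ by default (the first harmonic
   of a Ti:Sapphire repetition rate; configurable). The phase lifetime
   $\tau = s/(\omega g)$ is exact for mono-exponential decays at the laser
   harmonic, and silk pixels — whose autofluorescence lifetime is much
   longer than cellular NAD(P)H — are removed by thresholding $\tau$ at a
   cutoff (default 2.0 ns, sitting between silk at roughly 2.8 ns and
   cells at or below roughly 1.5 ns, so silk is removed with minimal loss
   of cellular signal).
4. **Redox maps and summaries.** $r = F/(F+N)$ per valid pixel; a pixel is
   valid when it passes the silk mask, lies in the registration overlap,
   and $F + N > \varepsilon$ (default $10^{-6}$ normalized units — this
   excludes dark background without touching dim cells). The per-field
   summary defaults to the intensity-weighted form
   $\sum F / \sum(F+N)$ — the FAD intensity contribution over the summed
   contributions — with the per-pixel mean available as `pixel_mean`
   (the histogram analysis needs per-pixel ratios anyway; both modes are
   reported and tested). Fields are averaged within each sample: the
   sample (a whole construct) is the unit of inference, which is what
   makes a two-condition comparison with $n = 3$ samples per group carry
   $df = 4$.
5. **Histogram decomposition and statistics.** Valid pixels are binned
   into 50 equal bins on $[0, 1]$; histograms from all groups are pooled
   and decomposed into $K$ shared Gaussian components (default $K = 4$);
   each image's component weights are then fitted with the basis frozen
   and normalized to 100%. Group comparisons use the pooled-variance
   unpaired two-tailed t-test (two groups) or one-way ANOVA with Tukey HSD
   (three or more), at the 0.05 threshold.

## The Gaussian basis fit, in detail

`fitBasis()` runs expectation–maximization on the bin-center-weighted
samples, i.e. the fit is a function of the histogram alone, not of raw
pixels. With 50 bins the discretization bias on a component mean is below
half a bin width (0.01) and the variance inflation is $w^2/12 \approx
3\times10^{-5}$ — both inside the recovery tolerances the tests assert.
The EM is restarted from `n_iter = 10` independent random initializations;
each run's components are sorted by ascending mean and the basis is the
element-wise average of the sorted parameters. Sorting before averaging
makes the result invariant to iteration order and gives components a
reproducible identity: Component 1 is always the lowest-mean
(glycolysis-associated) component, Component $K$ the highest. Runs that
collapse (a component SD under $10^{-4}$ or vanishing responsibility mass)
are restarted from a fresh sub-seed; more than 50 restarts aborts with an
error rather than returning a silently averaged-over-garbage basis.

`fitWeights()` freezes the basis and iterates EM over the mixture
proportions only, to a tolerance of $10^{-8}$ on the proportion scale,
then scales to percentages summing to 100 exactly. A test checks it
against a grid-search maximizer of the frozen-basis likelihood to within
0.5 percentage points. The contrast statistic between groups is the
image-wise ratio $W_k / (100 - W_k)$, i.e. each component's weight over
the summed weight of all others; a weight of exactly 100 reports an
infinite ratio rather than an error.

$K$ is user-chosen. No model-selection rule is invented; the BIC of the
averaged basis is attached to the result for information only.

## What the synthetic generator emulates — and what it does not

No microscopy data ship with the package, so every stage is validated
against `makeScene()` / `renderChannels()` / `renderDecays()` /
`makeCohort()` scenes with fully known truth:

* per-pixel redox ratios drawn i.i.d. from population-specific Gaussian
  mixtures (the generative twin of the components the decomposition
  recovers), clipped to $[0,1]$ with the clipped mass reported;
* expected channel intensities $F = rT$, $N = (1-r)T$ (so $N + F = T$ is
  conserved), scaled by $P^2 G$ per channel;
* a donut-shaped silk region with a long mono-exponential lifetime
  (default 2.8 ns) and cellular lifetimes of 0.8–1.5 ns — fixture values
  chosen to be realistic, not measured constants;
* a known integer shift applied to the FAD channel;
* Poisson shot noise per pixel (and per time bin in decay stacks);
* decay stacks binned from the truncated mono-exponential over one
  excitation period — the truncation is proportional to the periodic
  steady-state decay, so the phasor at the laser harmonic is exactly on
  the universal semicircle up to bin discretization.

Deliberately absent: optical point-spread simulation, depth attenuation,
bi-exponential bound/free NADH decays, and any spatial correlation of the
redox draws within a population. The last point matters for
interpretation: in real tissue the redox field is spatially coherent
(organelles, cells), so the Gaussian low-pass filter (`smoothRedoxMap()`,
default $\sigma = 1$ px, normalized convolution that excludes masked
pixels from the kernel support) suppresses shot noise without destroying
the pixel-value distribution. On i.i.d. synthetic scenes the same filter
averages independent draws and collapses mixture modes toward the
population mean. The synthetic end-to-end decomposition checks therefore
histogram the unsmoothed maps; smoothing is tested separately for its
analytic properties (identity at $\sigma = 0$, invariance on uniform maps,
mass conservation, mask respect). Passing tests consequently demonstrate
correctness of each stage and of their composition on mixture-structured
data, not that $\sigma = 1$ is optimal for any particular instrument.

Registration similarly relies on the two channels sharing intensity
structure (cell bodies and scaffold visible in both), which is how real
NADH/FAD pairs behave. In scenes where structural contrast is weak and
pixel-wise redox variation dominates, the channels anti-correlate
($N = (1-r)T$ vs $F = rT$) and correlation maximization is the wrong
tool; the registration fixtures therefore use bright structured scenes
(silk and cells well above a 50-count background), and the featureless
degenerate case is pinned to return the zero shift with score 0.

## Numerical and design choices

* **Ties in registration** are broken by the smallest Euclidean shift
  norm, then lexicographically by $(dx, dy)$ — fully deterministic,
  returning $(0,0)$ for constant images (correlation on a zero-variance
  overlap is defined as 0). Overlaps smaller than `min_overlap` (default
  32 px) are never scored; if no candidate shift is admissible the call
  errors rather than returning a silent extrapolation.
* **Masked pixels** are an explicit logical mask in memory; NaN encoding
  exists only in the float-TIFF on-disk format. No NaN arithmetic occurs
  in the core.
* **Zero-count decay pixels** get an undefined phasor (excluded
  downstream), not NaN propagation; pixels with undefined lifetimes are
  kept by the silk filter (they carry no silk evidence) and are instead
  excluded by the intensity floor of the redox map.
* **Degenerate t-tests**: identical groups give $t = 0, p = 1$; zero
  pooled variance with unequal means gives a $p = 0$ sentinel with a
  warning. The pooled-variance (not Welch) form is the default because it
  is the one whose $df = n_1 + n_2 - 2$ matches the construct-level
  design; Welch is available behind a flag.
* **No multiple-testing correction** is applied across a report beyond
  Tukey within an ANOVA family, matching the analysis conventions the
  pipeline reproduces.
* **Problem sizes in the tests** were chosen as the smallest that make
  the statistical assertions sharp: mixture recovery uses $5\times10^4$
  pixels, type-I error uses 2000 simulated null cohorts of 24×24-px
  fields (3 samples × 4 fields × 2 conditions), power and structure
  checks use 500 and 200 replicates. Field size cancels out of the
  statistical claims (rejection rates, orderings); it only sets the
  per-field shot-noise level.

## Known limitations

* Lifetime values for silk and cells are plausible fixtures; the cutoff
  default (2.0 ns) is a calibrated choice for those fixtures, not a
  reproduction of a measured threshold. It is a parameter
  (`cutoff_ns`) and should be set per instrument.
* The intensity-threshold fallback mask (for fields without decay stacks)
  is a coarse surrogate and is labeled as such in its output; the
  principled filter is lifetime-based.
* Whether EM should run on binned densities or raw pixel values is
  genuinely ambiguous for this kind of analysis; the binned choice is
  documented above and its discretization cost quantified, but it is a
  choice, not the only defensible one.
* Sub-pixel registration and nonrigid deformation are out of scope, as is
  any depth-resolved aggregation beyond treating each plane as a field.

## A compact worked run

```{r example, eval = FALSE}
des <- cohortDesign(
  conditions = list(CLG1 = uniformCondition(0.55),
                    HA = uniformCondition(0.45)),
  n_samples = 3, fields_per_sample = 4,
  width = 64, height = 64, field_sd = 0.03)
cohort <- makeCohort(des, seed = 1)
analysis <- analyzeCohort(cohort)
buildReport(analysis$samples)
```

The report carries the statistic, $df = 4$, the two-tailed $p$, group
means and SDs, and the direction of the difference — the same quantities
a figure legend would print.
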