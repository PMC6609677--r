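---
title: "Methods: tumor blood flow quantification and test-retest repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor blood flow quantification and test-retest repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbflow)
```

rbflow measures tumor blood flow (TBF) from ⁸²Rb PET two ways — dynamically,
as the one-tissue-compartment influx constant K1, and statically, as SUV
metrics on a late uptake frame — and quantifies how repeatable each measure
is across two scan sessions. This vignette documents the models, the
numerical choices, and the places where a convention had to be chosen.

## The kinetic model

⁸²Rb is a retention tracer: over the first minutes its tissue concentration
is well described by the one-tissue compartment model

$$\frac{dC_T}{dt} = K_1\,C_a(t) - k_2\,C_T(t), \qquad
C_T^{obs}(t) = C_T(t) + v_b\,C_a(t),$$

where $C_a$ is the arterial input function, $K_1$
(mL·min⁻¹·(mL tissue)⁻¹) is the flow-related delivery constant — the TBF
surrogate — $k_2$ (min⁻¹) the efflux constant, and $v_b$ an optional blood
volume fraction, off by default (`fit_vb = FALSE`): the minimal model is
identifiable from short noisy curves, and $v_b$ can be switched on where
spill-in matters. All curves are treated as decay-corrected; the generator
produces decay-corrected curves by construction.

**Evaluation.** `onetc_forward()` evaluates the convolution
$C_a \ast e^{-k_2 t}$ analytically on each interval of a fine grid
(default `dt = 0.1` s) on which $C_a$ is piecewise linear between the
midpoints of its frames, constant beyond the first/last midpoint. The
analytic per-interval solution avoids quadrature artifacts on coarse late
frames; midpoint anchoring makes a constant input exactly constant. Model
output is frame-averaged (trapezoid on the grid, which contains every frame
boundary) because PET frames report time averages, not samples.

**Fitting.** `onetc_fit()` minimises the weighted residual sum of squares
with bounded L-BFGS-B restarted from a deterministic 3×3 grid
($K_1 \in [0,3]$, $k_2 \in [0,5]$ min⁻¹); the best run is kept, its
convergence flag reported honestly, and `wrss` is the achieved objective.
Weights are uniform by default with a duration-proportional option — frame
weighting is a site convention and the statistics downstream are
insensitive to it on the phantoms tested. A flat-zero tissue curve is
special-cased to $K_1 = 0$ exactly.

## Image-derived input function

A direct arterial sample is not available, so the input function is
image-derived. `extract_idif()` k-means-clusters the voxel time-activity
curves inside a body mask (default 3 clusters, deterministic under its
`seed`) and must then decide which cluster is blood. The rule adopted —
**earliest-peaking mean curve, ties to the higher peak** — encodes the
physiology that the arterial bolus transits before any tissue uptake
accumulates; it is a package convention, as is the cluster count, both
exposed as arguments.

Because the cardiac IDIF is cleaner than the pelvic one but arrives earlier
and sharper, `delay_dispersion_correct()` maps it to the pelvic site: the
remote curve is shifted by $\Delta t$ and convolved with the unit-area
kernel $(1/\tau)e^{-t/\tau}$, and $(\Delta t, \tau)$ minimise the squared
mismatch to the local reference. Numerics worth noting:

- the mismatch is evaluated **in frame space** — the transformed remote
  curve is frame-averaged onto the reference frames before comparison —
  since the reference values are themselves frame averages; comparing a
  continuous curve against re-interpolated frame averages biases the delay
  by a substantial fraction of a frame.
- $\Delta t$ is searched on a dense grid (default 0.5 s over [−10, 20] s)
  with $\tau$ profiled by 1-D minimisation in $[0, 20]$ s at each delay;
  $\tau = 0$ is always evaluated explicitly so the identity is reachable
  exactly. An estimate on the edge of either range raises a boundary
  warning rather than being silently accepted.
- the kernel has unit area, so correction conserves the curve integral up
  to end-of-window truncation (tested to < 1% on padded curves).

## Static SUV analysis

`suv_scale()` uses body-weight SUV, $C / (\text{dose}/\text{weight})$; the
normaliser is an argument since lean-mass or BSA conventions exist. VOIs
come from a fixed SUV threshold (default 6) or a percent-of-max threshold
(default 30%) inside a search region, after removing an exclusion mask —
the generic form of manually masking bladder activity that would otherwise
merge with a lesion. Comparisons are closed (≥), and the largest 6-connected
component is retained, which is how "at the tumor site" is made
operational. `suv_metrics()` reports SUVmax, SUVmean, and SUVpeak; SUVpeak
is the EANM-style maximal mean over a 1 cm³ sphere (radius 6.2 mm) centred
on a VOI voxel, clipped to the volume. Vendor SUVpeak definitions vary;
this choice affects only phantom experiments, not the statistics computed
from the bundled table.

## Agreement statistics

The clinically relevant change is relative, so everything is computed on
log-transformed values via the per-lesion differences
$d_i = \ln(\text{retest}_i) - \ln(\text{test}_i)$. Two spread estimators
are deliberately kept distinct:

- $\sigma_w = \sqrt{\sum d_i^2 / 2n}$ — the Bland-Altman within-subject SD
  (no mean subtraction), which feeds the within-subject CV
  ($100\,\sigma_w$, a small-$\sigma$ approximation) and the repeatability
  coefficient $RC\% = 100\,(e^{1.96\sqrt{2}\,\sigma_w} - 1)$;
- the mean-subtracted, $n-1$ SD of $d$, which feeds the Bland-Altman
  limits of agreement $e^{\bar d \pm 1.96\,s_d}$ (kept as asymmetric
  retest/test ratios, not symmetrised) and the sample-size module.

Collapsing the two onto either estimator changes the reproduced tables; the
pairing above is the one consistent with both downstream uses. The ICC is
fixed to the one-way random-effects form ICC(1,1),
$(MS_B - MS_W)/(MS_B + MS_W)$ for two replicates on the log scale — with
two unlabeled-order sessions per lesion there is no rater structure to
support a two-way variant. Q-Q coordinates use $(i - 0.5)/n$ plotting
positions.

On the bundled 11-lesion table these give an ICC of 0.98 and RC of 33.4%
for K1 (the table's values are printed to 2 decimals; recomputation from
rounded inputs lands ~1 percentage point above an unrounded-source value of
about 32%, which is expected behaviour of the rounding, not reconciled
away), and RC of 57–70% for the SUV measures.

## Sample size

`required_n()` returns the smallest $n \ge 2$ with

$$t^{-1}(1-\alpha/2;\,n-1) + t^{-1}(\text{power};\,n-1)
 \le \frac{|\ln(1+\Delta)|\sqrt{n}}{\sigma_d},$$

the iterative central-t condition for a two-sided paired t-test on log
values. The plain z formula (`method = "z"`) is a lower bound exposed for
comparison, and `method = "exact"` iterates the noncentral-t power function
instead; the central-t rule is the default because it is the standard
paired-design calculation and its cells are confirmed by a simulation
oracle in the tests (achieved power within 2% of nominal at the returned
$n$). The floor of 2 reflects that a paired t-test needs two pairs.

## What the synthetic generators emulate

`sim_paired_table()` draws lesion log-levels $\mu + b_i$,
$b_i \sim N(0, \sigma_b^2)$, and session values
$e^{\mu + b_i + e}$, $e \sim N(0, \sigma_w^2)$ — exactly the log-normal
model the statistics assume. Defaults are the study conditions of the
bundled table: 11 lesions, $\sigma_b = 0.75$, per-measure $\sigma_w$ of
0.10/0.16/0.17/0.19 and geometric means near the observed columns.

`sim_input_function()` is a gamma-variate bolus (default peak 25 s,
shape 3, onset 5 s) with a mono-exponential recirculation tail (15% of
peak, 120 s) — a standard low-parameter description of a fast intravenous
bolus; the true infusion profile of a clinical generator is not modelled.
`sim_phantom()` builds a small voxel grid (default 12×12×6 at 4 mm, 24×5 s
+ 8×30 s frames) with blood/tumor/background regions; tumor defaults
($K_1 = 0.36$, $k_2 = 0.9$ min⁻¹) sit at the high end of the observed K1
range, background at the low end. Noise is independent Gaussian per
voxel-frame with SD equal to `noise_cov` × the noiseless value (default
5%). Tissue curves are produced by the same `onetc_forward()` used in
fitting, so zero-noise phantoms are exactly self-consistent — recovery
tests on them validate the optimiser, not the forward model; the forward
model is validated separately against an independent fine-grid quadrature
oracle.

What passing on these phantoms does **not** show: robustness to
reconstruction noise correlations and Poisson statistics, partial-volume
effects at real lesion sizes, patient motion, co-registration error between
sessions, or infusion-profile variability. The phantom results bound
algorithmic bias, not clinical variability.

## Problem sizes and runtime choices

The test suite runs phantoms of 12×12×6 voxels × 32 frames, 50-replicate
noise recoveries, 200-table ICC oracle comparisons, and 4000-trial power
simulations per grid cell — sizes chosen so the full suite completes in
well under a minute while keeping Monte-Carlo error comfortably inside the
asserted tolerances (e.g. the 500-lesion σ_w re-estimation has standard
error ≈ 0.003 against a ±0.01 band).

## Known limitations

- K1 is reported in conventional perfusion units, but the bundled table's
  printed values carry no explicit unit; since every statistic is a log
  ratio, units cancel and the convention is metadata only.
- The cluster count, mismatch window and clustering algorithm of the IDIF
  stage are package conventions exposed as arguments, not a validated
  reimplementation of any site's protocol.
- SUV repeatability values recomputed from a rounded 2-decimal table can
  differ by a few percentage points from unrounded-source values; the
  sample-size cells are integer-robust except where a cell sits within one
  unit of a rounding boundary.
- The delay search grid (0.5 s) bounds delay resolution; sub-grid
  refinement was not needed at the frame durations considered.
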