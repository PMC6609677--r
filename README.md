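# rbflow

Tumor blood flow (TBF) quantification from dynamic and static ⁸²Rb PET, and
the test-retest statistics that say how repeatable those measurements are.

⁸²Rb is a generator-produced perfusion tracer (half-life ≈ 76 s) that is
widely available for cardiac PET and is retained by tissue in proportion to
blood flow. Measuring TBF with it — by kinetic modelling of a dynamic scan,
or more simply by SUV on a late static frame — is a candidate tool for risk
stratification and treatment monitoring in prostate cancer. Whether a
measured change in a patient is real, and how many patients a response study
needs, both hinge on the test-retest repeatability of the measurement. This
package implements the full analysis chain for that question:

- **Kinetics** — the one-tissue compartment model
  `C_T(t) = K1 · (C_a ⊛ e^(−k2·t))(t) + vb·C_a(t)`, fitted by bounded
  multi-start weighted least squares (`onetc_fit()`); an image-derived input
  function (IDIF) extracted by k-means cluster analysis of voxel
  time-activity curves (`extract_idif()`); and delay/dispersion correction
  of a remote (cardiac) input function to the pelvic site — a shift Δt
  followed by convolution with `(1/τ)e^(−t/τ)`, estimated by dense grid
  search with τ profiled per delay (`delay_dispersion_correct()`).
- **Static SUV** — SUV scaling by injected dose per body weight
  (`suv_scale()`), VOI segmentation by fixed SUV threshold or
  percent-of-max with an exclusion (bladder) mask and largest-connected-
  component retention (`segment_fixed_threshold()`, `segment_percent_max()`),
  and SUVmax / SUVmean / SUVpeak over the VOI (`suv_metrics()`; SUVpeak is
  the maximal 1 cm³ sphere mean).
- **Statistics** — everything on the log scale, because the clinically
  relevant quantity is a *relative* change: within-lesion SD
  `σ_w = √(Σdᵢ²/2n)` of the log test-retest differences, the repeatability
  coefficient `RC% = 100·(e^(1.96·√2·σ_w) − 1)`, the one-way
  random-effects ICC, Bland-Altman limits of agreement back-transformed to
  retest/test ratios (`repeatability()`), and the sample size needed to
  detect a relative change Δ with a paired t-test on log values,
  `t⁻¹(1−α/2; n−1) + t⁻¹(power; n−1) ≤ |ln(1+Δ)|·√n/σ_d` iterated over n
  (`required_n()`, `sample_size_table()`).

A per-lesion test-retest table for 11 primary prostate lesions (10
patients, scanned twice within a week) is bundled as `table1_fixture()`,
and synthetic generators (`sim_paired_table()`, `sim_input_function()`,
`sim_phantom()`, `sim_static_volume()`) provide paired log-normal tables
and 4-D dynamic phantoms with known ground truth, so every stage runs
without external data.

## Worked example

```r
library(rbflow)

tab <- table1_fixture()
repeatability(tab)
#> Test-retest repeatability (n = 11 lesions)
#>   measure  ICC repeatability % wCV % mean ratio LoA low LoA high
#>        k1 0.98            33.4  10.4      0.972   0.722    1.307
#>   suv_max 0.90            56.8  16.2      0.967   0.607    1.542
#>  suv_mean 0.89            58.6  16.6      0.986   0.608    1.598
#>  suv_peak 0.87            70.5  19.2      0.914   0.539    1.549
```

Read: K1 from dynamic ⁸²Rb PET is highly repeatable — its ICC of 0.98 means
within-lesion variation is small against the between-lesion spread, and its
repeatability coefficient means a change larger than ~33% of the mean is
unlikely (95%) to be measurement noise. The static SUV measures are
markedly less repeatable (RC 57–70% from this table), so only large changes
are detectable per patient. `wCV %` is the within-lesion coefficient of
variation; the `LoA` columns are the 95% Bland-Altman limits as
retest/test ratios.

```r
sample_size_table(tab)
#> Sample sizes for a paired log-normal design (alpha = 0.05 two-sided, power = 0.95)
#>   measure N at -0.2 N at -0.3 N at -0.5
#>        k1         9         5         3
#>   suv_max        17         9         4
#>  suv_mean        19         9         4
#>  suv_peak        22        10         5
```

i.e. detecting a 30% flow decrease with K1 takes 5 paired subjects at
α = 5% / power 95%; with SUVpeak it takes 10.

The kinetic layer, end to end on synthetic data:

```r
frm <- default_frame_schedule()          # 24 x 5 s + 8 x 30 s
aif <- sim_input_function(frm)           # gamma-variate bolus + tail
tissue <- onetc_forward(k1 = 0.36, k2 = 0.9, input = aif, frames = frm)
onetc_fit(tissue, aif)
#> One-tissue compartment fit
#>   K1 = 0.36 mL/min/mL, k2 = 0.9 /min
#>   WRSS = 1.662e-10, converged: TRUE
```

`pipeline_simulate()` / `pipeline_quantify()` / `pipeline_report()` chain
these stages (phantom → IDIF + fit + SUV → measurement table → reports); a
thin command-line wrapper lives at `inst/cli/rbflow.R`.

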