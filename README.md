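# csfdyn

Quantitative physiology of cerebrospinal fluid (CSF) clearance in the
developing mouse brain, for researchers studying CSF dynamics, choroid
plexus (ChP) biology, and hydrocephalus models. The package implements,
as tested R functions:

* **The Marmarou model of CSF dynamics** for constant-rate infusion
  tests: the closed-form ICP curve, simulation of full recordings with
  cardiac/respiratory pulsation, zero-phase low-pass filtering, a
  catheter-placement quality control, and bounded nonlinear
  least-squares estimation of baseline ICP, the reference pressure
  p&#8320;, the resistance to CSF outflow R<sub>CSF</sub>, and the
  compliance coefficient C<sub>i</sub>.
* **Apical:basal polarity scoring** of organelles (e.g. mitochondria)
  in traced epithelial cells — exact point-to-polyline distances, the
  proximity ratio (1 = apical surface, 0 = basal), morphometrics, and
  Kolmogorov–Smirnov group comparison.
* **Cell-swelling volumetrics** under high-K⁺ challenge (percent volume
  increase, per-animal aggregation) and MRI-style group volume
  summaries with Welch comparisons.
* **Bioenergetics and statistics**: ATP-linked respiration from
  oligomycin-response OCR traces with same-plate adult normalization,
  Welch/Student t from raw data or printed summaries, Sidak adjustment.
* **Seeded synthetic-data generators** for every assay, parameterized
  by the study's printed developmental summaries, so the whole pipeline
  is testable without any raw instrument data.

## The model at the core

During a constant-rate infusion at rate *i* (µL/min), ICP follows

    dP/dt = ((P − p0)/C_i) · (i − (P − ICP_b)/R_CSF),   P(0) = ICP_b,

whose closed-form solution rises from the baseline ICP_b and plateaus at
ICP_b + i·R_CSF. C_i (µL) is inversely proportional to the rate of the
early rise; R_CSF (mmHg·min/µL) sets the plateau height. `fit_marmarou()`
recovers all four parameters from a recording.

## Worked example

Simulate an infusion test (2 min baseline, then 2 µL/min for 10 min,
with pulsation and sensor noise), filter, and fit:

```r
library(csfdyn)

truth <- marmarou_params(icp_baseline = 5, p0 = 2, r_csf = 4,
                         c_i = 10, i_infusion = 2)
trace <- simulate_infusion(truth, infusion_protocol(), waveform_spec(),
                           seed = 42)
fit <- fit_marmarou(lowpass_waveform_removal(trace))
fit
#> Marmarou model fit (2000 samples, residual RMS 0.039 mmHg, converged)
#>              estimate stderr
#> icp_baseline   4.9975 0.0019
#> p0             2.0678 0.0350
#> r_csf          3.9696 0.0110
#> c_i            9.8025 0.0822
```

The true R_CSF = 4 and C_i = 10 are recovered within ~1% from a noisy
recording. The placement QC confirms that pulse amplitude grows with
volume load:

```r
qc <- pulse_amplitude_qc(trace)
#> QC slope 0.055 mmHg/mmHg (se 0.002) -> pass = TRUE
```

Polarity: generate an apically biased and a basally biased field of
cells, score every organelle, and compare the distributions:

```r
adult_like <- gen_polarized_geometry(
  geometry_spec(n_mito = 300, depth_alpha = 5, depth_beta = 1),
  n_cells = 3, seed = 7)
embryo_like <- gen_polarized_geometry(
  geometry_spec(n_mito = 300, depth_alpha = 1, depth_beta = 2),
  n_cells = 3, seed = 8)
ra <- polarity_table(adult_like$mitos, adult_like$cells)$ratio
rb <- polarity_table(embryo_like$mitos, embryo_like$cells)$ratio
ks_two_sample(ra, rb)
#> mean ratio: adult-like 0.83, embryo-like 0.34; KS D = 0.75, p = 3e-222
```

Summary statistics reproduce printed comparisons directly:

```r
welch_t(list(mean = 2.50, sd = 0.20, n = 6),
        list(mean = 2.71, sd = 0.46, n = 6))$p_value
#> [1] 0.3400889
```

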