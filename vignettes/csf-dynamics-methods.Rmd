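---
title: "Methods: models, estimators, and synthetic data in csfdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators, and synthetic data in csfdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfdyn)
```

`csfdyn` packages the quantitative analyses used to study cerebrospinal
fluid (CSF) clearance in the developing mouse brain: infusion-test
estimation of CSF outflow resistance and intracranial compliance,
apical:basal polarity of organelles in choroid plexus (ChP) epithelium,
cell-swelling volumetrics under high-potassium challenge, ATP extraction
from oxygen-consumption assays, and developmental ion summaries. This
vignette explains each model, the numerical choices behind it, and what
the seeded synthetic generators do and do not emulate.

## The Marmarou model of a constant-rate infusion test

The constant-rate infusion test infuses artificial CSF into a lateral
ventricle at a fixed rate $i$ (uL/min) while intracranial pressure (ICP)
is recorded. In the lumped-parameter (Marmarou) model of CSF dynamics,
stored volume and pressure are related through an exponential
pressure-volume curve with compliance coefficient $C_i$ (uL), outflow is
proportional to the pressure above baseline with resistance $R_{CSF}$
(mmHg.min/uL), and a reference pressure $p_0$ (mmHg) anchors the
storage arm. ICP then obeys

$$\frac{dP}{dt} = \frac{P - p_0}{C_i}\left(i - \frac{P - ICP_b}{R_{CSF}}\right),
\qquad P(0) = ICP_b,$$

whose closed-form solution `icp_model()` rises monotonically from the
baseline $ICP_b$ to the plateau $ICP_b + i\,R_{CSF}$. We implement the
solution in the offset form with a leading $p_0$ term so that the $t=0$
boundary condition $P(0)=ICP_b$ and the plateau identity both hold
exactly; the test suite verifies the closed form against a Runge-Kutta
integration of the ODE above to below $10^{-6}$ mmHg over an hour of
simulated infusion. Intuitively, $C_i$ is inversely proportional to the
rate of the early pressure rise, and $R_{CSF}$ sets the plateau height.

**Units.** mmHg, minutes, and uL throughout; `convert_rate()` converts
uL/min to mL/min at the I/O boundary only. $C_i$ carries volume units,
as forced by the exponent of the model.

### Simulation

`simulate_infusion()` produces a full synthetic recording: a baseline
segment (default 2 min, the pre-infusion recording time of the assay),
the model rise (default 10 min of infusion), cardiac and respiratory
sinusoids, and i.i.d. Gaussian sensor noise. Defaults place the cardiac
component at 10 Hz (~600 bpm) and the respiratory component at 2.5 Hz,
typical of an anesthetized adult mouse, sampled at 50 Hz. The pulsation
amplitude is modulated as
$a(t) = a_0\,[1 + \kappa\,(P_{model}(t) - ICP_b)]$ with coupling gain
$\kappa = 0.1$ per mmHg by default, reproducing the physiological
observation that pulse amplitude grows with volume load — the property
the catheter-placement quality control relies on. The default truth used
in recovery studies ($ICP_b = 5$, $p_0 = 2$, $R_{CSF} = 4$, $C_i = 10$,
$i = 2$ uL/min, noise SD 0.3 mmHg) gives a 5 to 13 mmHg rise with a
~3.6 min time constant, matching the magnitudes of murine infusion
recordings; the infusion rate sits inside the 1-4 uL/min operating range
of the assay and is always an explicit input, never defaulted, in the
fitting path.

### Filtering and quality control

`lowpass_waveform_removal()` removes the waveform components before
fitting or display: a 2nd-order Butterworth filter applied
forward-backward (`signal::filtfilt`), giving zero phase shift (the
timing of the rise is untouched) and unit DC gain. The default cutoff of
0.5 Hz sits below the murine respiratory band and far above the
infusion-rise timescale. The trace is reflected at both ends before
filtering to suppress edge transients.

`pulse_amplitude_qc()` band-passes the recording over the waveform band
(default 0.5-15 Hz), measures pulsation amplitude and mean pressure in
consecutive 10 s windows, and regresses amplitude on pressure. QC passes
when the slope is positive with $slope/se > 3$; simulations with the
coupling disabled fail this check, as they should.

### Fitting

`fit_marmarou()` estimates $(ICP_b, p_0, R_{CSF}, C_i)$ by bounded
Levenberg-Marquardt least squares (`minpack.lm::nlsLM`, cost tolerance
$10^{-10}$, 500 iterations), modelling baseline samples as a constant
and post-infusion samples with the closed form. Choices that matter:

* **Reparameterisation.** The optimizer works in
  $x_0 = ICP_b - p_0 > 0$, which enforces $p_0 < ICP_b$ with a simple
  box bound instead of a joint constraint.
* **Initialization.** $ICP_b$ from the baseline-segment mean (samples
  before the infusion start minus a 5 s guard band), $R_{CSF}$ from
  (plateau $-$ baseline)/$i$ using the last tenth of the trace as the
  plateau, $C_i$ from the initial rise slope via
  $C_i = x_0 i / \dot P(0)$, and $p_0$ at baseline $-1$ mmHg. A coarse
  grid over $(R_{CSF}, C_i)$ is the fallback start if the first attempt
  fails.
* **Thinning.** Traces longer than 2000 samples are thinned evenly
  before fitting; after low-pass filtering the information about the
  slow rise lives far below the raw 50 Hz sampling rate, and the
  thinned fit is indistinguishable in recovery studies.
* **Degenerate inputs.** Zero infusion rate, no post-infusion samples,
  or no discernible rise (under 0.05 mmHg, i.e. below sensor noise) are
  unidentifiable and raise errors rather than returning garbage.
* $p_0$ is the weakest-identified parameter (it only shapes the
  transient); on noisy data its standard error is accordingly large,
  which the fit reports honestly.

On noiseless simulations all four parameters are recovered to better
than 0.1%; on 100 seeded noisy replicates at the default conditions the
median relative errors of $R_{CSF}$ and $C_i$ after filtering are about
0.4% and 1.2%, well inside the 5% design tolerance.

## Organelle polarity from traced geometry

Mitochondrial polarity in ChP epithelial cells is scored from
hand-traced 2-D geometry: an apical and a basal polyline per cell and
one centroid per organelle. `point_to_polyline_distance()` computes the
exact Euclidean distance to the nearest point of any segment (interior
projections included); polylines are treated as open curves, with no
closing segment. The proximity ratio is

$$\mathrm{ratio} = \frac{d_{basal}}{d_{apical} + d_{basal}},$$

which equals 1 on the apical surface and 0 on the basal surface — the
two anchors the assay defines. The interior interpolation is a design
choice: the endpoints alone do not fix it, and we use the simplest
continuous symmetric form. It is invariant under rigid motion and
uniform scaling (so pixel-vs-micrometre tracing is immaterial to the
ratio), and decreases monotonically along straight apical-to-basal paths
in convex cells. A point lying on both surfaces at once is a degenerate
tracing and is rejected.

`morphometrics()` reports organelle count, mean area, and percent area
occupancy (total organelle area over total traced epithelial area within
the field of view). Group distributions are compared with the two-sample
Kolmogorov-Smirnov test: `ks_two_sample()` computes $D$ as the supremum
of the ECDF difference over all observed points and the p-value from the
asymptotic two-sided KS distribution at effective sample size
$n_a n_b/(n_a+n_b)$. The asymptotic form is appropriate for the
~$10^3$-organelle samples this assay produces; the suite checks $D$
against an exhaustive oracle on all sample sizes up to 8 and the p-value
against the reference implementation in `stats`.

## Cell-swelling volumetrics

Under a high-extracellular-K$^+$ challenge, ChP epithelial cells swell
in proportion to their cotransporter activity. `percent_volume_increase()`
computes $100\,(V_t - V_0)/V_0$ per timepoint, unit-free.
`per_animal_swelling()` averages cells within each animal so an animal
is the statistical unit, excluding (with a warning, overridable) animals
contributing fewer than five cells — the assay's minimum. Timepoints are
aligned by acquisition index, with a tolerance of half a minute on the
nominal times, matching an acquisition of five stacks over ten minutes.
Both the per-cell and the per-animal level are returned, since error
bars can legitimately be drawn at either level.

`volume_from_mask()` converts voxel counts from manual MRI segmentation
to mm$^3$ (e.g. with the 0.6 mm slice thickness of the imaging
protocol), and `group_volume_summary()` reports group means, SDs, and
pairwise Welch comparisons plus the ratio of group means (the headline
quantity in ventriculomegaly comparisons). `brain_size_proxy()` averages
per-slice cross-sectional areas without excluding ventricle regions,
mirroring how whole-brain size is summarized alongside ventricle
volumes.

## Bioenergetics and statistics

`atp_production()` extracts ATP-linked respiration from a mitochondrial
stress test: the drop in oxygen consumption rate (OCR) when ATP synthase
is inhibited by oligomycin. Per well we use the last pre-injection cycle
and, by default, the post-injection nadir cycle (the first post-injection
cycle is available behind a flag, since instruments differ in how fast
the drug takes effect); the difference is divided by the well's calcein
fluorescence (tissue amount) and then by the same-plate adult-group
mean, so adult wells average 1.0 on every plate and the readout is
invariant to uniform rescaling of a plate's OCR.

`welch_t()` implements Welch's two-tailed unpaired t-test from raw
samples or from (mean, sd, n) summaries — the latter so printed results
can be reproduced; the pooled-variance Student form is available via
`var_equal = TRUE`, and for the CSF total-protein comparison
(2.50 ± 0.20 vs 2.71 ± 0.46 mg/ml, n = 6) the two give p = 0.340 and
p = 0.329 respectively; we report both rather than guessing which
"unpaired t-test" a given figure used. `sidak_adjust()` applies the
Sidak familywise correction $1-(1-p)^m$. Welch's ANOVA with Dunnett's T3
is out of scope; pairwise Welch tests with Sidak adjustment are the
offered (and so labelled) substitute. Outlier handling substitutes a
documented MAD rule (`mad_outliers()`, threshold 4.45 scaled-MAD units,
comparable stringency to common robust outlier screens) for proprietary
robust-regression screening; it is off by default everywhere and only
ever flags, never silently removes.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and a single
integer seed, drawn without disturbing the caller's RNG stream, and
their outputs round-trip bit-identically through the package's
readers/writers.

`dev_reference_table()` holds the summary parameters the generators
draw from: developmental CSF [K$^+$] (9.6 ± 3.5 mM at birth, 4.4 ± 0.9
at P7, 3.1 ± 0.6 in adults), P50 lateral-ventricle volumes under control
vs ChP NKCC1 overexpression (3.12 ± 0.59 vs 1.28 ± 0.28 mm$^3$), and
CSF protein. Only mean ± SD is available for these quantities, so
`gen_ion_samples()` and `gen_group_values()` draw normal samples
truncated at zero — the truncation matters only for the P0 K$^+$ row,
where ~0.3% of draws are redrawn and the induced mean bias (~0.03 mM) is
an order of magnitude below the 2-standard-error recovery band the
acceptance checks use. Serum [K$^+$] levels are not part of the printed
summaries; the serum rows are labelled synthetic assumptions at textbook
murine values and exist only so CSF/serum ratios can be exercised.

`gen_polarized_geometry()` builds rectangular cells (default 20 × 15 um,
the scale of ChP epithelial cross-sections) with sinusoidally perturbed
apical and basal edges and scatters organelle depths from a Beta
distribution over normalized apical depth: Beta(1,1) is unpolarized,
Beta(5,1) strongly apical, Beta(1,5) strongly basal — the simplest
family spanning the embryonic-to-adult polarity shift. Organelle areas
are lognormal (median ~0.3 um$^2$). Centroids are guaranteed inside the
cell region.

`gen_swelling()` emulates saturating swelling,
$\%\Delta V(t) = \mathrm{plateau}\,(1 - e^{-kt})$ plus Gaussian noise,
with 4 animals × 5 cells and five post-challenge stacks over 10 min by
default; a higher rate constant gives uniformly higher early-time
swelling, which is the ordering the pipeline must preserve.

None of the generators simulate raw images, instrument files, or
sequencing data; they reproduce the *statistical structure* each
pipeline stage assumes (pressure dynamics plus pulsation, depth-biased
geometry, mean ± SD group samples, saturating timecourses). Passing
recovery tests therefore demonstrates that the estimators are correct
and well-calibrated under those assumptions — not that real recordings
satisfy them; in particular real ICP waveforms are non-sinusoidal, real
tracing error is not Gaussian, and real swelling curves need not be
mono-exponential.

## Problem sizes and reproducibility

The recovery studies shipped with the package use 100 noisy infusion
replicates at 50 Hz × 12 min, 200 random parameter sets for the
ODE-equivalence check, $10^4$ null replicates for the Welch size check,
and $n = 1000$ draws per reference row for generator recovery — sizes at
which every Monte-Carlo band in the checks is comfortably resolved on a
single CPU in well under a minute each. `scripts/acceptance.R` re-runs
all of them from scratch with a caller-supplied seed and writes the
resulting quantities as JSON.
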