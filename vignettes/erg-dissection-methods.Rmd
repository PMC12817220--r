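---
title: "Methods: waveform model, dissection and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waveform model, dissection and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergdissect)
```

This vignette documents the model underlying the synthetic generator, the
conventions of the dissection and measurement steps, the fitting and
statistical machinery, and the numerical choices made along the way. It is
the reference for *why* the defaults are what they are.

## 1. What the generator emulates — and what it does not

`simulate_family()` emulates an ex vivo transretinal ERG experiment: one
isolated retina, perfused sequentially with three solutions, stimulated with
a family of brief full-field flashes spanning several decades of strength,
each flash repeated over a few sweeps. What it reproduces:

- additive superposition of the photoreceptor, ON-bipolar and Müller glial
  (MGC) components in the recorded conditions;
- component kinetics of realistic shape and time scale (fast biphasic
  a-wave, delayed positive b-wave, slow negative glial wave);
- saturating Hill-type growth of each component's amplitude with flash
  strength;
- acquisition-chain low-pass filtering and additive broadband recording
  noise;
- retina-to-retina biological variability of amplitude and sensitivity.

What it deliberately does not model: oscillatory potentials, photoreceptor
response compression/kinetic changes with intensity, drug wash-in dynamics or
incomplete block, drift and line noise, OFF-pathway responses, or any
interaction between components (summation is exactly linear). These are
stated limitations, not oversights: the generator's purpose is a ground
truth against which the *analysis* pipeline can be validated exactly, not a
biophysical retina model.

## 2. Waveform model

Each component is a fixed kinetic template scaled by an intensity-dependent
Hill amplitude:

$$V_c(t, I) = p_c \, A_c(I) \, s_c(t), \qquad
A_c(I) = \frac{R_{\max,c}\, I^{n_c}}{I^{n_c} + K_c^{n_c}}$$

with polarity $p_c$ = −1 for photoreceptor and MGC, +1 for ON-bipolar. The
templates are built from the alpha function
$\alpha(t;\tau) = (t/\tau)\,e^{1 - t/\tau}$ (zero for $t<0$):

- **photoreceptor**: a fast trough ("nose") plus a slower
  recovery/plateau, `0.3 * alpha(t, 0.012) + 0.7 * (1 - exp(-t/0.008)) * exp(-t/0.8)`;
- **ON-bipolar**: `alpha(t - 0.02, 0.08)` — a 20 ms synaptic delay then an
  80 ms alpha wave;
- **MGC**: `alpha(t, 0.30)` — slow glial potassium wave.

Templates are normalized to unit peak *on the simulation grid*, so the peak
amplitude of a noise-free component equals the Hill value $A_c(I)$ exactly.
That exactness is what makes sample-level and amplitude-level oracle tests
possible.

### Hill normalisation

The half-maximal constant enters as $K^n$, not $K$: with
$R = R_{\max} I^n/(I^n + K^n)$, the response is exactly $R_{\max}/2$ at
$I = K$ for every slope $n$, and the equation is dimensionally consistent
($I$ and $K$ share units). Field shorthand sometimes writes the denominator
as $I^n + k$; we use the $K^n$ form throughout and report `k` in flash-strength
units plus `log10_k` for statistics.

### Default parameters

Flash strengths default to 9 log-spaced values from 5 to 50 000
photons µm⁻² (`sim_config()$intensities`). Wild-type baselines
(`baseline_components()`), in µV:

| component | stage | R_max | K | n |
|---|---|---|---|---|
| photoreceptor | pre-eye-opening / eye-opening / adult | 150 / 300 / 320 | 1000 | 1.0 |
| ON-bipolar | " | 100 / 250 / 450 | 100 | 1.2 |
| MGC | " | 80 / 150 / 300 | 400 | 1.0 |

The stage progression encodes the usual developmental picture: the
photoreceptor response is near-mature at eye opening, while the
post-receptoral (b-wave) and glial components keep growing into adulthood.
The K values order the components by sensitivity (ON-bipolar most sensitive,
photoreceptor least), and n is near 1 with a slightly steeper b-wave.

`genotype_effects()` ships three mutant presets (`KO`, `R141C`, `C59S`)
against `WT`, chosen to produce a retinoschisis-like pattern:

- **ADULT**: all three components scaled ×0.5 in every mutant —
  proportional loss, sensitivity unchanged;
- **EYE_OPENING**: photoreceptor ×0.6 in all mutants; ON-bipolar ×0.6 in
  `R141C` only; MGC R_max ×1.4 with K ×0.7 in `C59S` (a gain-of-glial
  signature distinguishing missense classes);
- **PRE_EYE_OPENING**: no effects — a true null for type-I-error work.

These numbers are fixed study conditions of the package; they were set once
from the qualitative pattern above and are not tuned.

### Variability and noise

Per retina, every component's R_max and K are multiplied by independent
lognormal factors with coefficient of variation `retina_cv` (default 0.15) —
`exp(rnorm(1, 0, sdlog))` with `sdlog = sqrt(log(1 + cv^2))`. Per sweep,
i.i.d. Gaussian noise of standard deviation `noise_sd` (default 2 µV) is
added to every sample. All randomness flows from a single seed through
`child_seed()`, which maps `(seed, i)` to a deterministic 31-bit sub-seed,
so a study is reproducible sweep-for-sweep.

### Acquisition filter

Conditions are low-pass filtered with an 8-pole Bessel filter at 300 Hz
(−3 dB), the standard anti-alias chain of patch/ERG amplifiers. The
installed `signal` package provides Butterworth but not Bessel designs, so
`bessel_lowpass()` constructs the analog prototype directly from the reverse
Bessel polynomial coefficients $a_k = (2n-k)!\,/\,(2^{n-k} k! (n-k)!)$,
normalizes the −3 dB point by root-finding on the analytic magnitude, and
discretizes via the bilinear transform (`signal::bilinear`). Designs are
cached per (order, cutoff, rate). Filtering uses a first-sample offset so a
constant trace passes through exactly — the filter must not bias baselines.
The test suite verifies DC gain 1, cutoff gain $1/\sqrt2$, and steep
stop-band attenuation via an FFT-of-impulse-response oracle that shares no
algebra with the design code.

Ground-truth traces stored in the `ground_truth` attribute are the
*filtered*, noise-free components: the pipeline is validated against what
the acquisition chain would actually deliver.

## 3. Dissection and measurement conventions

`average_sweeps()` averages sweeps within retina × condition × intensity.
`derive_components()` then forms:

- `MGC = LOCKES − BACL2` (barium-sensitive; comes out negative),
- `ON_BIPOLAR = BACL2 − BACL2_LAP4_AA` (L-AP4-sensitive; positive),
- `PHOTORECEPTOR = BACL2_LAP4_AA` as recorded.

The subtraction orientation follows "condition with the component minus
condition without it", so each derived trace carries the component's native
polarity. Intensities are matched across conditions after rounding to 4
significant digits (`canonical_intensity()`), absorbing storage round-trips.

`measure_amplitude()` subtracts the mean of the 0.1 s pre-flash baseline and
reports the unsigned extremum within a post-flash window
(`measurement_windows()`):

- photoreceptor **NOSE**: minimum in [0, 0.3] s after flash — the a-wave
  trough, the primary photoreceptor statistic;
- photoreceptor **RECOVERY**: mean over [0.4, 0.6] s — the plateau phase,
  reported alongside but not used in the Hill fits (`primary_amplitudes()`
  keeps NOSE);
- ON-bipolar: peak in [0, 1] s; MGC: trough in [0, 2] s (clipped to the
  record).

The nose/recovery split matters physiologically — the trough tracks the
circulating-current amplitude while the plateau mixes in slower currents —
which is why both are measured but only the trough feeds the
intensity–response analysis.

## 4. Hill fitting

`fit_hill()` uses bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`): start values are $R_{\max,0}$ = max amplitude,
$K_0$ = log-interpolated half-max crossing, $n_0 = 1$; bounds are
$R_{\max} \in (0, 10\,\max]$, $K \in [\min I/10, 10 \max I]$,
$n \in (0, 10]$. Fewer than 4 intensities or negative amplitudes raise a
classed error; an all-zero response returns a flagged degenerate fit rather
than failing a whole study. A `k_identifiable` flag marks fits where the
response spread is under 1 % of R_max or K sits on a bound — such K values
are excluded from K statistics downstream.

Correctness is established two ways that are never collapsed: exact-class
recovery on noise-free Hill data, and a noisy benchmark in which the fitter
is compared replicate-by-replicate against an independent grid-search
least-squares oracle (hierarchical geometric grids refined to 1 %
resolution, implemented only in the test helpers and the acceptance script).

## 5. Statistics

- `welch_test()` wraps `stats::t.test(var.equal = FALSE)`; the suite checks
  it against the closed-form Welch/Satterthwaite formulas and measures the
  empirical type-I rate under the null preset. Two identical constant
  samples return p = 1 by convention; degenerate inputs raise classed
  errors. Significance stars use strict inequalities (`p < 0.05` → `*`,
  `< 0.01` → `**`, `< 0.001` → `***`), with boundary values falling to the
  less significant bin.
- `compare_per_intensity()` and `compare_parameters()` run Welch tests per
  intensity and per fitted parameter (R_max and log10 K; K is compared on
  the log scale because its sampling distribution is closer to lognormal).
  Non-converged, degenerate or K-unidentifiable fits are dropped from the
  corresponding comparisons.
- `proportionality()` normalizes each mutant retina's component R_max by the
  wild-type group mean and plots component pairs against the identity line;
  the signed diagonal distance $(y - x)/\sqrt2$ is the deviation statistic,
  summarized with a seeded bootstrap CI (`proportionality_deviation()`).
  Uniform scaling puts all points on the diagonal (deviation 0); a
  component-selective deficit pushes points off it.
- `trajectory()` aggregates mean ± SEM of R_max per genotype × age ×
  component; SEM is `NA` for single retinas.

## 6. Problem sizes, configuration and determinism

The acquisition defaults (10 kHz, 1.4 s records) mirror real recordings, but
the validation benchmarks run at reduced problem sizes chosen for turnaround
on one CPU: 1–2 kHz sampling with 1.2 s records. These rates are far above
twice the 300 Hz filter cutoff, so amplitudes and fits are unaffected to
within the tolerances tested; the reduction only trades unnecessary temporal
oversampling for speed. Replicate counts (200 fitting replicates, 1000
type-I replicates, 8 retinas per group in preset studies) are package
choices sized so binomial/Monte-Carlo error is small relative to the
tolerances checked.

Run configuration is YAML (`run_config()`, `read_run_config()`): YAML is the
serialization for which a reader is universally available in R scientific
stacks, and the config is a flat, validated whitelist of keys — unknown keys
and invalid values are classed errors, not warnings. `run_pipeline()` writes
CSV result tables and a `provenance.json` containing the seed, a
configuration hash and the package version; two runs under one config are
byte-identical, which the acceptance tests enforce.

## 7. Limitations

Beyond the generator simplifications of §1: the subtraction logic assumes
stable recordings across perfusion conditions (no drift correction is
applied); amplitude measurement uses fixed windows rather than adaptive peak
detection; the Hill model is fitted per retina with no hierarchical pooling;
and the bootstrap proportionality CI resamples retinas within genotype,
which is optimistic for very small groups. These are the natural next
extensions, kept out of scope to keep every shipped behaviour fully
validated against ground truth.
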