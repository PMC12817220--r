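# ergdissect

Pharmacological dissection and intensity–response analysis of ex vivo
electroretinogram (ERG) recordings, with a fully seeded synthetic waveform
generator for validation.

## Scientific background

The transretinal ERG of an isolated, superfused retina sums currents from
several cell classes. Perfusing blockers in sequence lets the individual
generators be isolated by subtraction:

| Perfusion condition | Components present |
|---|---|
| `LOCKES` (control Ringer) | photoreceptor + ON-bipolar + Müller glial (MGC) |
| `BACL2` (barium chloride) | photoreceptor + ON-bipolar |
| `BACL2_LAP4_AA` (+ L-AP4 + aspartate) | photoreceptor only |

Barium blocks the inwardly rectifying potassium channels that generate the
slow negative MGC component; L-AP4 silences the photoreceptor→ON-bipolar
synapse and removes the b-wave; aspartate suppresses remaining OFF-pathway
contributions. `ergdissect` implements the subtractions

- **MGC** = `LOCKES` − `BACL2` (slow negative wave),
- **ON-bipolar** = `BACL2` − `BACL2_LAP4_AA` (positive b-wave),
- **photoreceptor** = `BACL2_LAP4_AA` as recorded (negative a-wave with a
  fast "nose" trough and slower recovery plateau),

measures per-intensity amplitudes against a pre-flash baseline, and fits the
Hill (Naka–Rushton) intensity–response relation

R(I) = R_max · Iⁿ / (Iⁿ + Kⁿ)

per retina and component, where R_max is the saturated amplitude, K the
half-maximal flash strength and n the slope. Downstream tools compare
genotypes with Welch's unequal-variance t-test, quantify whether mutant
losses are proportional across components, and aggregate developmental
trajectories of R_max.

Because real quantitative ground truth for isolated components is
unobservable, the package ships a synthetic generator
(`simulate_family()` / `simulate_study()`) that builds each component from
alpha-function kinetics with Hill-scaled amplitudes, sums them into the three
perfusion conditions, applies an 8-pole Bessel acquisition filter and
additive recording noise, and attaches the exact ground truth as an
attribute — so every stage of the pipeline can be checked against truth.

## Quick start

Simulate one wild-type adult retina, isolate the components, measure
amplitudes and fit the photoreceptor intensity–response curve:

```r
library(ergdissect)

cfg <- sim_config(noise_sd = 2, sweeps = 3)
fam <- simulate_family("WT", "ADULT", retina_id = "r1", config = cfg, seed = 42)
fam
#> <flash_family> 81 sweep(s), 1 retina(s), 3 condition(s), 9 intensities
#>   sample_rate 10000 Hz, flash at t0 = 0.2 s, 14000 samples/trace
#> # A tibble: 81 × 8
#>    retina_id genotype age_class age_days condition intensity sweep samples
#>  * <chr>     <chr>    <chr>        <int> <chr>         <dbl> <int> <list>
#>  1 r1        WT       ADULT           60 BACL2           5       1 <dbl>
#>  ...

comp <- derive_components(average_sweeps(fam))
amps <- primary_amplitudes(measure_components(comp))
amps
#> # A tibble: 27 × 9
#>    retina_id genotype age_class age_days component  intensity amplitude polarity
#>    <chr>     <chr>    <chr>        <int> <chr>          <dbl>     <dbl>    <dbl>
#>  1 r1        WT       ADULT           60 PHOTORECE…       5        5.60       -1
#>  2 r1        WT       ADULT           60 ON_BIPOLAR       5       14.9         1
#>  3 r1        WT       ADULT           60 MGC              5        9.32       -1
#>  ...

fit <- fit_hill(dplyr::filter(amps, component == "PHOTORECEPTOR"))
fit
#> <hill_fit> r_max = 396.7 uV, k = 1087 photons/um^2 (log10 k = 3.036), n = 0.976
#>   rss = 25.91, n_obs = 9, converged: TRUE, k identifiable: TRUE

tidy(fit)
#> # A tibble: 3 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 r_max  397.       2.18
#> 2 k     1087.      23.5
#> 3 n        0.976    0.0160
```

(The fitted r_max of 397 µV differs from the wild-type adult mean of 320 µV
because retina-to-retina variability, `retina_cv`, is on by default.)

Plot helpers return ggplot objects: `plot_components()`,
`plot_intensity_response()`, `autoplot()` on a `hill_fit`,
`plot_proportionality()`, `plot_trajectory()`.

## Group comparisons

`simulate_amplitudes()` is a fast amplitude-level generator (it skips
waveforms) useful for statistical work; `fit_hill_all()` fits every
retina × component, and `compare_parameters()` runs Welch tests per
genotype × component:

```r
amps <- simulate_amplitudes(age_class = "ADULT", n_retinas = 8, seed = 7)
res  <- compare_parameters(fit_hill_all(amps))
dplyr::filter(res, parameter == "r_max")
#> # A tibble: 9 × 15
#>   genotype component     parameter group1 group2    n1    n2 mean1 mean2 ...
#> 1 C59S     MGC           r_max     WT     C59S       8     8  319.  146.
#> 2 C59S     ON_BIPOLAR    r_max     WT     C59S       8     8  452.  224.
#> 3 C59S     PHOTORECEPTOR r_max     WT     C59S       8     8  378.  158.
#> ...                                             p_value star
#>                                              0.000156   ***
```

The shipped genotype presets (`genotype_effects()`) encode a retinoschisis-like
pattern: uniform R_max loss in all mutants at adult ages, photoreceptor-led
loss at eye opening with an MGC gain in `C59S`, and no differences before eye
opening.

The full pipeline — simulate, isolate, measure, fit, compare, aggregate —
runs from a validated YAML config via `run_pipeline(run_config(...))`, which
writes CSV result tables plus a `provenance.json` (seed, config hash,
package version). A thin command-line wrapper lives at
`inst/scripts/ergdissect.R`.

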