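t_grid <- seq(-0.2, 1.2, by = 1e-3)

test_that("component waveforms obey the Hill amplitude law exactly", {
  m <- component_model("MGC", r_max = 150, k = 400, n = 1)
  expect_equal(component_waveform(m, 0, t_grid), rep(0, length(t_grid)))
  # saturation limit
  w <- component_waveform(m, 1e6 * 400, t_grid)
  expect_equal(max(abs(w)), 150, tolerance = 1e-3)
  # half-maximal definition of K
  w2 <- component_waveform(m, 400, t_grid)
  expect_equal(max(abs(w2)), 75, tolerance = 1e-9)
  expect_error(component_waveform(m, -5, t_grid),
               class = "erg_structure_error")
})

test_that("peak magnitude matches the Hill form for random parameters", {
  set.seed(21)
  for (i in 1:20) {
    kind <- sample(erg_components(), 1)
    m <- component_model(kind, r_max = runif(1, 50, 500),
                         k = 10^runif(1, 1, 4), n = runif(1, 0.5, 2))
    I <- 10^runif(1, 0.7, 4.7)
    w <- component_waveform(m, I, t_grid)
    expect_equal(max(abs(w)), hill_amplitude(I, m$r_max, m$k, m$n),
                 tolerance = 1e-9)
  }
})

test_that("polarities and time-to-extremum ordering match the waveform anatomy", {
  p <- component_waveform(component_model("PHOTORECEPTOR", 300, 1000), 5e4, t_grid)
  b <- component_waveform(component_model("ON_BIPOLAR", 300, 100), 5e4, t_grid)
  m <- component_waveform(component_model("MGC", 300, 400), 5e4, t_grid)
  expect_lt(min(p), 0); expect_equal(max(p), 0)
  expect_gt(max(b), 0); expect_equal(min(b), 0)
  expect_lt(min(m), 0)
  t_p <- t_grid[which.min(p)]
  t_b <- t_grid[which.max(b)]
  t_m <- t_grid[which.min(m)]
  expect_lt(t_p, t_b)
  expect_lt(t_b, t_m)
  # photoreceptor: fast trough then partial relaxation to a slower plateau
  expect_lt(t_p, 0.1)
  plateau <- mean(p[t_grid >= 0.4 & t_grid <= 0.6])
  expect_lt(plateau, 0)           # still hyperpolarised
  expect_gt(plateau, min(p))      # but relaxed from the nose
})

test_that("noise-free condition traces are exact component sums", {
  fam <- simulate_family("WT", "ADULT", "r1", fast_config(), seed = 3)
  gt <- attr(fam, "ground_truth")$traces
  tb <- tibble::as_tibble(fam)
  get <- function(cond, i) tb$samples[[which(tb$condition == cond &
                                               tb$intensity == i)]]
  ggt <- function(comp, i) gt$samples[[which(gt$component == comp &
                                               gt$intensity == i)]]
  for (i in unique(tb$intensity)) {
    expect_equal(get("LOCKES", i) - get("BACL2", i), ggt("MGC", i),
                 tolerance = 1e-12)
    expect_equal(get("BACL2", i) - get("BACL2_LAP4_AA", i),
                 ggt("ON_BIPOLAR", i), tolerance = 1e-12)
    expect_identical(get("BACL2_LAP4_AA", i), ggt("PHOTORECEPTOR", i))
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- fast_config(noise_sd = 2, sweeps = 2, retina_cv = 0.15)
  f1 <- simulate_family("KO", "ADULT", "r1", cfg, seed = 99)
  f2 <- simulate_family("KO", "ADULT", "r1", cfg, seed = 99)
  expect_identical(f1$samples, f2$samples)
  expect_identical(attr(f1, "ground_truth"), attr(f2, "ground_truth"))
  f3 <- simulate_family("KO", "ADULT", "r1", cfg, seed = 100)
  expect_false(identical(f1$samples, f3$samples))
})

test_that("genotype r_max scaling propagates multiplicatively to ground truth", {
  eff <- genotype_effects("ADULT")
  eff$r_max_scale[eff$genotype == "KO" &
                    eff$component == "PHOTORECEPTOR"] <- 0.5
  eff$r_max_scale[eff$genotype == "KO" &
                    eff$component != "PHOTORECEPTOR"] <- 1
  cfg <- fast_config()
  wt <- simulate_family("WT", "ADULT", "w", cfg, effects = eff, seed = 5)
  ko <- simulate_family("KO", "ADULT", "k", cfg, effects = eff, seed = 5)
  gtw <- attr(wt, "ground_truth")$traces
  gtk <- attr(ko, "ground_truth")$traces
  for (i in unique(gtw$intensity)) {
    pw <- gtw$samples[[which(gtw$component == "PHOTORECEPTOR" &
                               gtw$intensity == i)]]
    pk <- gtk$samples[[which(gtk$component == "PHOTORECEPTOR" &
                               gtk$intensity == i)]]
    expect_equal(min(pk) / min(pw), 0.5, tolerance = 1e-9)
  }
})

test_that("acquisition filter has unit DC gain and strong stopband attenuation", {
  expect_equal(acquisition_filter(rep(5, 200), 1000), rep(5, 200))
  expect_equal(acquisition_filter(rep(0, 200), 1000), rep(0, 200))
  fs <- 10000
  x <- sin(2 * pi * 3000 * (0:(fs - 1)) / fs)
  y <- acquisition_filter(x, fs)
  atten <- max(abs(y[(fs / 2):fs]))
  expect_lt(atten, 1 / 20)
  # time-domain attenuation agrees with the impulse-response FFT oracle
  gain <- impulse_gain_oracle(function(v) acquisition_filter(v, fs),
                              3000, fs)
  expect_equal(atten, gain, tolerance = 0.05 * max(gain, 1e-6) + 1e-6)
  expect_error(acquisition_filter(x, fs, cutoff_hz = 6000),
               class = "erg_structure_error")
})

test_that("simulate_amplitudes is seeded and shaped for the statistics layer", {
  a1 <- simulate_amplitudes(n_retinas = 3, seed = 7)
  a2 <- simulate_amplitudes(n_retinas = 3, seed = 7)
  expect_identical(a1, a2)
  expect_setequal(
    names(a1),
    c("retina_id", "genotype", "age_class", "component", "intensity",
      "amplitude", "polarity", "phase"))
  expect_true(all(a1$amplitude >= 0))
  expect_equal(nrow(a1), 4 * 3 * 3 * 9)
})
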