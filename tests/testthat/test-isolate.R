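test_that("sweep averaging is idempotent, symmetric and a no-op for singles", {
  fam3 <- constant_family(values = c(LOCKES = 7, BACL2 = 7,
                                     BACL2_LAP4_AA = 7), sweeps = 3)
  avg <- average_sweeps(fam3)
  expect_equal(nrow(avg), 3 * 4)
  expect_true(all(vapply(avg$samples, function(s) all(s == 7), TRUE)))

  tb <- tibble::as_tibble(constant_family(sweeps = 3))
  tb$samples <- lapply(seq_len(nrow(tb)), function(i) {
    rep(c(10, 0, -10)[tb$sweep[i]], 600)
  })
  fam <- flash_family(tb, 1000, 0.2)
  avg2 <- average_sweeps(fam)
  expect_true(all(vapply(avg2$samples, function(s) all(s == 0), TRUE)))

  one <- constant_family(values = c(LOCKES = 3, BACL2 = 2,
                                    BACL2_LAP4_AA = 1), sweeps = 1)
  avg3 <- average_sweeps(one)
  expect_identical(tibble::as_tibble(avg3)$samples,
                   tibble::as_tibble(one)$samples)
})

test_that("derived components follow the condition arithmetic and sign conventions", {
  fam <- simulate_family("WT", "ADULT", "r1", fast_config(), seed = 13)
  comp <- derive_components(average_sweeps(fam))
  gt <- attr(fam, "ground_truth")$traces
  tb <- tibble::as_tibble(comp)
  expect_setequal(unique(tb$component), erg_components())
  for (r in seq_len(nrow(tb))) {
    g <- gt$samples[[which(gt$component == tb$component[r] &
                             gt$intensity == tb$intensity[r])]]
    expect_equal(tb$samples[[r]], g, tolerance = 1e-12)
  }
  # derived MGC trough is negative, ON-bipolar peak positive
  mgc <- tb$samples[[which(tb$component == "MGC" &
                             tb$intensity == max(tb$intensity))]]
  onb <- tb$samples[[which(tb$component == "ON_BIPOLAR" &
                             tb$intensity == max(tb$intensity))]]
  expect_lt(min(mgc), 0)
  expect_gt(max(onb), 0)
})

test_that("self-subtraction gives a zero MGC component", {
  fam <- constant_family(values = c(LOCKES = 4, BACL2 = 4,
                                    BACL2_LAP4_AA = 0))
  comp <- derive_components(average_sweeps(fam))
  tb <- tibble::as_tibble(comp)
  mgc <- tb$samples[tb$component == "MGC"]
  expect_true(all(vapply(mgc, function(s) all(s == 0), TRUE)))
  amps <- measure_components(comp)
  expect_true(all(amps$amplitude[amps$component == "MGC"] == 0))
})

test_that("missing conditions and unmatched intensities are errors", {
  fam <- constant_family()
  drop_drugged <- tibble::as_tibble(fam) |>
    dplyr::filter(condition != "BACL2_LAP4_AA")
  fam2 <- flash_family(drop_drugged, 1000, 0.2)
  expect_error(derive_components(fam2), class = "erg_missing_condition")
  expect_error(derive_components(fam2), "BACL2_LAP4_AA")

  tb <- tibble::as_tibble(fam)
  tb$intensity[tb$condition == "LOCKES" & tb$intensity == 10] <- 20
  fam3 <- flash_family(tb, 1000, 0.2)
  expect_error(derive_components(fam3), class = "erg_intensity_mismatch")

  # un-averaged input is rejected
  fam4 <- constant_family(sweeps = 3)
  expect_error(derive_components(fam4), class = "erg_structure_error")
})

test_that("amplitudes are baseline-referenced extremum magnitudes", {
  n <- 1200
  t0 <- 0.2
  trough <- function(base, depth) {
    x <- rep(base, n)
    x[300:400] <- depth
    x
  }
  rec <- measure_amplitude(trough(0, -150), "MGC", 1000, t0)
  expect_equal(rec$amplitude, 150)
  expect_equal(rec$polarity, -1)
  rec2 <- measure_amplitude(trough(10, -140), "MGC", 1000, t0)
  expect_equal(rec2$amplitude, 150)
  flat <- measure_amplitude(rep(0, n), "ON_BIPOLAR", 1000, t0)
  expect_equal(flat$amplitude, 0)
})

test_that("amplitude measurement is invariant to constant offsets", {
  fam <- simulate_family("WT", "ADULT", "r1",
                         fast_config(noise_sd = 2, sweeps = 3), seed = 17)
  comp <- derive_components(average_sweeps(fam))
  a0 <- measure_components(comp)
  shifted <- comp
  shifted$samples <- lapply(shifted$samples, function(s) s + 37.5)
  a1 <- measure_components(shifted)
  expect_equal(a0$amplitude, a1$amplitude, tolerance = 1e-12)
})

test_that("component derivation is linear in the input traces", {
  fam <- simulate_family("WT", "ADULT", "r1", fast_config(), seed = 19)
  avg <- average_sweeps(fam)
  scaled <- avg
  scaled$samples <- lapply(scaled$samples, function(s) 2.5 * s)
  c1 <- derive_components(avg)
  c2 <- derive_components(scaled)
  expect_equal(lapply(c2$samples, function(s) s / 2.5), c1$samples,
               tolerance = 1e-12)
})

test_that("photoreceptor nose and recovery phases are both recorded", {
  fam <- simulate_family("WT", "ADULT", "r1", fast_config(), seed = 23)
  amps <- measure_components(derive_components(average_sweeps(fam)))
  pr <- dplyr::filter(amps, component == "PHOTORECEPTOR")
  expect_setequal(unique(pr$phase), c("NOSE", "RECOVERY"))
  expect_true(all(is.na(amps$phase[amps$component != "PHOTORECEPTOR"])))
  hi <- dplyr::filter(pr, intensity == max(intensity))
  # nose trough exceeds the relaxed plateau
  expect_gt(hi$amplitude[hi$phase == "NOSE"],
            hi$amplitude[hi$phase == "RECOVERY"])
  prim <- primary_amplitudes(amps)
  expect_true(all(prim$phase[prim$component == "PHOTORECEPTOR"] == "NOSE"))
})

test_that("recovery plateau estimate is unbiased under trace noise", {
  cfg <- fast_config(noise_sd = 5, sweeps = 1)
  clean <- simulate_family("WT", "ADULT", "r0", cfg, seed = 29)
  gt <- attr(clean, "ground_truth")$traces
  i_max <- max(gt$intensity)
  base <- gt$samples[[which(gt$component == "PHOTORECEPTOR" &
                              gt$intensity == i_max)]]
  truth <- measure_amplitude(base, "PHOTORECEPTOR", 1000, 0.2,
                             phase = "RECOVERY")$amplitude
  set.seed(31)
  n_rep <- 200
  est <- replicate(n_rep, {
    noisy <- base + rnorm(length(base), 0, 5)
    measure_amplitude(noisy, "PHOTORECEPTOR", 1000, 0.2,
                      phase = "RECOVERY")$amplitude
  })
  n_win <- 0.2 * 1000
  se_single <- 5 * sqrt(1 / n_win + 1 / (0.1 * 1000))
  expect_lt(abs(mean(est) - truth), 3 * se_single / sqrt(n_rep))
})
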