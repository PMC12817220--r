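test_that("welch_test reproduces hand-computed values and the closed form", {
  w <- welch_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, -3.674, tolerance = 1e-3)
  expect_equal(w$df, 4.0, tolerance = 1e-9)

  set.seed(61)
  for (i in 1:200) {
    x <- rnorm(sample(2:15, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(2:15, 1), mean = runif(1, -1, 1),
               sd = runif(1, 0.5, 3))
    w <- welch_test(x, y)
    o <- welch_oracle(x, y)
    expect_equal(w$statistic, o$t, tolerance = 1e-10)
    expect_equal(w$df, o$df, tolerance = 1e-10)
    expect_equal(w$p_value, o$p, tolerance = 1e-10)
  }
})

test_that("welch_test edge cases follow the stated conventions", {
  x <- c(3, 1, 4, 1, 5)
  w <- welch_test(x, x)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  expect_equal(w$star, "ns")

  expect_error(welch_test(1, c(1, 2)), class = "erg_stats_error")
  const <- welch_test(rep(2, 3), rep(2, 4))
  expect_equal(const$p_value, 1)
  expect_error(welch_test(rep(1, 3), rep(2, 3)), class = "erg_stats_error")
})

test_that("significance stars partition (0, 1] with open-interval boundaries", {
  expect_equal(p_star(c(0.2, 0.04, 0.004, 1e-4)),
               c("ns", "*", "**", "***"))
  # boundary values fall to the less-significant bin
  expect_equal(p_star(c(0.05, 0.01, 0.001)), c("ns", "*", "**"))
  expect_equal(p_star(0.004), "**")
})

test_that("per-intensity comparisons detect the shipped adult effect and skip small groups", {
  amps <- simulate_amplitudes(genotypes = c("WT", "KO"),
                              age_class = "ADULT", n_retinas = 8,
                              seed = 67)
  res <- compare_per_intensity(amps)
  expect_equal(nrow(res), 3 * 9)
  mid_high <- dplyr::filter(res, intensity >= 500)
  expect_gt(mean(mid_high$p_value < 0.05), 0.5)

  solo <- dplyr::filter(amps, genotype == "WT" |
                          retina_id == amps$retina_id[amps$genotype == "KO"][1])
  warns <- testthat::capture_warnings(skipped <- compare_per_intensity(solo))
  expect_true(any(grepl("fewer than 2", warns)))
  expect_equal(nrow(skipped), 0)
})

test_that("WT-vs-WT split halves are significant at roughly the alpha rate", {
  set.seed(71)
  hits <- 0; total <- 0
  for (r in 1:120) {
    amps <- simulate_amplitudes(genotypes = c("WT", "KO"),
                                age_class = "PRE_EYE_OPENING",
                                n_retinas = 4, component = "PHOTORECEPTOR",
                                intensities = 1581, seed = 5000 + r)
    res <- compare_per_intensity(amps)
    hits <- hits + sum(res$p_value < 0.05)
    total <- total + nrow(res)
  }
  rate <- hits / total
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / total))
})

test_that("parameter comparisons mirror the adult and null patterns", {
  adult <- simulate_amplitudes(age_class = "ADULT", n_retinas = 8, seed = 73)
  fits <- fit_hill_all(adult)
  res <- compare_parameters(fits)
  rmax <- dplyr::filter(res, parameter == "r_max")
  expect_equal(nrow(rmax), 9)
  expect_true(all(rmax$p_value < 0.05))
  expect_true(all(rmax$mean2 < rmax$mean1))  # mutants reduced
  logk <- dplyr::filter(res, parameter == "log10_k")
  expect_lte(sum(logk$p_value < 0.05), 2)

  null <- simulate_amplitudes(age_class = "PRE_EYE_OPENING", n_retinas = 8,
                              seed = 79)
  res0 <- compare_parameters(fit_hill_all(null))
  expect_lte(sum(res0$p_value < 0.05), 3)

  expect_equal(nrow(compare_parameters(tibble::tibble())), 0)
})

test_that("proportionality normalisation and deviation sign behave as designed", {
  # noise-free: every mutant component scaled by the same factor
  amps <- simulate_amplitudes(age_class = "ADULT", n_retinas = 3,
                              retina_cv = 0, meas_sd = 0, seed = 83)
  fits <- fit_hill_all(amps)
  rec <- proportionality(fits)
  wt <- dplyr::filter(rec, genotype == "WT")
  expect_equal(wt$x, rep(1, nrow(wt)), tolerance = 1e-6)
  expect_equal(wt$y, rep(1, nrow(wt)), tolerance = 1e-6)
  mut <- dplyr::filter(rec, genotype != "WT")
  expect_equal(mut$deviation, rep(0, nrow(mut)), tolerance = 1e-6)

  # disproportionate ON-bipolar loss sits below the diagonal
  eff <- genotype_effects("ADULT")
  eff$r_max_scale[eff$genotype == "KO"] <- 0.5
  eff$r_max_scale[eff$genotype == "KO" &
                    eff$component == "ON_BIPOLAR"] <- 0.25
  amps2 <- simulate_amplitudes(genotypes = c("WT", "KO"),
                               age_class = "ADULT", n_retinas = 3,
                               effects = eff, retina_cv = 0, meas_sd = 0,
                               seed = 89)
  rec2 <- proportionality(fit_hill_all(amps2))
  ko <- dplyr::filter(rec2, genotype == "KO")
  expect_true(all(ko$deviation < 0))
  expect_true(all(ko$y < ko$x))

  expect_error(proportionality(dplyr::filter(fits, genotype != "WT")),
               class = "erg_stats_error")
})

test_that("bootstrap deviation interval covers zero under the null", {
  amps <- simulate_amplitudes(age_class = "ADULT", n_retinas = 8, seed = 97)
  rec <- proportionality(fit_hill_all(amps))
  summ <- proportionality_deviation(rec, n_boot = 500, seed = 7)
  expect_setequal(names(summ),
                  c("genotype", "n", "mean_deviation", "ci_lower",
                    "ci_upper"))
  # uniform adult scaling: intervals should straddle zero
  covered <- with(summ, ci_lower <= 0 & ci_upper >= 0)
  expect_gte(mean(covered), 0.75)
  # deterministic under the seed
  summ2 <- proportionality_deviation(rec, n_boot = 500, seed = 7)
  expect_identical(summ, summ2)
})

test_that("trajectory aggregates r_max by genotype, age and component", {
  per_age <- lapply(erg_age_classes(), function(ac) {
    fit_hill_all(simulate_amplitudes(genotypes = "WT", age_class = ac,
                                     n_retinas = 4, retina_cv = 0,
                                     meas_sd = 0,
                                     seed = 100 + match(ac, erg_age_classes())))
  })
  traj <- trajectory(dplyr::bind_rows(per_age))
  pr <- dplyr::filter(traj, component == "PHOTORECEPTOR")
  pr <- pr[order(pr$age_class), ]
  # photoreceptor r_max rises into eye opening, then is stable
  expect_gt(pr$mean_r_max[2], 1.5 * pr$mean_r_max[1])
  expect_lt(abs(pr$mean_r_max[3] - pr$mean_r_max[2]) / pr$mean_r_max[2],
            0.15)
  # ON-bipolar and MGC keep growing after eye opening
  for (cmp in c("ON_BIPOLAR", "MGC")) {
    cc <- dplyr::filter(traj, component == cmp)
    cc <- cc[order(cc$age_class), ]
    expect_gt(cc$mean_r_max[3], cc$mean_r_max[2])
  }
  # identical retinas: SEM exactly 0; single retina: SEM absent
  expect_true(all(traj$sem_r_max < 1e-8))
  one <- trajectory(fit_hill_all(
    simulate_amplitudes(genotypes = "WT", n_retinas = 1, seed = 3)))
  expect_true(all(is.na(one$sem_r_max)))
  expect_equal(nrow(trajectory(tibble::tibble())), 0)
})
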