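# Small simulation configurations used across tests: coarser sampling and
# shorter records than the acquisition defaults keep individual tests fast
# without changing the model structure.

fast_config <- function(noise_sd = 0, sweeps = 1, retina_cv = 0,
                        sample_rate = 1000, record_length = 1.2, ...) {
  sim_config(noise_sd = noise_sd, sweeps = sweeps, retina_cv = retina_cv,
             sample_rate = sample_rate, record_length = record_length, ...)
}

# minimal hand-built flash family: constant traces per condition, no noise
constant_family <- function(values = c(LOCKES = 0, BACL2 = 0,
                                       BACL2_LAP4_AA = 0),
                            intensities = c(10, 100, 1000, 10000),
                            sweeps = 1, n = 1200, sample_rate = 1000,
                            t0_flash = 0.2) {
  grid <- expand.grid(condition = names(values),
                      intensity = intensities,
                      sweep = seq_len(sweeps),
                      stringsAsFactors = FALSE)
  grid$samples <- lapply(seq_len(nrow(grid)), function(i) {
    rep(unname(values[grid$condition[i]]), n)
  })
  sweeps_tb <- tibble::tibble(
    retina_id = "t1", genotype = "WT", age_class = "ADULT", age_days = 60L,
    condition = grid$condition, intensity = grid$intensity,
    sweep = as.integer(grid$sweep), samples = grid$samples)
  flash_family(sweeps_tb, sample_rate = sample_rate, t0_flash = t0_flash)
}
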