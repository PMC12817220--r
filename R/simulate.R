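#' Hill-type intensity-response amplitude
#'
#' Saturating amplitude law `R(I) = r_max * I^n / (I^n + k^n)`, where `k` is
#' the flash intensity eliciting a half-maximal response (photons/um^2) and
#' `n` the dimensionless slope. The same form is used by the waveform
#' generator and by [fit_hill()], so simulated and fitted parameters live on
#' the same scale.
#'
#' @param intensity Flash intensity (photons/um^2), >= 0. Vectorised.
#' @param r_max Maximal response amplitude (microvolts), >= 0.
#' @param k Half-maximal intensity (photons/um^2), > 0.
#' @param n Hill slope, > 0.
#' @return Amplitude in microvolts; 0 at intensity 0, `r_max/2` at
#'   `intensity == k`, `r_max` in the saturation limit.
#' @export
#' @examples
#' hill_amplitude(200, r_max = 300, k = 200, n = 1)  # half-maximal
hill_amplitude <- function(intensity, r_max, k, n) {
  stopifnot(all(intensity >= 0), r_max >= 0, k > 0, n > 0)
  ik <- (intensity / k)^n
  r_max * ik / (ik + 1)
}

#' Ground-truth component model for the simulator
#'
#' Bundles the Hill parameters and kinetic constants that generate one
#' cellular component's waveform. Kinetics are sums of alpha-type functions
#' `(t/tau) * exp(1 - t/tau)`; the photoreceptor adds a fast "nose" trough
#' of fractional depth `nose_frac` on top of a slower sustained phase, and
#' the ON-bipolar response is delayed by a synaptic `delay`.
#'
#' @param kind One of [erg_components()].
#' @param r_max Maximal amplitude (microvolts, >= 0).
#' @param k Half-maximal intensity (photons/um^2, > 0).
#' @param n Hill slope (> 0).
#' @param kinetics Named list of kinetic constants (seconds), component
#'   dependent. Defaults reproduce the canonical waveform ordering: fast
#'   photoreceptor trough, later ON-bipolar peak, slowest MGC trough.
#' @return A `component_model` list.
#' @export
component_model <- function(kind, r_max, k, n = 1, kinetics = NULL) {
  kind <- match.arg(kind, erg_components())
  stopifnot(r_max >= 0, k > 0, n > 0)
  default_kin <- switch(kind,
    PHOTORECEPTOR = list(tau_nose = 0.012, tau_rise = 0.008,
                         tau_slow = 0.8, nose_frac = 0.3),
    ON_BIPOLAR = list(delay = 0.02, tau = 0.08),
    MGC = list(tau = 0.30))
  kinetics <- utils::modifyList(default_kin, kinetics %||% list())
  if (any(unlist(kinetics[grep("^tau", names(kinetics))]) <= 0)) {
    rlang::abort("All kinetic time constants must be > 0.")
  }
  if (!is.null(kinetics$delay) && kinetics$delay < 0) {
    rlang::abort("ON-bipolar synaptic delay must be >= 0.")
  }
  structure(list(kind = kind, r_max = r_max, k = k, n = n,
                 kinetics = kinetics),
            class = "component_model")
}

# alpha function, peak 1 at t = tau, zero for t <= 0
alpha_fn <- function(t, tau) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / tau) * exp(1 - t[pos] / tau)
  out
}

# unit-peak waveform shape on the grid (unsigned); t relative to flash onset
component_shape <- function(model, t) {
  kin <- model$kinetics
  s <- switch(model$kind,
    PHOTORECEPTOR = {
      sustained <- ifelse(t > 0,
                          (1 - exp(-pmax(t, 0) / kin$tau_rise)) *
                            exp(-pmax(t, 0) / kin$tau_slow), 0)
      kin$nose_frac * alpha_fn(t, kin$tau_nose) +
        (1 - kin$nose_frac) * sustained
    },
    ON_BIPOLAR = alpha_fn(t - kin$delay, kin$tau),
    MGC = alpha_fn(t, kin$tau))
  peak <- max(s)
  if (peak > 0) s / peak else s
}

#' Generate one component's waveform at a given flash intensity
#'
#' The waveform is the component's unit-peak kinetic shape scaled by the
#' Hill amplitude [hill_amplitude()] at that intensity and signed by the
#' component's polarity (negative for photoreceptor and MGC, positive for
#' ON-bipolar). Because the shape is normalised to unit peak on the supplied
#' time grid, the waveform's peak magnitude equals the Hill amplitude
#' exactly.
#'
#' @param model A [component_model()].
#' @param intensity Flash intensity (photons/um^2), >= 0.
#' @param t Numeric time grid in seconds relative to flash onset (t = 0 at
#'   the flash; negative times are pre-stimulus and give 0).
#' @return Numeric voltage vector (microvolts) on `t`.
#' @export
#' @examples
#' m <- component_model("MGC", r_max = 150, k = 400)
#' w <- component_waveform(m, 400, seq(-0.1, 1.2, by = 1e-3))
#' min(w)  # -75: half-maximal trough
component_waveform <- function(model, intensity, t) {
  if (length(intensity) != 1 || intensity < 0) {
    rlang::abort("`intensity` must be a single value >= 0.",
                 class = "erg_structure_error")
  }
  amp <- hill_amplitude(intensity, model$r_max, model$k, model$n)
  component_polarity(model$kind) * amp * component_shape(model, t)
}

#' Digital 8-pole Bessel low-pass filter emulating the acquisition chain
#'
#' Designs the analog Bessel prototype of the requested order from the
#' reverse Bessel polynomial (closed-form coefficients), rescales it so the
#' -3 dB point sits at `cutoff_hz`, and discretises by bilinear transform.
#' Filtering is causal; the trace is offset by its first sample before
#' filtering and restored after, so a constant trace passes unchanged
#' (DC gain 1) with no start-up transient.
#'
#' @param samples Numeric voltage trace.
#' @param sample_rate Sampling rate in Hz.
#' @param cutoff_hz -3 dB cutoff frequency in Hz (default 300), must be
#'   below Nyquist.
#' @param poles Filter order (default 8).
#' @return Filtered trace, same length.
#' @export
#' @examples
#' acquisition_filter(rep(5, 100), sample_rate = 1000)[1:3]  # unchanged
acquisition_filter <- function(samples, sample_rate, cutoff_hz = 300,
                               poles = 8) {
  ba <- bessel_lowpass(sample_rate, cutoff_hz, poles)
  x0 <- samples[1]
  x0 + as.numeric(signal::filter(ba, samples - x0))
}

# cache filter designs per (fs, cutoff, poles)
.filter_cache <- new.env(parent = emptyenv())

bessel_lowpass <- function(sample_rate, cutoff_hz, poles) {
  if (cutoff_hz >= sample_rate / 2) {
    rlang::abort(sprintf(
      "Filter cutoff (%g Hz) must be below Nyquist (%g Hz).",
      cutoff_hz, sample_rate / 2), class = "erg_structure_error")
  }
  key <- paste(sample_rate, cutoff_hz, poles, sep = "_")
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  # reverse Bessel polynomial: a_k = (2n-k)! / (2^(n-k) k! (n-k)!), k = 0..n
  n <- poles
  k <- 0:n
  a <- factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
  p <- polyroot(a)  # poles of the delay-normalised prototype
  gain <- Re(prod(-p))
  mag <- function(w) abs(gain / apply(outer(1i * w, p, "-"), 1, prod))
  w3 <- stats::uniroot(function(w) mag(w) - 1 / sqrt(2), c(0.05, 20))$root
  p_scaled <- p * (2 * pi * cutoff_hz) / w3
  zp <- signal::bilinear(Sz = numeric(0), Sp = p_scaled,
                         Sg = Re(prod(-p_scaled)), T = 1 / sample_rate)
  arma <- signal::as.Arma(signal::Zpg(zero = zp$zero, pole = zp$pole,
                                      gain = zp$gain))
  ba <- signal::Arma(Re(arma$b), Re(arma$a))
  .filter_cache[[key]] <- ba
  ba
}

# analytic magnitude response of the designed digital filter, used as the
# attenuation oracle in tests
bessel_lowpass_gain <- function(freq_hz, sample_rate, cutoff_hz = 300,
                                poles = 8) {
  ba <- bessel_lowpass(sample_rate, cutoff_hz, poles)
  z <- exp(-1i * 2 * pi * freq_hz / sample_rate)
  abs(sum(ba$b * z^(seq_along(ba$b) - 1)) /
        sum(ba$a * z^(seq_along(ba$a) - 1)))
}

#' Simulation configuration
#'
#' Defaults emulate the acquisition protocol the analysis expects: nine
#' log-spaced flash intensities spanning 5 to 50,000 photons/um^2, sweeps
#' collected in triplicate, 10 kHz sampling through a 300 Hz 8-pole Bessel
#' low-pass, 1-4 ms flashes, and additive Gaussian noise of 2 uV SD per
#' sample. Between-retina biological variability is lognormal with
#' coefficient of variation `retina_cv` on both r_max and K.
#'
#' @param intensities Flash intensity series (photons/um^2).
#' @param sweeps Sweeps per stimulus (default 3).
#' @param sample_rate Hz (default 10000).
#' @param pre_stimulus Pre-flash recording length, seconds (default 0.2).
#' @param record_length Total trace duration, seconds (default 1.4).
#' @param flash_duration Seconds (default 0.002).
#' @param noise_sd Per-sample Gaussian noise SD, microvolts (default 2).
#' @param drift Linear drift over the whole trace, microvolts (default 0).
#' @param retina_cv Between-retina lognormal CV on r_max and K (default
#'   0.15).
#' @param apply_filter Apply the acquisition Bessel filter (default TRUE).
#' @param filter_cutoff,filter_poles Filter parameters (300 Hz, 8 poles).
#' @param mgc_residual Fraction of the MGC component surviving BaCl2
#'   blockade (default 0: complete removal).
#' @return A `sim_config` list.
#' @export
sim_config <- function(intensities = canonical_intensity(
                         10^seq(log10(5), log10(50000), length.out = 9)),
                       sweeps = 3,
                       sample_rate = 10000,
                       pre_stimulus = 0.2,
                       record_length = 1.4,
                       flash_duration = 0.002,
                       noise_sd = 2,
                       drift = 0,
                       retina_cv = 0.15,
                       apply_filter = TRUE,
                       filter_cutoff = 300,
                       filter_poles = 8,
                       mgc_residual = 0) {
  stopifnot(all(intensities > 0), sweeps >= 1, sample_rate > 0,
            pre_stimulus > 0, record_length > pre_stimulus,
            flash_duration > 0, noise_sd >= 0, retina_cv >= 0,
            mgc_residual >= 0, mgc_residual <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Baseline wildtype component parameters by age class
#'
#' Ground-truth Hill parameters used by the simulator for wildtype retinas.
#' The developmental pattern follows the known maturation of the ex vivo
#' ERG: the photoreceptor response grows up to eye opening and then
#' stabilises, while ON-bipolar and MGC responses keep growing into
#' adulthood.
#'
#' @param age_class One of [erg_age_classes()].
#' @return Tibble with columns `component`, `r_max` (uV), `k`
#'   (photons/um^2), `n`.
#' @export
baseline_components <- function(age_class = "ADULT") {
  age_class <- match.arg(age_class, erg_age_classes())
  rmax <- switch(age_class,
    PRE_EYE_OPENING = c(PHOTORECEPTOR = 150, ON_BIPOLAR = 100, MGC = 80),
    EYE_OPENING     = c(PHOTORECEPTOR = 300, ON_BIPOLAR = 250, MGC = 150),
    ADULT           = c(PHOTORECEPTOR = 320, ON_BIPOLAR = 450, MGC = 300))
  tibble::tibble(
    component = erg_components(),
    r_max = unname(rmax[erg_components()]),
    k = c(1000, 100, 400),
    n = c(1, 1.2, 1))
}

#' Genotype effect presets
#'
#' Multiplicative scalings of per-component r_max and K applied to mutant
#' genotypes relative to wildtype, per age class. The shipped preset encodes
#' the qualitative disease pattern of the Rs1 mutants: in adults every
#' component is reduced by about half in every mutant; at eye opening the
#' photoreceptor is reduced in all mutants, the ON-bipolar only in R141C,
#' and the MGC is enhanced (larger and more sensitive) in C59S; before eye
#' opening all genotypes are indistinguishable.
#'
#' @param age_class One of [erg_age_classes()], or `"all"` for the full
#'   table across age classes.
#' @return Tibble with columns `genotype`, `age_class`, `component`,
#'   `r_max_scale`, `k_scale`. Wildtype factors are all 1.
#' @export
#' @examples
#' genotype_effects("ADULT")
genotype_effects <- function(age_class = "all") {
  grid <- tidyr::expand_grid(
    genotype = erg_genotypes(),
    age_class = erg_age_classes(),
    component = erg_components())
  eff <- grid %>%
    dplyr::mutate(
      r_max_scale = dplyr::case_when(
        .data$genotype == "WT" ~ 1,
        .data$age_class == "ADULT" ~ 0.5,
        .data$age_class == "EYE_OPENING" &
          .data$component == "PHOTORECEPTOR" ~ 0.6,
        .data$age_class == "EYE_OPENING" & .data$component == "ON_BIPOLAR" &
          .data$genotype == "R141C" ~ 0.6,
        .data$age_class == "EYE_OPENING" & .data$component == "MGC" &
          .data$genotype == "C59S" ~ 1.4,
        TRUE ~ 1),
      k_scale = dplyr::case_when(
        .data$genotype != "WT" & .data$age_class == "EYE_OPENING" &
          .data$component == "MGC" & .data$genotype == "C59S" ~ 0.7,
        TRUE ~ 1))
  if (age_class != "all") {
    age_class <- match.arg(age_class, erg_age_classes())
    eff <- dplyr::filter(eff, .data$age_class == !!age_class)
  }
  eff
}

# deterministic child seed fan-out: one substream per retina index
child_seed <- function(seed, index) {
  (as.integer(seed) %% 100003L) * 10007L %% 2147483647L + index
}

age_days_for <- function(age_class) {
  switch(age_class, PRE_EYE_OPENING = 11L, EYE_OPENING = 13L, ADULT = 60L)
}

#' Simulate one retina's flash family with ground truth
#'
#' Builds the three cellular component waveforms for every flash intensity,
#' passes each through the acquisition filter, and assembles the three
#' perfusion conditions by additive composition: Locke's = P + B + M;
#' Locke's + BaCl2 = P + B (plus any configured MGC residual); Locke's +
#' BaCl2 + L-AP4 + AA = P. Gaussian noise and optional drift are added per
#' sweep. With `noise_sd = 0` the condition traces obey the component sums
#' exactly, sample for sample.
#'
#' @param genotype One of [erg_genotypes()].
#' @param age_class One of [erg_age_classes()].
#' @param retina_id Identifier string.
#' @param config A [sim_config()].
#' @param effects Genotype-effect table as from [genotype_effects()];
#'   defaults to the shipped preset for `age_class`.
#' @param seed Integer seed for this retina's biological variability and
#'   noise.
#' @return A [flash_family()] with a `ground_truth` attribute: a list with
#'   `params` (per-component effective r_max, k, n) and `traces`
#'   (per-component, per-intensity noise-free filtered waveforms, as a
#'   tibble with a `samples` list-column).
#' @export
simulate_family <- function(genotype, age_class, retina_id,
                            config = sim_config(),
                            effects = genotype_effects(age_class),
                            seed = 1L) {
  genotype <- match.arg(genotype, erg_genotypes())
  age_class <- match.arg(age_class, erg_age_classes())
  set.seed(seed)
  base <- baseline_components(age_class)
  eff <- effects %>%
    dplyr::filter(.data$genotype == !!genotype,
                  .data$age_class == !!age_class) %>%
    dplyr::select("component", "r_max_scale", "k_scale")
  if (nrow(eff) != 3) {
    rlang::abort("`effects` must cover all three components for this genotype/age class.")
  }
  params <- base %>%
    dplyr::left_join(eff, by = "component") %>%
    dplyr::mutate(
      r_max = .data$r_max * .data$r_max_scale *
        exp(stats::rnorm(dplyr::n(), 0, config$retina_cv)),
      k = .data$k * .data$k_scale *
        exp(stats::rnorm(dplyr::n(), 0, config$retina_cv))) %>%
    dplyr::select("component", "r_max", "k", "n")

  n_samp <- round(config$record_length * config$sample_rate)
  t <- (seq_len(n_samp) - 1) / config$sample_rate - config$pre_stimulus

  models <- purrr::pmap(params, function(component, r_max, k, n) {
    component_model(component, r_max = r_max, k = k, n = n)
  })
  names(models) <- params$component

  intensities <- canonical_intensity(config$intensities)
  # noise-free filtered component traces per intensity
  gt_traces <- tidyr::expand_grid(component = erg_components(),
                                  intensity = intensities)
  gt_traces$samples <- purrr::map2(gt_traces$component, gt_traces$intensity,
    function(comp, i) {
      w <- component_waveform(models[[comp]], i, t)
      if (config$apply_filter) {
        w <- acquisition_filter(w, config$sample_rate,
                                config$filter_cutoff, config$filter_poles)
      }
      w
    })

  comp_of <- function(comp, i) {
    gt_traces$samples[[which(gt_traces$component == comp &
                               gt_traces$intensity == i)]]
  }
  condition_trace <- function(cond, i) {
    switch(cond,
      LOCKES = comp_of("PHOTORECEPTOR", i) + comp_of("ON_BIPOLAR", i) +
        comp_of("MGC", i),
      BACL2 = comp_of("PHOTORECEPTOR", i) + comp_of("ON_BIPOLAR", i) +
        config$mgc_residual * comp_of("MGC", i),
      BACL2_LAP4_AA = comp_of("PHOTORECEPTOR", i))
  }

  grid <- tidyr::expand_grid(condition = erg_conditions(),
                             intensity = intensities,
                             sweep = seq_len(config$sweeps))
  drift_vec <- if (config$drift != 0) {
    config$drift * (seq_len(n_samp) - 1) / (n_samp - 1)
  } else {
    numeric(n_samp)
  }
  grid$samples <- purrr::pmap(grid, function(condition, intensity, sweep) {
    clean <- condition_trace(condition, intensity)
    if (config$noise_sd > 0) {
      clean <- clean + stats::rnorm(n_samp, 0, config$noise_sd)
    }
    clean + drift_vec
  })

  sweeps <- tibble::tibble(
    retina_id = retina_id, genotype = genotype, age_class = age_class,
    age_days = age_days_for(age_class),
    condition = grid$condition, intensity = grid$intensity,
    sweep = as.integer(grid$sweep), samples = grid$samples)
  fam <- flash_family(sweeps, sample_rate = config$sample_rate,
                      t0_flash = config$pre_stimulus,
                      flash_duration = config$flash_duration)
  attr(fam, "ground_truth") <- list(params = params, traces = gt_traces)
  fam
}

#' Simulate a whole study arm: several retinas per genotype
#'
#' Runs [simulate_family()] for `n_retinas` retinas of each genotype at one
#' age class, with a deterministic per-retina child seed derived from
#' `seed`, and binds the results into one flash family. Ground truth is
#' carried along with retina identifiers.
#'
#' @param genotypes Character vector of genotypes (default all four).
#' @param age_class One of [erg_age_classes()].
#' @param n_retinas Retinas per genotype.
#' @param config A [sim_config()].
#' @param effects Genotype-effect table (default shipped preset).
#' @param seed Top-level integer seed; every retina gets a derived child
#'   seed, so the whole study is reproducible from this one value.
#' @return A [flash_family()] spanning all retinas, with a `ground_truth`
#'   attribute (list of `params` and `traces` tibbles keyed by `retina_id`).
#' @export
simulate_study <- function(genotypes = erg_genotypes(),
                           age_class = "ADULT",
                           n_retinas = 8,
                           config = sim_config(),
                           effects = genotype_effects(age_class),
                           seed = 1L) {
  grid <- tidyr::expand_grid(genotype = genotypes,
                             replicate = seq_len(n_retinas))
  fams <- purrr::pmap(grid, function(genotype, replicate) {
    rid <- sprintf("%s_%s_%02d", genotype, age_class, replicate)
    idx <- which(grid$genotype == genotype & grid$replicate == replicate)
    simulate_family(genotype, age_class, rid, config = config,
                    effects = effects, seed = child_seed(seed, idx))
  })
  sweeps <- purrr::map_dfr(fams, tibble::as_tibble)
  gt_params <- purrr::map_dfr(fams, function(f) {
    dplyr::mutate(attr(f, "ground_truth")$params,
                  retina_id = f$retina_id[1],
                  genotype = f$genotype[1], age_class = f$age_class[1],
                  .before = 1)
  })
  gt_traces <- purrr::map_dfr(fams, function(f) {
    dplyr::mutate(attr(f, "ground_truth")$traces,
                  retina_id = f$retina_id[1], .before = 1)
  })
  out <- flash_family(sweeps, sample_rate = config$sample_rate,
                      t0_flash = config$pre_stimulus,
                      flash_duration = config$flash_duration)
  attr(out, "ground_truth") <- list(params = gt_params, traces = gt_traces)
  out
}

#' Fast amplitude-level simulator
#'
#' Draws per-retina component amplitudes directly from the generative
#' amplitude model — Hill law with lognormal between-retina variability on
#' r_max and K, plus Gaussian measurement noise — without synthesising
#' waveforms. Used for statistical benchmarks (type-I error, power,
#' parameter-recovery replicates) where only the amplitude table matters.
#'
#' @param genotypes Character vector of genotypes.
#' @param age_class One of [erg_age_classes()].
#' @param n_retinas Retinas per genotype.
#' @param component Components to simulate (default all three).
#' @param intensities Flash intensity series.
#' @param effects Genotype-effect table (default shipped preset).
#' @param retina_cv Between-retina lognormal CV on r_max and K.
#' @param meas_sd Measurement noise SD on each amplitude, microvolts.
#' @param seed Integer seed.
#' @return Tibble with columns `retina_id`, `genotype`, `age_class`,
#'   `component`, `intensity`, `amplitude`, `polarity`, `phase`, plus a
#'   `true_params` attribute (per-retina effective r_max, k, n).
#' @export
simulate_amplitudes <- function(genotypes = erg_genotypes(),
                                age_class = "ADULT",
                                n_retinas = 8,
                                component = erg_components(),
                                intensities = sim_config()$intensities,
                                effects = genotype_effects(age_class),
                                retina_cv = 0.15,
                                meas_sd = 3,
                                seed = 1L) {
  set.seed(seed)
  base <- baseline_components(age_class)
  grid <- tidyr::expand_grid(genotype = genotypes,
                             replicate = seq_len(n_retinas),
                             component = component) %>%
    dplyr::left_join(base, by = "component") %>%
    dplyr::left_join(
      dplyr::select(dplyr::filter(effects, .data$age_class == !!age_class),
                    "genotype", "component", "r_max_scale", "k_scale"),
      by = c("genotype", "component")) %>%
    dplyr::mutate(
      retina_id = sprintf("%s_%s_%02d", .data$genotype, age_class,
                          .data$replicate),
      age_class = age_class,
      r_max = .data$r_max * .data$r_max_scale *
        exp(stats::rnorm(dplyr::n(), 0, retina_cv)),
      k = .data$k * .data$k_scale *
        exp(stats::rnorm(dplyr::n(), 0, retina_cv)))
  true_params <- dplyr::select(grid, "retina_id", "genotype", "age_class",
                               "component", "r_max", "k", "n")
  out <- tidyr::expand_grid(
    dplyr::select(grid, "retina_id", "genotype", "age_class", "component",
                  "r_max", "k", "n"),
    intensity = canonical_intensity(intensities)) %>%
    dplyr::mutate(
      amplitude = pmax(0, hill_amplitude(.data$intensity, .data$r_max,
                                         .data$k, .data$n) +
                         stats::rnorm(dplyr::n(), 0, meas_sd)),
      polarity = component_polarity(.data$component),
      phase = ifelse(.data$component == "PHOTORECEPTOR", "NOSE", NA_character_)) %>%
    dplyr::select("retina_id", "genotype", "age_class", "component",
                  "intensity", "amplitude", "polarity", "phase")
  attr(out, "true_params") <- true_params
  out
}
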