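#' Average triplicate sweeps point-wise
#'
#' Each stimulus condition is collected in replicate sweeps and averaged
#' off-line before any subtraction or measurement. Averaging is point-wise
#' with equal weights and no outlier rejection; a single sweep passes
#' through unchanged.
#'
#' @param family A [flash_family()].
#' @return A `flash_family` with one trace per (retina, condition,
#'   intensity); the `sweep` column records the number of sweeps averaged.
#' @export
average_sweeps <- function(family) {
  stopifnot(inherits(family, "flash_family"))
  tb <- tibble::as_tibble(family)
  avg <- tb %>%
    dplyr::group_by(.data$retina_id, .data$genotype, .data$age_class,
                    .data$age_days, .data$condition, .data$intensity) %>%
    dplyr::summarise(
      samples = list(Reduce(`+`, .data$samples) / length(.data$samples)),
      sweep = dplyr::n(),
      .groups = "drop") %>%
    dplyr::mutate(sweep = as.integer(.data$sweep))
  out <- flash_family(avg, sample_rate = sample_rate(family),
                      t0_flash = t0_flash(family),
                      flash_duration = attr(family, "flash_duration"))
  attr(out, "ground_truth") <- attr(family, "ground_truth")
  attr(out, "averaged") <- TRUE
  out
}

#' Derive cellular components by intensity-matched subtraction
#'
#' Implements the pharmacological subtraction logic on sweep-averaged
#' traces, per retina and per flash intensity:
#' \itemize{
#'   \item MGC = Locke's − (Locke's + BaCl2): BaCl2 removes the slow
#'     negative Mueller glial potential, so the difference is that negative
#'     wave directly.
#'   \item ON-bipolar = (Locke's + BaCl2) − (Locke's + BaCl2 + L-AP4 + AA):
#'     L-AP4 removes the positive b-wave, so this difference is the
#'     positive-going ON-bipolar component. (The small OFF-bipolar residual
#'     included in this subtraction is accepted, not modelled.)
#'   \item Photoreceptor = the fully drugged condition as recorded.
#' }
#' Intensities are matched exactly after canonical rounding
#' ([canonical_intensity()]); there is no nearest-neighbour matching.
#'
#' @param family A sweep-averaged [flash_family()] (run [average_sweeps()]
#'   first). All three perfusion conditions must be present per retina with
#'   a common intensity set.
#' @return A `component_set` tibble: one row per (retina, component,
#'   intensity) with the derived trace in the `samples` list-column, plus
#'   metadata columns, carrying `sample_rate`/`t0_flash` attributes and a
#'   `provenance` attribute naming the condition arithmetic.
#' @export
derive_components <- function(family) {
  stopifnot(inherits(family, "flash_family"))
  tb <- tibble::as_tibble(family)
  multi <- tb %>%
    dplyr::count(.data$retina_id, .data$condition, .data$intensity) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    rlang::abort(
      "Multiple sweeps per (condition, intensity); run average_sweeps() first.",
      class = "erg_structure_error")
  }
  out <- tb %>%
    dplyr::group_by(.data$retina_id) %>%
    dplyr::group_modify(function(df, key) derive_components_one(df)) %>%
    dplyr::ungroup()
  meta <- tb %>%
    dplyr::distinct(.data$retina_id, .data$genotype, .data$age_class,
                    .data$age_days)
  out <- dplyr::left_join(out, meta, by = "retina_id") %>%
    dplyr::select("retina_id", "genotype", "age_class", "age_days",
                  "component", "intensity", "samples")
  structure(out,
            sample_rate = sample_rate(family),
            t0_flash = t0_flash(family),
            provenance = c(
              PHOTORECEPTOR = "BACL2_LAP4_AA",
              ON_BIPOLAR = "BACL2 - BACL2_LAP4_AA",
              MGC = "LOCKES - BACL2"),
            class = c("component_set", class(tibble::tibble())))
}

derive_components_one <- function(df) {
  missing_cond <- setdiff(erg_conditions(), unique(df$condition))
  if (length(missing_cond) > 0) {
    rlang::abort(paste0("Missing perfusion condition(s): ",
                        paste(missing_cond, collapse = ", ")),
                 class = "erg_missing_condition")
  }
  ints <- split(df$intensity, df$condition)
  common <- Reduce(intersect, ints)
  unmatched <- setdiff(unique(df$intensity), common)
  if (length(unmatched) > 0) {
    rlang::abort(paste0(
      "Intensities not present in all three conditions: ",
      paste(sort(unmatched), collapse = ", ")),
      class = "erg_intensity_mismatch")
  }
  get <- function(cond, i) {
    df$samples[[which(df$condition == cond & df$intensity == i)]]
  }
  purrr::map_dfr(sort(common), function(i) {
    tibble::tibble(
      component = erg_components(),
      intensity = i,
      samples = list(
        get("BACL2_LAP4_AA", i),
        get("BACL2", i) - get("BACL2_LAP4_AA", i),
        get("LOCKES", i) - get("BACL2", i)))
  })
}

#' Default amplitude-measurement windows
#'
#' Search and baseline windows in seconds relative to flash onset. The
#' photoreceptor "nose" is the global minimum over the early window; the
#' recovery plateau is the mean over a late fixed window; the ON-bipolar
#' peak and MGC trough searches reflect the components' kinetic ordering.
#' Windows extending past the end of a trace are clipped.
#'
#' @return Named list of two-element numeric windows plus the baseline
#'   window length.
#' @export
measurement_windows <- function() {
  list(baseline = 0.1,
       nose = c(0, 0.3),
       recovery = c(0.4, 0.6),
       on_bipolar = c(0, 1),
       mgc = c(0, 2))
}

#' Measure one baseline-referenced component amplitude
#'
#' Amplitude is `|extremum − baseline|`, with the extremum the minimum
#' (photoreceptor, MGC) or maximum (ON-bipolar) of the trace within the
#' component's search window, and the baseline the pre-stimulus mean
#' ([baseline()]). For the photoreceptor, `phase = "NOSE"` measures the
#' early trough and `phase = "RECOVERY"` the mean of the late plateau
#' window.
#'
#' @param samples Numeric voltage trace (microvolts).
#' @param component One of [erg_components()].
#' @param sample_rate Hz.
#' @param t0_flash Flash onset, seconds from the first sample.
#' @param windows Window set as from [measurement_windows()].
#' @param phase `"NOSE"` or `"RECOVERY"` for the photoreceptor; ignored
#'   otherwise.
#' @return One-row tibble: `component`, `amplitude` (>= 0, microvolts),
#'   `polarity`, `phase`.
#' @export
measure_amplitude <- function(samples, component, sample_rate, t0_flash,
                              windows = measurement_windows(),
                              phase = c("NOSE", "RECOVERY")) {
  component <- match.arg(component, erg_components())
  phase <- if (component == "PHOTORECEPTOR") match.arg(phase) else NA_character_
  b <- baseline(samples, sample_rate, t0_flash, windows$baseline)
  t <- (seq_along(samples) - 1) / sample_rate - t0_flash
  win <- switch(component,
    PHOTORECEPTOR = if (identical(phase, "RECOVERY")) windows$recovery
                    else windows$nose,
    ON_BIPOLAR = windows$on_bipolar,
    MGC = windows$mgc)
  idx <- which(t >= win[1] & t <= min(win[2], max(t)))
  if (length(idx) == 0) {
    rlang::abort("Search window contains no samples.",
                 class = "erg_window_error")
  }
  seg <- samples[idx]
  value <- if (identical(phase, "RECOVERY")) {
    mean(seg)
  } else if (component == "ON_BIPOLAR") {
    max(seg)
  } else {
    min(seg)
  }
  tibble::tibble(component = component,
                 amplitude = abs(value - b),
                 polarity = component_polarity(component),
                 phase = phase)
}

#' Measure all component amplitudes of a component set
#'
#' Applies [measure_amplitude()] to every derived trace. Photoreceptor
#' traces yield two records (NOSE and RECOVERY); the NOSE trough is the
#' default photoreceptor amplitude used downstream, with the recovery
#' plateau additionally recorded.
#'
#' @param components A `component_set` from [derive_components()].
#' @param windows Window set as from [measurement_windows()].
#' @return Tidy tibble: `retina_id`, `genotype`, `age_class`, `age_days`,
#'   `component`, `intensity`, `amplitude`, `polarity`, `phase`.
#' @export
measure_components <- function(components, windows = measurement_windows()) {
  stopifnot(inherits(components, "component_set"))
  sr <- sample_rate(components)
  t0 <- t0_flash(components)
  tb <- tibble::as_tibble(components)
  purrr::pmap_dfr(
    list(tb$retina_id, tb$genotype, tb$age_class, tb$age_days,
         tb$component, tb$intensity, tb$samples),
    function(rid, gt, ac, ad, comp, i, s) {
      phases <- if (comp == "PHOTORECEPTOR") c("NOSE", "RECOVERY") else "NOSE"
      purrr::map_dfr(phases, function(ph) {
        rec <- measure_amplitude(s, comp, sr, t0, windows, phase = ph)
        tibble::tibble(retina_id = rid, genotype = gt, age_class = ac,
                       age_days = ad, component = comp, intensity = i,
                       amplitude = rec$amplitude, polarity = rec$polarity,
                       phase = rec$phase)
      })
    })
}

#' Default amplitude table for intensity-response fitting
#'
#' Keeps the photoreceptor NOSE measure (baseline-to-trough) and drops the
#' RECOVERY records, giving one amplitude per (retina, component,
#' intensity) as consumed by [fit_hill_all()].
#'
#' @param amplitudes Output of [measure_components()].
#' @return Filtered tibble.
#' @export
primary_amplitudes <- function(amplitudes) {
  dplyr::filter(amplitudes,
                .data$component != "PHOTORECEPTOR" | .data$phase == "NOSE")
}
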