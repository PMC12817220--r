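#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr %>%
NULL

#' Perfusion conditions of the dissection protocol
#'
#' The three sequential perfusion solutions used to dissect the ex vivo ERG:
#' normal Locke's; Locke's + BaCl2 (blocks the inwardly rectifying potassium
#' currents of the Mueller glia, removing the slow negative MGC component);
#' and Locke's + BaCl2 + L-AP4 + aspartic acid (L-AP4 silences the
#' photoreceptor to ON-bipolar synapse, AA suppresses OFF-bipolar responses,
#' leaving the photoreceptor response).
#'
#' @return Character vector of the three condition codes, in the order the
#'   solutions are applied.
#' @export
#' @examples
#' erg_conditions()
erg_conditions <- function() {
  c("LOCKES", "BACL2", "BACL2_LAP4_AA")
}

#' Cellular components of the ex vivo ERG
#'
#' @return Character vector of the three component codes: the fast negative
#'   photoreceptor a-wave (with its "nose" trough and recovery plateau), the
#'   positive ON-bipolar b-wave, and the slow negative Mueller glial cell
#'   (MGC) potential.
#' @export
#' @examples
#' erg_components()
erg_components <- function() {
  c("PHOTORECEPTOR", "ON_BIPOLAR", "MGC")
}

#' Recognised genotype and age-class labels
#'
#' @return Character vector of labels.
#' @export
erg_genotypes <- function() c("WT", "KO", "R141C", "C59S")

#' @rdname erg_genotypes
#' @export
erg_age_classes <- function() c("PRE_EYE_OPENING", "EYE_OPENING", "ADULT")

# signed extremum polarity per component: trough for photoreceptor and MGC,
# peak for ON-bipolar
component_polarity <- function(component) {
  unname(c(PHOTORECEPTOR = -1, ON_BIPOLAR = 1, MGC = -1)[component])
}

#' Canonical intensity rounding used for intensity matching
#'
#' Flash intensities are matched across perfusion conditions by exact
#' equality after rounding to 4 significant figures, so that values written
#' and re-read through text interchange still match.
#'
#' @param intensity Numeric vector of flash intensities (photons/um^2).
#' @return Rounded numeric vector.
#' @export
canonical_intensity <- function(intensity) signif(intensity, 4)

#' Assemble a validated flash family
#'
#' A flash family holds every sweep recorded from one or more retinas: one
#' row per sweep, with the voltage trace (microvolts) stored as a
#' list-column, and acquisition timing shared across rows as attributes.
#' All downstream stages (sweep averaging, component subtraction,
#' amplitude measurement) consume this container.
#'
#' @param sweeps A data frame with columns `retina_id`, `genotype`,
#'   `age_class`, `age_days`, `condition` (one of [erg_conditions()]),
#'   `intensity` (photons/um^2, >= 0), `sweep` (integer index), and
#'   `samples` (list-column of numeric voltage vectors, microvolts).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param t0_flash Time of flash onset in seconds relative to the first
#'   sample. Must leave at least `min_baseline` of pre-stimulus recording.
#' @param flash_duration Flash duration in seconds.
#' @param intensity_range Permitted intensity range (photons/um^2).
#' @param min_baseline Minimum pre-stimulus segment required before the
#'   flash, in seconds.
#' @return A `flash_family` tibble (one row per sweep) carrying
#'   `sample_rate`, `t0_flash` and `flash_duration` attributes.
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   retina_id = "r1", genotype = "WT", age_class = "ADULT", age_days = 60L,
#'   condition = "LOCKES", intensity = 100, sweep = 1L,
#'   samples = list(rep(0, 2000))
#' )
#' fam <- flash_family(tr, sample_rate = 2000, t0_flash = 0.2,
#'                     flash_duration = 0.002)
#' nrow(fam)
flash_family <- function(sweeps, sample_rate, t0_flash,
                         flash_duration = 0.002,
                         intensity_range = c(5, 50000),
                         min_baseline = 0.1) {
  if (!is.data.frame(sweeps) || nrow(sweeps) == 0) {
    abort("`sweeps` must be a non-empty data frame.", class = "erg_empty_input")
  }
  required <- c("retina_id", "genotype", "age_class", "age_days",
                "condition", "intensity", "sweep", "samples")
  missing_cols <- setdiff(required, names(sweeps))
  if (length(missing_cols) > 0) {
    abort(paste0("`sweeps` is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "erg_structure_error")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number (Hz).",
          class = "erg_structure_error")
  }
  if (t0_flash < min_baseline) {
    abort(sprintf(
      "`t0_flash` (%.4g s) must leave at least %.4g s of pre-stimulus baseline.",
      t0_flash, min_baseline), class = "erg_structure_error")
  }
  lens <- lengths(sweeps$samples)
  if (any(lens == 0)) {
    abort("All traces must be non-empty.", class = "erg_structure_error")
  }
  if (length(unique(lens)) != 1) {
    abort("All traces in a flash family must have the same length.",
          class = "erg_structure_error")
  }
  bad_cond <- setdiff(unique(sweeps$condition), erg_conditions())
  if (length(bad_cond) > 0) {
    abort(paste0("Unknown perfusion condition(s): ",
                 paste(bad_cond, collapse = ", ")),
          class = "erg_structure_error")
  }
  if (any(sweeps$intensity < 0)) {
    abort("Flash intensities must be >= 0.", class = "erg_structure_error")
  }
  out_of_range <- sweeps$intensity < intensity_range[1] |
    sweeps$intensity > intensity_range[2]
  if (any(out_of_range)) {
    abort(sprintf(
      "Intensities outside the configured range [%g, %g]: %s",
      intensity_range[1], intensity_range[2],
      paste(unique(sweeps$intensity[out_of_range]), collapse = ", ")),
      class = "erg_structure_error")
  }
  out <- tibble::as_tibble(sweeps)
  out$intensity <- canonical_intensity(out$intensity)
  out <- dplyr::arrange(out, .data$retina_id, .data$condition,
                        .data$intensity, .data$sweep)
  new_flash_family(out, sample_rate = sample_rate, t0_flash = t0_flash,
                   flash_duration = flash_duration)
}

new_flash_family <- function(x, sample_rate, t0_flash, flash_duration) {
  structure(x,
            sample_rate = sample_rate,
            t0_flash = t0_flash,
            flash_duration = flash_duration,
            class = c("flash_family", class(tibble::tibble())))
}

#' Acquisition metadata of a flash family or component set
#'
#' @param x A `flash_family` or `component_set`.
#' @return `sample_rate()`: Hz; `t0_flash()`: seconds; `family_time()`:
#'   numeric vector of sample times in seconds relative to flash onset
#'   (t = 0 at the flash).
#' @export
sample_rate <- function(x) attr(x, "sample_rate")

#' @rdname sample_rate
#' @export
t0_flash <- function(x) attr(x, "t0_flash")

#' @rdname sample_rate
#' @export
family_time <- function(x) {
  n <- length(x$samples[[1]])
  (seq_len(n) - 1) / sample_rate(x) - t0_flash(x)
}

#' @export
print.flash_family <- function(x, ...) {
  cat(sprintf(
    "<flash_family> %d sweep(s), %d retina(s), %d condition(s), %d intensities\n",
    nrow(x), dplyr::n_distinct(x$retina_id), dplyr::n_distinct(x$condition),
    dplyr::n_distinct(x$intensity)))
  cat(sprintf("  sample_rate %g Hz, flash at t0 = %g s, %d samples/trace\n",
              sample_rate(x), t0_flash(x), length(x$samples[[1]])))
  NextMethod()
}

# keep attributes through dplyr verbs that return data frames
#' @export
`[.flash_family` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "samples" %in% names(out)) {
    return(new_flash_family(out, sample_rate(x), t0_flash(x),
                            attr(x, "flash_duration")))
  }
  out
}

#' Mean pre-stimulus baseline voltage of a trace
#'
#' Averages the voltage over the window immediately preceding flash onset,
#' i.e. over `[t0_flash - window, t0_flash)`. Component amplitudes are
#' referenced to this value, which makes the measurement invariant to
#' constant voltage offsets.
#'
#' @param samples Numeric voltage trace (microvolts).
#' @param sample_rate Sampling rate in Hz.
#' @param t0_flash Flash onset in seconds relative to the first sample.
#' @param window Baseline window length in seconds (default 0.1 s).
#' @return Mean voltage (microvolts) over the window.
#' @export
#' @examples
#' baseline(rep(-12, 1000), sample_rate = 1000, t0_flash = 0.5)
baseline <- function(samples, sample_rate, t0_flash, window = 0.1) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  if (window <= 0) abort("`window` must be positive.")
  if (t0_flash - window < 0) {
    abort(sprintf(
      "Baseline window (%.4g s) does not fit before flash onset at %.4g s.",
      window, t0_flash), class = "erg_window_error")
  }
  t <- (seq_along(samples) - 1) / sample_rate
  idx <- which(t >= t0_flash - window & t < t0_flash)
  if (length(idx) == 0) {
    abort("Baseline window contains no samples.", class = "erg_window_error")
  }
  mean(samples[idx])
}
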