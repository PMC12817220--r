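#' Plot the derived component waveforms of one retina
#'
#' Time courses of the isolated photoreceptor, ON-bipolar and MGC traces,
#' one panel per component, colour-graded by flash intensity, with the
#' flash at t = 0 marked.
#'
#' @param components A `component_set` from [derive_components()].
#' @param retina Retina to plot (default: the first).
#' @return A ggplot object.
#' @export
plot_components <- function(components, retina = NULL) {
  stopifnot(inherits(components, "component_set"))
  tb <- tibble::as_tibble(components)
  retina <- retina %||% tb$retina_id[1]
  tb <- dplyr::filter(tb, .data$retina_id == retina)
  t <- family_time(components)
  long <- tb %>%
    dplyr::mutate(component = factor(.data$component,
                                     levels = erg_components())) %>%
    dplyr::mutate(data = purrr::map(.data$samples, function(s) {
      tibble::tibble(time = t, voltage = s)
    })) %>%
    dplyr::select(-"samples") %>%
    tidyr::unnest("data")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$voltage,
                                     group = .data$intensity,
                                     colour = log10(.data$intensity))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "Time from flash (s)", y = "Voltage (µV)",
                  colour = expression(log[10]~I),
                  title = paste("Isolated ERG components:", retina)) +
    ggplot2::theme_minimal()
}

#' Intensity-response curves with per-intensity significance stars
#'
#' Per-genotype mean amplitude (with SEM bars) against flash intensity on a
#' log axis, one panel per component, overlaid with the pooled Hill curve
#' per genotype and the stars from [compare_per_intensity()].
#'
#' @param amplitudes Tidy amplitude tibble (one row per retina, component,
#'   intensity; see [primary_amplitudes()]).
#' @param stats Optional result of [compare_per_intensity()] for star
#'   annotation.
#' @return A ggplot object.
#' @export
plot_intensity_response <- function(amplitudes, stats = NULL) {
  summ <- amplitudes %>%
    dplyr::group_by(.data$genotype, .data$component, .data$intensity) %>%
    dplyr::summarise(mean_amp = mean(.data$amplitude),
                     sem = stats::sd(.data$amplitude) /
                       sqrt(dplyr::n()), .groups = "drop")
  curves <- amplitudes %>%
    dplyr::group_by(.data$genotype, .data$component) %>%
    dplyr::group_modify(function(df, key) {
      ft <- tryCatch(fit_pooled(df), error = function(e) NULL)
      if (is.null(ft) || ft$degenerate) return(tibble::tibble())
      ii <- 10^seq(log10(min(df$intensity)), log10(max(df$intensity)),
                   length.out = 80)
      tibble::tibble(intensity = ii, amplitude = predict(ft, ii))
    }) %>%
    dplyr::ungroup()
  p <- ggplot2::ggplot(summ, ggplot2::aes(.data$intensity, .data$mean_amp,
                                          colour = .data$genotype)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_amp - .data$sem,
                                          ymax = .data$mean_amp + .data$sem),
                             size = 0.25) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(.data$intensity, .data$amplitude,
                                    colour = .data$genotype),
                       linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = expression(Flash~intensity~(photons/mu*m^2)),
                  y = "Amplitude (µV)") +
    ggplot2::theme_minimal()
  if (!is.null(stats) && nrow(stats) > 0) {
    star_df <- dplyr::filter(stats, .data$star != "ns")
    if (nrow(star_df) > 0) {
      tops <- summ %>%
        dplyr::group_by(.data$component) %>%
        dplyr::summarise(ymax = max(.data$mean_amp + .data$sem,
                                    na.rm = TRUE), .groups = "drop")
      star_df <- dplyr::left_join(star_df, tops, by = "component")
      p <- p + ggplot2::geom_text(
        data = star_df,
        ggplot2::aes(.data$intensity, 1.05 * .data$ymax,
                     label = .data$star, colour = .data$genotype),
        show.legend = FALSE, size = 3)
    }
  }
  p
}

#' Plot a single Hill fit over its data
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  ii <- 10^seq(log10(min(d$intensity)), log10(max(d$intensity)),
               length.out = 100)
  curve <- tibble::tibble(intensity = ii, amplitude = predict(object, ii))
  ggplot2::ggplot(d, ggplot2::aes(.data$intensity, .data$amplitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(Flash~intensity~(photons/mu*m^2)),
                  y = "Amplitude (µV)",
                  subtitle = sprintf(
                    "r_max = %.1f µV, log10 K = %.2f, n = %.2f",
                    object$r_max, object$log10_k, object$n)) +
    ggplot2::theme_minimal()
}

#' Proportionality scatter with the identity diagonal
#'
#' Wildtype-normalised r_max of one component against another, per retina;
#' the diagonal marks a proportional change of both components relative to
#' wildtype.
#'
#' @param records Output of [proportionality()].
#' @return A ggplot object.
#' @export
plot_proportionality <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(.data$x, .data$y,
                                        colour = .data$genotype)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = paste0("Normalised r_max (", records$x_component[1], ")"),
      y = paste0("Normalised r_max (", records$y_component[1], ")")) +
    ggplot2::theme_minimal()
}

#' Developmental trajectory of r_max
#'
#' Mean r_max (with SEM bars) per genotype over the three age classes, one
#' panel per component.
#'
#' @param traj Output of [trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  ggplot2::ggplot(traj, ggplot2::aes(.data$age_class, .data$mean_r_max,
                                     colour = .data$genotype,
                                     group = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_r_max - .data$sem_r_max,
      ymax = .data$mean_r_max + .data$sem_r_max)) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(R[max]~(mu*V))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
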