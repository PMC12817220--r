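#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Significance stars from a p-value
#'
#' The star convention used throughout the figures: `*` for
#' 0.01 < p < 0.05, `**` for 0.001 < p < 0.01, `***` for p < 0.001, `ns`
#' otherwise. The published bins are open intervals, so a p-value landing
#' exactly on a boundary (0.05, 0.01, 0.001) is assigned to the
#' less-significant bin.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of `ns`, `*`, `**`, `***`.
#' @export
#' @examples
#' p_star(c(0.2, 0.04, 0.004, 1e-4, 0.001))
p_star <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns")
}

#' Welch unequal-variance two-sample t-test
#'
#' Thin tidy wrapper around the unequal-variance t-test
#' (`stats::t.test(var.equal = FALSE)`): Welch statistic,
#' Welch-Satterthwaite degrees of freedom, two-sided p-value, and the
#' figure star. If both samples have zero variance and equal means the
#' result is `t = 0, p = 1` by convention.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param labels Length-2 character vector naming the groups.
#' @return One-row tibble: `group1`, `group2`, `n1`, `n2`, `mean1`,
#'   `mean2`, `var1`, `var2`, `statistic`, `df`, `p_value`, `star`.
#' @export
#' @examples
#' welch_test(c(1, 2, 3), c(4, 5, 6))
welch_test <- function(x, y, labels = c("x", "y")) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("Each sample needs n >= 2.", class = "erg_stats_error")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(
        group1 = labels[1], group2 = labels[2],
        n1 = length(x), n2 = length(y),
        mean1 = mean(x), mean2 = mean(y), var1 = vx, var2 = vy,
        statistic = 0, df = length(x) + length(y) - 2,
        p_value = 1, star = "ns"))
    }
    rlang::abort("Both samples are constant with different means.",
                 class = "erg_stats_error")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  p <- tt$p.value
  tibble::tibble(
    group1 = labels[1], group2 = labels[2],
    n1 = length(x), n2 = length(y),
    mean1 = mean(x), mean2 = mean(y), var1 = vx, var2 = vy,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = p, star = p_star(p))
}

#' Per-intensity genotype comparisons against wildtype
#'
#' For every (mutant genotype, component, flash intensity) shared with the
#' reference genotype, runs [welch_test()] on the per-retina amplitudes —
#' the per-intensity significance stars drawn on intensity-response plots.
#' No multiplicity correction is applied by default, matching the raw
#' per-intensity star convention; Holm correction is available.
#'
#' @param amplitudes Tidy amplitude tibble with one row per
#'   (retina, component, intensity) (see [primary_amplitudes()]).
#' @param reference Reference genotype (default `"WT"`).
#' @param correct `"none"` (default) or `"holm"` (applied within each
#'   genotype x component series).
#' @return Tibble: `genotype`, `component`, `intensity` plus the
#'   [welch_test()] columns. Comparisons with fewer than 2 retinas in a
#'   group are skipped with a warning.
#' @export
compare_per_intensity <- function(amplitudes, reference = "WT",
                                  correct = c("none", "holm")) {
  correct <- match.arg(correct)
  stopifnot(is.data.frame(amplitudes))
  muts <- setdiff(unique(amplitudes$genotype), reference)
  grid <- amplitudes %>%
    dplyr::filter(.data$genotype != reference) %>%
    dplyr::distinct(.data$genotype, .data$component, .data$intensity)
  out <- purrr::pmap_dfr(grid, function(genotype, component, intensity) {
    xa <- amplitudes$amplitude[amplitudes$genotype == reference &
                                 amplitudes$component == component &
                                 amplitudes$intensity == intensity]
    ya <- amplitudes$amplitude[amplitudes$genotype == genotype &
                                 amplitudes$component == component &
                                 amplitudes$intensity == intensity]
    if (length(xa) < 2 || length(ya) < 2) {
      rlang::warn(sprintf(
        "Skipping %s %s at %g photons/um^2: fewer than 2 retinas.",
        genotype, component, intensity))
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(genotype = genotype, component = component,
                     intensity = intensity),
      welch_test(xa, ya, labels = c(reference, genotype)))
  })
  if (correct == "holm" && nrow(out) > 0) {
    out <- out %>%
      dplyr::group_by(.data$genotype, .data$component) %>%
      dplyr::mutate(p_value = stats::p.adjust(.data$p_value, "holm"),
                    star = p_star(.data$p_value)) %>%
      dplyr::ungroup()
  }
  out
}

#' Genotype comparisons of fitted Hill parameters
#'
#' Welch tests of per-retina fitted `r_max` and `log10_k` (sensitivity)
#' between each mutant genotype and the reference, per component.
#' Non-converged or degenerate fits are dropped first; for `log10_k`,
#' fits flagged K-non-identifiable are also dropped.
#'
#' @param fits Fit table from [fit_hill_all()].
#' @param reference Reference genotype (default `"WT"`).
#' @param parameters Which parameters to compare.
#' @return Tibble: `genotype`, `component`, `parameter` plus the
#'   [welch_test()] columns. Empty input gives an empty tibble.
#' @export
compare_parameters <- function(fits, reference = "WT",
                               parameters = c("r_max", "log10_k")) {
  stopifnot(is.data.frame(fits))
  if (nrow(fits) == 0) return(tibble::tibble())
  usable <- dplyr::filter(fits, .data$converged, !.data$degenerate)
  grid <- tidyr::expand_grid(
    genotype = setdiff(unique(usable$genotype), reference),
    component = unique(usable$component),
    parameter = parameters)
  purrr::pmap_dfr(grid, function(genotype, component, parameter) {
    sub <- usable[usable$component == component, ]
    if (parameter == "log10_k") sub <- sub[sub$k_identifiable, ]
    xa <- sub[[parameter]][sub$genotype == reference]
    ya <- sub[[parameter]][sub$genotype == genotype]
    if (length(xa) < 2 || length(ya) < 2) {
      rlang::warn(sprintf("Skipping %s %s %s: fewer than 2 usable fits.",
                          genotype, component, parameter))
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(genotype = genotype, component = component,
                     parameter = parameter),
      welch_test(xa, ya, labels = c(reference, genotype)))
  })
}

#' Wildtype-normalised r_max proportionality records
#'
#' Normalises each retina's fitted `r_max` for a pair of components by the
#' corresponding wildtype mean `r_max`, giving one (x, y) point per retina:
#' x the photoreceptor-normalised (first component) value, y the other
#' component's. Points on the identity diagonal indicate a proportional
#' change of both components relative to wildtype; points below it, a
#' disproportionate reduction of the second component.
#'
#' @param fits Fit table from [fit_hill_all()].
#' @param pair Length-2 character vector of components `(x, y)`; default
#'   photoreceptor vs ON-bipolar.
#' @param reference Reference genotype whose mean r_max per component is
#'   the normalisation denominator.
#' @return Tibble: `genotype`, `retina_id`, `x_component`, `y_component`,
#'   `x`, `y`, `deviation` (signed perpendicular distance from the identity
#'   line, `(y - x) / sqrt(2)`).
#' @export
proportionality <- function(fits,
                            pair = c("PHOTORECEPTOR", "ON_BIPOLAR"),
                            reference = "WT") {
  stopifnot(is.data.frame(fits), length(pair) == 2)
  usable <- dplyr::filter(fits, .data$converged, !.data$degenerate,
                          .data$component %in% pair)
  denom <- usable %>%
    dplyr::filter(.data$genotype == reference) %>%
    dplyr::group_by(.data$component) %>%
    dplyr::summarise(wt_mean = mean(.data$r_max), .groups = "drop")
  if (nrow(denom) < 2 || any(denom$wt_mean <= 0)) {
    rlang::abort("Wildtype baseline r_max missing or non-positive for the pair.",
                 class = "erg_stats_error")
  }
  wide <- usable %>%
    dplyr::left_join(denom, by = "component") %>%
    dplyr::mutate(norm = .data$r_max / .data$wt_mean) %>%
    dplyr::select("retina_id", "genotype", "component", "norm") %>%
    tidyr::pivot_wider(names_from = "component", values_from = "norm")
  if (!all(pair %in% names(wide))) {
    rlang::abort("Both components of the pair must be fitted per retina.",
                 class = "erg_stats_error")
  }
  tibble::tibble(
    genotype = wide$genotype, retina_id = wide$retina_id,
    x_component = pair[1], y_component = pair[2],
    x = wide[[pair[1]]], y = wide[[pair[2]]],
    deviation = (wide[[pair[2]]] - wide[[pair[1]]]) / sqrt(2)) %>%
    dplyr::filter(!is.na(.data$x), !is.na(.data$y))
}

#' Per-genotype summary of proportionality deviation
#'
#' Mean signed perpendicular deviation from the identity diagonal per
#' genotype, with a seeded bootstrap percentile interval. A deviation of 0
#' means the two components changed proportionally relative to wildtype.
#'
#' @param records Output of [proportionality()].
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Interval coverage (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return Tibble: `genotype`, `n`, `mean_deviation`, `ci_lower`,
#'   `ci_upper`.
#' @export
proportionality_deviation <- function(records, n_boot = 2000, conf = 0.95,
                                      seed = 1L) {
  stopifnot(is.data.frame(records))
  set.seed(seed)
  alpha <- (1 - conf) / 2
  records %>%
    dplyr::group_by(.data$genotype) %>%
    dplyr::group_modify(function(df, key) {
      dev <- df$deviation
      ci <- if (length(dev) >= 2) {
        boot <- replicate(n_boot, mean(sample(dev, replace = TRUE)))
        stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
      } else c(NA_real_, NA_real_)
      tibble::tibble(n = length(dev), mean_deviation = mean(dev),
                     ci_lower = ci[1], ci_upper = ci[2])
    }) %>%
    dplyr::ungroup()
}

#' Developmental trajectory of maximal responses
#'
#' Mean and SEM of per-retina fitted `r_max` for each genotype x age class
#' x component cell, with the number of retinas. SEM is reported only for
#' cells with at least two retinas.
#'
#' @param fits Fit table from [fit_hill_all()] (rows labelled with
#'   `age_class`).
#' @return Tibble: `genotype`, `age_class`, `component`, `mean_r_max`,
#'   `sem_r_max`, `n`.
#' @export
trajectory <- function(fits) {
  stopifnot(is.data.frame(fits))
  if (nrow(fits) == 0) return(tibble::tibble())
  fits %>%
    dplyr::filter(.data$converged, !.data$degenerate) %>%
    dplyr::group_by(.data$genotype, .data$age_class, .data$component) %>%
    dplyr::summarise(
      mean_r_max = mean(.data$r_max),
      sem_r_max = if (dplyr::n() >= 2) {
        stats::sd(.data$r_max) / sqrt(dplyr::n())
      } else NA_real_,
      n = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(age_class = factor(.data$age_class,
                                     levels = erg_age_classes())) %>%
    dplyr::arrange(.data$component, .data$genotype, .data$age_class)
}
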