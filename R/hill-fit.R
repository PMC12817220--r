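#' Fit the Hill intensity-response function to one retina's amplitudes
#'
#' Least-squares fit of `R(I) = r_max * I^n / (I^n + k^n)` to
#' (intensity, amplitude) pairs, by Levenberg-Marquardt with box bounds.
#' `k` is the half-maximal intensity (the fitted curve at `I = k` equals
#' `r_max / 2` by construction) and is reported alongside `log10_k`, the
#' scale on which group statistics compare sensitivity. Initialisation is
#' parameter-free: `r_max` starts at the maximum amplitude, `k` at the
#' intensity interpolated at half that maximum, `n` at 1. Bounds
#' (`r_max` in (0, 10 x max amplitude], `k` in [min I / 10, max I x 10],
#' `n` in (0, 10]) keep the optimiser finite on flat data.
#'
#' A fit is flagged `k_identifiable = FALSE` when the data carry no
#' information below saturation (relative amplitude spread under 1%) or the
#' fitted `k` lands on a bound. All-zero amplitudes yield a flagged null
#' fit (all estimates `NA`, `converged = FALSE`) rather than arbitrary
#' parameters.
#'
#' @param data Data frame with columns `intensity` (> 0) and `amplitude`
#'   (>= 0); at least 4 distinct intensities.
#' @param fix_n Optional value at which to fix the slope `n` instead of
#'   fitting it.
#' @param init Optional named list overriding the automatic starting
#'   values (`r_max`, `k`, `n`).
#' @param bounds Optional list with `lower`/`upper` named numeric vectors
#'   overriding the defaults.
#' @return A `hill_fit` object; see [tidy.hill_fit()] and
#'   [glance.hill_fit()].
#' @export
#' @examples
#' I <- 10^seq(log10(5), log10(50000), length.out = 9)
#' d <- data.frame(intensity = I,
#'                 amplitude = hill_amplitude(I, 300, 200, 1))
#' glance(fit_hill(d))
fit_hill <- function(data, fix_n = NULL, init = NULL, bounds = NULL) {
  stopifnot(is.data.frame(data),
            all(c("intensity", "amplitude") %in% names(data)))
  d <- data %>%
    dplyr::filter(!is.na(.data$intensity), !is.na(.data$amplitude)) %>%
    dplyr::group_by(.data$intensity) %>%
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop") %>%
    dplyr::arrange(.data$intensity)
  # fitting uses per-intensity points as given; replicates at an intensity
  # in the input are retained via the original rows
  d_fit <- dplyr::arrange(
    dplyr::filter(data, !is.na(.data$intensity), !is.na(.data$amplitude)),
    .data$intensity)
  if (dplyr::n_distinct(d$intensity) < 4) {
    rlang::abort("Hill fitting needs at least 4 distinct intensities.",
                 class = "erg_fit_error")
  }
  if (any(d_fit$amplitude < 0)) {
    rlang::abort("Amplitudes must be >= 0.", class = "erg_fit_error")
  }
  max_amp <- max(d$amplitude)
  if (max_amp <= 0) {
    return(new_hill_fit(NA_real_, NA_real_, NA_real_, rss = 0,
                        converged = FALSE, k_identifiable = FALSE,
                        degenerate = TRUE, data = d_fit, vcov = NULL))
  }
  k0 <- interp_half_max(d$intensity, d$amplitude, max_amp)
  start <- list(r_max = max_amp, k = k0, n = 1)
  if (!is.null(init)) start <- utils::modifyList(start, init)
  lower <- c(r_max = 1e-8, k = min(d$intensity) / 10, n = 1e-3)
  upper <- c(r_max = 10 * max_amp, k = max(d$intensity) * 10, n = 10)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  start$k <- min(max(start$k, lower["k"]), upper["k"])

  if (!is.null(fix_n)) {
    form <- amplitude ~ r_max * intensity^n0 / (intensity^n0 + k^n0)
    d_fit$n0 <- fix_n
    start$n <- NULL
    lower <- lower[c("r_max", "k")]
    upper <- upper[c("r_max", "k")]
  } else {
    form <- amplitude ~ r_max * intensity^n / (intensity^n + k^n)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = d_fit, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_hill_fit(NA_real_, NA_real_, NA_real_, rss = NA_real_,
                        converged = FALSE, k_identifiable = FALSE,
                        degenerate = TRUE, data = d_fit, vcov = NULL))
  }
  est <- stats::coef(fit)
  n_hat <- if (is.null(fix_n)) unname(est["n"]) else fix_n
  rss <- sum(stats::residuals(fit)^2)
  converged <- isTRUE(fit$convInfo$isConv)
  spread <- (max_amp - min(d$amplitude)) / max_amp
  on_bound <- est["k"] <= lower["k"] * (1 + 1e-6) ||
    est["k"] >= upper["k"] * (1 - 1e-6)
  k_ident <- spread > 0.01 && !on_bound
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  new_hill_fit(unname(est["r_max"]), unname(est["k"]), n_hat,
               rss = rss, converged = converged, k_identifiable = k_ident,
               degenerate = FALSE, data = d_fit, vcov = vc, nls = fit)
}

interp_half_max <- function(intensity, amplitude, max_amp) {
  half <- max_amp / 2
  above <- which(amplitude >= half)
  if (length(above) == 0) return(max(intensity))
  j <- min(above)
  if (j == 1) return(intensity[1])
  # linear interpolation in log-intensity between the bracketing points
  x1 <- log10(intensity[j - 1]); x2 <- log10(intensity[j])
  y1 <- amplitude[j - 1]; y2 <- amplitude[j]
  if (y2 == y1) return(intensity[j])
  10^(x1 + (half - y1) * (x2 - x1) / (y2 - y1))
}

new_hill_fit <- function(r_max, k, n, rss, converged, k_identifiable,
                         degenerate, data, vcov, nls = NULL) {
  structure(list(r_max = r_max, k = k, log10_k = log10(k), n = n,
                 rss = rss, converged = converged,
                 k_identifiable = k_identifiable, degenerate = degenerate,
                 n_obs = nrow(data), data = data, vcov = vcov, nls = nls),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<hill_fit> degenerate (flagged null fit)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<hill_fit> r_max = %.4g uV, k = %.4g photons/um^2 (log10 k = %.3f), n = %.3f\n",
    x$r_max, x$k, x$log10_k, x$n))
  cat(sprintf("  rss = %.4g, n_obs = %d, converged: %s, k identifiable: %s\n",
              x$rss, x$n_obs, x$converged, x$k_identifiable))
  invisible(x)
}

#' Tidy a Hill fit into a one-row-per-term tibble
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  se <- rep(NA_real_, 3)
  if (!is.null(x$vcov)) {
    nm <- colnames(x$vcov)
    se_v <- sqrt(diag(x$vcov))
    se <- se_v[match(c("r_max", "k", "n"), nm)]
  }
  tibble::tibble(term = c("r_max", "k", "n"),
                 estimate = c(x$r_max, x$k, x$n),
                 std.error = unname(se))
}

#' One-row fit summary
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return One-row tibble: `r_max`, `k`, `log10_k`, `n`, `rss`, `sigma`,
#'   `n_obs`, `converged`, `k_identifiable`, `degenerate`.
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  p <- if (!is.null(x$nls)) length(stats::coef(x$nls)) else 3
  sigma <- if (!x$degenerate && x$n_obs > p) sqrt(x$rss / (x$n_obs - p))
           else NA_real_
  tibble::tibble(r_max = x$r_max, k = x$k, log10_k = x$log10_k, n = x$n,
                 rss = x$rss, sigma = sigma, n_obs = x$n_obs,
                 converged = x$converged,
                 k_identifiable = x$k_identifiable,
                 degenerate = x$degenerate)
}

#' Predict amplitudes from a Hill fit
#'
#' @param object A `hill_fit`.
#' @param intensity Intensities at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric amplitudes.
#' @export
predict.hill_fit <- function(object, intensity, ...) {
  if (object$degenerate) return(rep(NA_real_, length(intensity)))
  hill_amplitude(intensity, object$r_max, object$k, object$n)
}

#' Fit Hill functions per retina across a study
#'
#' Groups an amplitude table by retina, component (and carried metadata)
#' and fits each group with [fit_hill()]. Photoreceptor RECOVERY records
#' should be removed first ([primary_amplitudes()]).
#'
#' @param amplitudes Tidy amplitude tibble (from [measure_components()] or
#'   [simulate_amplitudes()]).
#' @param fix_n Optional fixed slope passed to [fit_hill()].
#' @return Tibble with one row per (retina, component): metadata plus the
#'   [glance.hill_fit()] columns.
#' @export
fit_hill_all <- function(amplitudes, fix_n = NULL) {
  stopifnot(is.data.frame(amplitudes))
  amplitudes %>%
    dplyr::group_by(.data$retina_id, .data$genotype, .data$age_class,
                    .data$component) %>%
    dplyr::group_modify(function(df, key) {
      glance(fit_hill(df, fix_n = fix_n))
    }) %>%
    dplyr::ungroup()
}

#' Pooled Hill fit for one genotype x age class x component
#'
#' Fits a single curve to the points of all retinas pooled together — the
#' summarising dashed curve drawn through a collated data set. Used for
#' display, not inference.
#'
#' @param amplitudes Amplitude tibble for one group (all rows are pooled).
#' @param ... Passed to [fit_hill()].
#' @return A `hill_fit`.
#' @export
fit_pooled <- function(amplitudes, ...) {
  if (!is.data.frame(amplitudes) || nrow(amplitudes) == 0) {
    rlang::abort("No amplitudes to pool.", class = "erg_fit_error")
  }
  fit_hill(amplitudes, ...)
}
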