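# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# closed-form Welch statistic, Satterthwaite df and two-sided p
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# hierarchical grid-search least-squares Hill fit: coarse 10% pass over wide
# ranges, then a 1%-resolution refinement around the coarse optimum. All
# grids are geometric, so "resolution" is a 1% multiplicative step per axis.
hill_grid_oracle <- function(intensity, amplitude) {
  rss_grid <- function(r_grid, k_grid, n_grid) {
    grid <- expand.grid(r_max = r_grid, k = k_grid, n = n_grid)
    pred <- outer(seq_len(nrow(grid)), seq_along(intensity),
                  function(gi, ii) {
                    ik <- (intensity[ii] / grid$k[gi])^grid$n[gi]
                    grid$r_max[gi] * ik / (ik + 1)
                  })
    grid$rss <- rowSums((pred - rep(amplitude, each = nrow(grid)))^2)
    grid
  }
  geo <- function(lo, hi, step) exp(seq(log(lo), log(hi), by = log(step)))
  max_amp <- max(amplitude)
  coarse <- rss_grid(geo(max_amp / 2, max_amp * 2, 1.1),
                     geo(min(intensity) / 10, max(intensity) * 10, 1.1),
                     geo(0.3, 3, 1.1))
  best <- coarse[which.min(coarse$rss), ]
  # staged zoom: each pass brackets the previous optimum by +/- 4 steps of
  # the previous resolution, ending on a 1% grid
  for (step in c(1.03, 1.01)) {
    prev <- if (step == 1.03) 1.1 else 1.03
    span <- prev^4
    fine <- rss_grid(geo(best$r_max / span, best$r_max * span, step),
                     geo(best$k / span, best$k * span, step),
                     geo(best$n / span, best$n * span, step))
    best <- fine[which.min(fine$rss), ]
  }
  list(r_max = best$r_max, k = best$k, n = best$n, rss = best$rss)
}

# gain of a linear filter at one frequency, measured from the FFT of its
# impulse response (no transfer-function algebra shared with the package)
impulse_gain_oracle <- function(filter_fun, freq_hz, sample_rate,
                                n = 2^14) {
  # unit impulse one sample in, so a leading-sample baseline convention in
  # the filter under test sees a zero baseline
  imp <- c(0, 1, rep(0, n - 2))
  h <- filter_fun(imp)
  H <- stats::fft(h)
  bin <- round(freq_hz / sample_rate * n) + 1
  abs(H[bin])
}
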