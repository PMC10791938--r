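# f-wave frequency analysis: activation detection, instantaneous frequency,
# peak-conditioned spectral selection, spatial trimmed averaging, mean
# frequency, respiration-band modulation magnitude and Spearman correlation
# against the ACh waveform.

#' Detect activations in a voltage trace
#'
#' One activation per beat, located at the local maximum of dV/dt exceeding
#' a threshold (a fraction of the trace's global maximum slope), with a
#' minimum refractory separation between accepted activations.
#'
#' @param v membrane potential samples (mV)
#' @param dt sampling interval (ms)
#' @param refractory_min minimum separation between activations (ms)
#' @param threshold_frac slope threshold as a fraction of the global maximum
#' @param min_slope absolute slope floor (mV/ms); traces whose maximum slope
#'   is below this are treated as quiescent
#' @return activation times (ms); empty if no activations
#' @export
detect_activations <- function(v, dt, refractory_min = 40,
                               threshold_frac = 0.1, min_slope = 1) {
  if (length(v) < 2) stopf("trace must have at least 2 samples")
  dv <- diff(v) / dt
  m <- max(dv)
  if (!is.finite(m) || m < min_slope) return(numeric(0))
  thr <- threshold_frac * m
  n <- length(dv)
  is_peak <- dv >= thr &
    dv >= c(-Inf, dv[-n]) & dv >= c(dv[-1], -Inf)
  cand <- which(is_peak)
  if (!length(cand)) return(numeric(0))
  keep_t <- numeric(0)
  keep_a <- numeric(0)
  gap <- refractory_min / dt
  for (i in cand) {
    if (length(keep_t) && i - keep_t[length(keep_t)] < gap) {
      # within the refractory window: keep the steeper of the two
      if (dv[i] > keep_a[length(keep_a)]) {
        keep_t[length(keep_t)] <- i
        keep_a[length(keep_a)] <- dv[i]
      }
    } else {
      keep_t <- c(keep_t, i)
      keep_a <- c(keep_a, dv[i])
    }
  }
  keep_t * dt
}

#' Instantaneous-frequency series
#'
#' Converts an activation train into frequency samples
#' \eqn{F(t_i) = 1/(t_i - t_{i-1})} and linearly interpolates them onto a
#' uniform grid (default 20 Hz) spanning the activation times.  The grid is
#' aligned to absolute time so series from different probes share sample
#' instants.
#'
#' @param times activation times (ms), strictly increasing, at least 2
#' @param out_rate output sampling rate (Hz)
#' @return list with `t` (ms) and `f` (Hz)
#' @export
instantaneous_frequency <- function(times, out_rate = 20) {
  if (length(times) < 2) stopf("need at least 2 activations")
  if (any(diff(times) <= 0)) stopf("activation times must be increasing")
  f <- 1000 / diff(times)
  tf <- times[-1]
  step <- 1000 / out_rate
  t0 <- ceiling(tf[1] / step) * step
  t1 <- floor(tf[length(tf)] / step) * step
  if (t1 < t0) stopf("activation span shorter than one output sample")
  tg <- seq(t0, t1, by = step)
  list(t = tg, f = stats::approx(tf, f, xout = tg, rule = 2)$y)
}

# Restrict a set of per-probe series to a common time span.  Probes whose
# series start late or end early relative to the ensemble (more than 5% of
# the median span) are dropped first, so a single straggler cannot truncate
# the analysis window for everyone.
common_grid <- function(series, slack = 0.05) {
  starts <- vapply(series, function(s) s$t[1], numeric(1))
  ends <- vapply(series, function(s) s$t[length(s$t)], numeric(1))
  S <- stats::median(starts); E <- stats::median(ends)
  tol <- slack * (E - S)
  keep <- starts <= S + tol & ends >= E - tol
  if (!any(keep)) keep <- rep(TRUE, length(series))
  series <- series[keep]
  t0 <- max(starts[keep])
  t1 <- min(ends[keep])
  if (t1 <= t0) stopf("probe series have no common time span")
  tg <- series[[1]]$t
  tg <- tg[tg >= t0 - 1e-9 & tg <= t1 + 1e-9]
  mat <- vapply(series, function(s) s$f[match(round(tg), round(s$t))],
                numeric(length(tg)))
  list(t = tg, f = matrix(mat, nrow = length(tg)), kept = keep)
}

# tile a series end-to-end until it is at least min_s seconds long
replicate_series <- function(x, fs, min_s) {
  k <- max(1, ceiling(min_s * fs / length(x)))
  rep(x, k)
}

# Order-4 Butterworth bandpass as cascaded biquad sections.  The direct
# transfer-function form of a 0.06 Hz band on a 20 Hz stream is numerically
# ill-conditioned (8 poles within 1e-2 of the unit circle); factoring into
# second-order sections keeps the zero-phase filter accurate to machine
# precision.
butter_bp_sections <- function(lo, hi, fs) {
  # analog order-4 Butterworth prototype (upper-half-plane poles), lowpass
  # to bandpass transform, bilinear map - poles computed directly, never by
  # factoring the ill-conditioned degree-8 polynomial
  wl <- 2 * fs * tan(pi * lo / fs)        # prewarped band edges (rad/s)
  wh <- 2 * fs * tan(pi * hi / fs)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  proto <- exp(1i * pi * c(5, 7) / 8)     # Im > 0 prototype poles
  p_dig <- complex(0)
  for (pp in proto) {
    disc <- sqrt((pp * bw)^2 - 4 * w0^2)
    s_poles <- c((pp * bw + disc) / 2, (pp * bw - disc) / 2)
    p_dig <- c(p_dig, (2 * fs + s_poles) / (2 * fs - s_poles))
  }
  secs <- lapply(p_dig, function(pk)
    list(b = c(1, 0, -1), a = c(1, -2 * Re(pk), Mod(pk)^2)))
  # normalize the cascade to unit gain at the geometric center frequency
  z <- exp(-1i * 2 * pi * sqrt(lo * hi) / fs * (0:2))
  g <- prod(vapply(secs, function(s)
    Mod(sum(s$b * z) / sum(s$a * z)), numeric(1)))
  list(sections = secs, gain = g)
}

# zero-phase bandpass via forward-backward filtering of each biquad section
bandpass_filtfilt <- function(x, lo, hi, fs) {
  f <- butter_bp_sections(lo, hi, fs)
  for (s in f$sections) x <- signal::filtfilt(s$b, s$a, x)
  x / f$gain^2
}

#' Peak-conditioned spectral selection
#'
#' Discards instantaneous-frequency series whose spectra are not
#' sufficiently peaked.  Each (demeaned, detrended, tiled) series gets a
#' periodogram; a series is accepted iff the fraction of spectral power
#' within `window_hz` of its largest peak reaches `threshold`.
#'
#' @param fmat matrix of per-probe series (time x probes) on a common grid
#' @param fs sampling rate (Hz)
#' @param window_hz half-width of the peak window (Hz)
#' @param threshold minimum concentration ratio for acceptance
#' @param min_s tile each series to at least this many seconds before the
#'   spectrum is computed (must cover one respiration period)
#' @return list with logical `accepted`, the concentration `ratio`, and the
#'   spectra (`freq`, `power` matrix)
#' @export
peak_conditioned_selection <- function(fmat, fs = 20, window_hz = 0.03,
                                       threshold = 0.4, min_s = 64) {
  fmat <- as.matrix(fmat)
  nprobe <- ncol(fmat)
  ratio <- numeric(nprobe)
  n <- length(replicate_series(fmat[, 1], fs, min_s))
  half <- floor(n / 2)
  fr <- (1:half) * fs / n
  pow <- matrix(0, half, nprobe)
  for (q in seq_len(nprobe)) {
    x <- replicate_series(fmat[, q], fs, min_s)
    x <- x - mean(x)
    x <- stats::lm.fit(cbind(1, seq_along(x)), x)$residuals
    P <- Mod(stats::fft(x))^2
    P <- P[2:(half + 1)]                 # drop DC
    pow[, q] <- P
    tot <- sum(P)
    if (tot <= 0) { ratio[q] <- 0; next }
    pk <- fr[which.max(P)]
    ratio[q] <- sum(P[abs(fr - pk) <= window_hz]) / tot
  }
  list(accepted = ratio >= threshold, ratio = ratio, freq = fr, power = pow)
}

#' Pool probe series by spatial trimmed averaging
#'
#' Pointwise trimmed mean across the accepted probes (default 10% trimmed
#' from each tail at every time instant).
#'
#' @param fmat matrix (time x probes) of accepted series on a common grid
#' @param trim trim fraction per tail
#' @return pooled series (numeric vector)
#' @export
pool_ff <- function(fmat, trim = 0.1) {
  fmat <- as.matrix(fmat)
  if (ncol(fmat) == 0) stopf("no accepted series to pool")
  apply(fmat, 1, mean, trim = trim)
}

#' Temporal mean of the pooled frequency series
#' @param ff pooled frequency series (Hz)
#' @return mean frequency (Hz)
#' @export
mean_ff <- function(ff) {
  if (!length(ff)) stopf("empty series")
  mean(ff)
}

#' Respiration-band modulation magnitude
#'
#' The magnitude of the f-wave frequency modulation: the series is tiled
#' end-to-end to at least `min_s` seconds, bandpass filtered (zero-phase
#' order-4 Butterworth) in a 0.06 Hz band centered on the respiration rate,
#' and the upper envelope is taken as the magnitude of the analytic signal
#' (Hilbert transform).  The modulation magnitude is the median of the
#' envelope after trimming two filter time constants from each end.  For a
#' pure tone \eqn{\bar F + A \sin(2\pi f_r t)} this returns A.
#'
#' @param ff pooled frequency series (Hz) sampled at `fs`
#' @param resp_freq respiration rate (Hz); must exceed the half band-width
#'   0.03 Hz
#' @param fs sampling rate (Hz)
#' @param band_halfwidth half-width of the pass band (Hz)
#' @param min_s minimum tiled length (s)
#' @return modulation magnitude (Hz)
#' @export
delta_ff <- function(ff, resp_freq = 0.125, fs = 20, band_halfwidth = 0.03,
                     min_s = 64) {
  if (resp_freq <= band_halfwidth)
    stopf("respiration frequency must exceed the filter half-band %.2f Hz",
          band_halfwidth)
  x <- replicate_series(ff, fs, min_s)
  xf <- bandpass_filtfilt(x - mean(x), resp_freq - band_halfwidth,
                          resp_freq + band_halfwidth, fs)
  env <- Mod(analytic_signal(xf))
  tc <- 1 / (pi * band_halfwidth)          # filter time constant (s)
  k <- min(floor(2 * tc * fs), floor((length(env) - 8) / 2))
  stats::median(env[(k + 1):(length(env) - k)])
}

#' Spearman correlation between ACh and frequency series
#'
#' Standard rank correlation (average ranks for ties) between the ACh
#' waveform and the pooled frequency series on a common grid.
#'
#' @param ach ACh samples (uM)
#' @param ff frequency samples (Hz), same length
#' @return rho in [-1, 1]; NA (with a message) for constant input
#' @export
spearman_ach_ff <- function(ach, ff) {
  if (length(ach) != length(ff)) stopf("series lengths differ")
  if (length(ff) < 10) stopf("need at least 10 samples")
  if (stats::sd(ach) == 0 || stats::sd(ff) == 0) {
    message("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(ach, ff, method = "spearman")
}

#' Correlation under a fixed ACh-activation delay
#'
#' Shifts the ACh series by `delay` (the frequency response at time t is
#' attributed to the ACh concentration at t - delay), truncates both series
#' to the overlap, and returns the Spearman correlation.
#'
#' @param ach ACh samples on the common grid (uM)
#' @param ff frequency samples (Hz)
#' @param delay activation delay (ms), non-negative
#' @param fs sampling rate (Hz)
#' @return rho
#' @export
apply_delay_and_correlate <- function(ach, ff, delay = 0, fs = 20) {
  if (delay < 0) stopf("delay must be non-negative")
  k <- round(delay * fs / 1000)
  n <- length(ff)
  if (n - k < 10) stopf("fewer than 10 overlapping samples after the delay")
  if (k == 0) return(spearman_ach_ff(ach, ff))
  spearman_ach_ff(ach[seq_len(n - k)], ff[(k + 1):n])
}

#' Full f-wave frequency pipeline
#'
#' Runs the complete analysis chain on a probe recording: activation
#' detection at each probe, instantaneous frequency at 20 Hz, restriction to
#' the common time span, peak-conditioned spectral selection, spatial
#' trimmed averaging, and the summary metrics \eqn{\bar F_f} (temporal
#' mean), \eqn{\Delta F_f} (respiration-band modulation magnitude) and the
#' Spearman correlation \eqn{\rho} against the ACh waveform.
#'
#' @param recording a `voltage_recording` (from [simulate_tissue()] or
#'   [synth_ap_grid()])
#' @param ach an [ach_release()] model evaluated on the pooled grid, or a
#'   numeric series already on that grid, or NULL to skip the correlation
#' @param resp_freq respiration rate (Hz)
#' @param out_rate instantaneous-frequency sampling rate (Hz)
#' @param trim spatial trim fraction per tail
#' @param selection_threshold spectral concentration threshold
#' @param min_activations probes with fewer activations are dropped before
#'   selection
#' @param delay optional fixed ACh-activation delay (ms) applied before the
#'   correlation
#' @return an object of class `ff_series` with elements `t`, `ff`, `ffbar`,
#'   `dff`, `rho`, `accepted`, `n_probes_used`, `resp_freq`, `ach`
#' @export
ff_pipeline <- function(recording, ach = NULL, resp_freq = 0.125,
                        out_rate = 20, trim = 0.1,
                        selection_threshold = 0.4, min_activations = 4,
                        delay = 0) {
  v <- recording$v
  dt <- recording$sample_dt
  # detect_activations times are relative to the trace start; anchor them to
  # the recording's own clock so the ACh waveform is evaluated at the time
  # the tissue actually saw (recordings may start mid-simulation)
  offset <- if (!is.null(recording$t)) recording$t[1] - dt else 0
  series <- list()
  for (q in seq_len(ncol(v))) {
    act <- detect_activations(v[, q], dt) + offset
    if (length(act) < min_activations) next
    series[[length(series) + 1]] <- instantaneous_frequency(act, out_rate)
  }
  if (!length(series)) stopf("no probe produced enough activations")
  cg <- common_grid(series)
  sel <- peak_conditioned_selection(cg$f, fs = out_rate,
                                    threshold = selection_threshold,
                                    min_s = max(64, 1 / resp_freq))
  use <- sel$accepted
  if (!any(use)) use <- rep(TRUE, ncol(cg$f))  # degenerate: keep all
  ff <- pool_ff(cg$f[, use, drop = FALSE], trim = trim)
  ffbar <- mean_ff(ff)
  dff <- delta_ff(ff, resp_freq = resp_freq, fs = out_rate)
  ach_series <- NULL
  rho <- NA_real_
  if (!is.null(ach)) {
    ach_series <- if (inherits(ach, "ach_release")) {
      ach_waveform(cg$t, ach)
    } else as.numeric(ach)
    rho <- apply_delay_and_correlate(ach_series, ff, delay = delay,
                                     fs = out_rate)
  }
  structure(list(t = cg$t, ff = ff, ffbar = ffbar, dff = dff, rho = rho,
                 accepted = sel$accepted, ratio = sel$ratio,
                 n_probes_used = sum(use), resp_freq = resp_freq,
                 ach = ach_series),
            class = "ff_series")
}

#' @export
print.ff_series <- function(x, ...) {
  cat(sprintf(
    "f-wave frequency series: %d samples, %d probes pooled\n  Ffbar = %.3f Hz, dFf = %.3f Hz, rho = %s\n",
    length(x$ff), x$n_probes_used, x$ffbar, x$dff,
    ifelse(is.na(x$rho), "NA", sprintf("%.3f", x$rho))))
  invisible(x)
}
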