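# Synthetic fixtures: instantaneous-frequency series, AP-train probe grids
# and stylized travelling-wave fields, so the analysis pipeline is testable
# in seconds without PDE runs.  Every generator returns its ground truth.

#' Synthetic fixture specification
#'
#' Parameters of the synthetic generators: a base activation rate modulated
#' sinusoidally at the respiration frequency, optional additive noise, and a
#' stylized AP template for voltage-level fixtures.
#'
#' @param fbar base frequency (Hz)
#' @param a modulation amplitude (Hz); must satisfy `fbar - a > 0`
#' @param f_r modulation (respiration) frequency (Hz)
#' @param phase modulation phase (rad)
#' @param noise_sd additive Gaussian noise SD (Hz) on the frequency series
#' @param probes number of probes
#' @param duration_s duration (s); at least `2 / f_r`
#' @param seed RNG seed
#' @param apd AP-template duration to 90% repolarization (ms); the default
#'   80 ms reflects fibrillatory APDs and must stay below the shortest cycle
#'   length
#' @param fs frequency-series sampling rate (Hz)
#' @return an object of class `synth_spec`
#' @export
synth_spec <- function(fbar = 8, a = 0.15, f_r = 0.125, phase = 0,
                       noise_sd = 0, probes = 169, duration_s = 8, seed = 1,
                       apd = 80, fs = 20) {
  if (fbar - a <= 0) stopf("fbar - a must be positive")
  if (duration_s < 2 / f_r)
    stopf("duration must cover at least two modulation periods (%.1f s)",
          2 / f_r)
  structure(list(fbar = fbar, a = a, f_r = f_r, phase = phase,
                 noise_sd = noise_sd, probes = probes,
                 duration_s = duration_s, seed = seed, apd = apd, fs = fs),
            class = "synth_spec")
}

#' Synthetic instantaneous-frequency series
#'
#' Per-probe series \eqn{F_j(t) = \bar F + A \sin(2\pi f_r t + \phi) +
#' \epsilon_j(t)} on the uniform frequency grid, with seeded Gaussian noise.
#'
#' @param spec a [synth_spec()]
#' @return list with `t` (ms), `f` (time x probes matrix) and the ground
#'   truth `truth = list(fbar, a, f_r)`
#' @export
synth_ff_series <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  tg <- seq(0, spec$duration_s * 1000, by = 1000 / spec$fs)
  base <- spec$fbar + spec$a * sin(2 * pi * spec$f_r * tg / 1000 + spec$phase)
  f <- matrix(rep(base, spec$probes), ncol = spec$probes)
  if (spec$noise_sd > 0)
    f <- f + with_seed(spec$seed,
                       matrix(rnorm(length(f), 0, spec$noise_sd), nrow(f)))
  list(t = tg, f = f,
       truth = list(fbar = spec$fbar, a = spec$a, f_r = spec$f_r))
}

# stylized AP template sampled at dt ms: 1 ms upstroke from rest to peak,
# cosine plateau-decay reaching 90% repolarization at `apd`, then a short
# linear tail back to rest.
ap_template <- function(apd, dt, rest = -80, peak = 20) {
  amp <- peak - rest
  t_up <- seq(0, 1, by = dt)[-1]
  up <- rest + amp * t_up / 1
  t_dec <- seq(dt, apd, by = dt)
  dec <- rest + amp * (0.55 + 0.45 * cos(pi * t_dec / apd))
  tail_n <- max(1, round(15 / dt))
  tl <- seq(rest + 0.1 * amp, rest, length.out = tail_n)
  c(up, dec, tl)
}

# activation times from integrating the instantaneous rate r(t) =
# fbar + a sin(2 pi f_r t + phase): an activation fires each time the
# integral crosses an integer.
rate_activation_times <- function(fbar, a, f_r, phase, t_end_ms, t0_ms = 0) {
  # closed-form integral of the rate (in activations)
  Rint <- function(t_ms) {
    t <- t_ms / 1000
    fbar * t - a / (2 * pi * f_r) * cos(2 * pi * f_r * t + phase)
  }
  r0 <- Rint(t0_ms)
  n_max <- floor(Rint(t_end_ms) - r0)
  if (n_max < 1) return(numeric(0))
  out <- numeric(n_max)
  t_lo <- t0_ms
  for (k in seq_len(n_max)) {
    f <- function(t) Rint(t) - r0 - k
    t_hi <- t_end_ms
    out[k] <- stats::uniroot(f, c(t_lo, t_hi), tol = 1e-6)$root
    t_lo <- out[k]
  }
  out
}

#' Synthetic AP-train probe grid
#'
#' Builds a probe-grid voltage recording whose activation times follow the
#' prescribed modulated rate: the next activation fires when the integral of
#' \eqn{r(t) = \bar F + A\sin(2\pi f_r t + \phi)} crosses an integer, and a
#' stylized AP template is placed at each activation.  Per-probe start
#' offsets (seeded, uniform over one mean cycle) desynchronize the probes as
#' spatially distributed recording points would be.
#'
#' @param spec a [synth_spec()]
#' @param sample_dt voltage sampling interval (ms)
#' @return a `voltage_recording`-compatible object with the ground-truth
#'   activation times in `$truth`
#' @export
synth_ap_grid <- function(spec, sample_dt = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  min_cl <- 1000 / (spec$fbar + spec$a)
  if (spec$apd + 2 >= min_cl)
    stopf("AP template (%g ms) does not fit the shortest cycle length (%.1f ms)",
          spec$apd, min_cl)
  dur <- spec$duration_s * 1000
  tg <- seq(0, dur, by = sample_dt)
  tmpl <- ap_template(spec$apd, sample_dt)
  rest <- -80
  offsets <- with_seed(spec$seed, runif(spec$probes, 0, 1000 / spec$fbar))
  v <- matrix(rest, length(tg), spec$probes)
  truth <- vector("list", spec$probes)
  for (q in seq_len(spec$probes)) {
    act <- rate_activation_times(spec$fbar, spec$a, spec$f_r, spec$phase,
                                 dur, t0_ms = offsets[q])
    truth[[q]] <- act
    for (tm in act) {
      i0 <- round(tm / sample_dt) + 1
      idx <- i0:min(length(tg), i0 + length(tmpl) - 1)
      v[idx, q] <- tmpl[seq_along(idx)]
    }
  }
  structure(list(t = tg, v = v, probes = seq_len(spec$probes),
                 probe_xy = NULL, sample_dt = sample_dt,
                 nx = NA, ny = NA, h = NA, snapshots = NULL, snap_t = NULL,
                 truth = truth),
            class = "voltage_recording")
}

#' Stylized travelling-wave field sequence
#'
#' A plane wave of stylized APs sweeping bottom-to-top across a small grid
#' at a known front speed and activation rate; used as ground truth for the
#' pseudo-ECG operators.
#'
#' @param nx,ny grid size (nodes)
#' @param h_um spacing (um)
#' @param speed_cm_s front speed (cm/s)
#' @param rate_hz activation rate (Hz)
#' @param duration_ms duration (ms)
#' @param snapshot_dt snapshot interval (ms)
#' @param apd template APD (ms)
#' @return a `voltage_recording`-compatible object with full-field snapshots
#' @export
synth_field_snapshot_sequence <- function(nx = 40, ny = 40, h_um = 500,
                                          speed_cm_s = 50, rate_hz = 8,
                                          duration_ms = 2000,
                                          snapshot_dt = 2, apd = 80) {
  h_cm <- h_um / 1e4
  tg <- seq(snapshot_dt, duration_ms, by = snapshot_dt)
  period <- 1000 / rate_hz
  tmpl <- ap_template(apd, snapshot_dt)
  rest <- -80
  ys <- rep((0:(ny - 1)) * h_cm, each = 1)
  snaps <- matrix(rest, nx * ny, length(tg))
  for (s in seq_along(tg)) {
    # time since the front passed each row (periodic re-excitation)
    lag <- (tg[s] - ys / speed_cm_s * 1000) %% period
    row_v <- ifelse(tg[s] - ys / speed_cm_s * 1000 < 0, rest, {
      i <- pmin(length(tmpl), pmax(1, round(lag / snapshot_dt)))
      tmpl[i]
    })
    row_v[tg[s] - ys / speed_cm_s * 1000 >= 0 & lag / snapshot_dt > length(tmpl)] <- rest
    snaps[, s] <- rep(row_v, each = nx)
  }
  probes <- c(round(nx / 2) + nx * round(ny * 0.25),
              round(nx / 2) + nx * round(ny * 0.75))
  structure(list(t = tg, v = t(snaps[probes, , drop = FALSE]),
                 probes = probes, probe_xy = NULL, sample_dt = snapshot_dt,
                 nx = nx, ny = ny, h = h_um / 1000,
                 snapshots = snaps, snap_t = tg,
                 truth = list(speed_cm_s = speed_cm_s, rate_hz = rate_hz)),
            class = "voltage_recording")
}
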