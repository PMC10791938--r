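# Anisotropic 2D monodomain tissue: construction, conductivity calibration,
# stimulation protocols, simulation and conduction-velocity measurement.

# Longitudinal diffusivity (mm^2/ms) calibrated once so that a planar wave in
# a fibrosis-free, ACh-free strip of psAF-remodeled myocytes travels at
# 50 cm/s along the fiber direction (see calibrate_conductivity()).
DEFAULT_D_LONG <- 0.1279

#' Build a 2D atrial tissue model
#'
#' Constructs a rectangular sheet with a uniform bottom-to-top fiber
#' direction, a seeded diffuse-fibrosis label field (fibroblast nodes follow
#' the MacCannell model) and anisotropic gap-junctional coupling.
#' Fibroblast-fibroblast coupling is 1/4 of myocyte-myocyte coupling, and
#' myocyte-fibroblast coupling is divided by the myocyte's fibroblast
#' neighbor count, keeping the total fibroblast load per myocyte constant.
#'
#' @param size_cm tissue extent `c(x, y)` in cm; the fiber (longitudinal)
#'   direction is y, bottom to top
#' @param h_um node spacing (um)
#' @param fibrosis_fraction fraction of nodes assigned fibroblast properties
#'   (exact count, uniformly randomly placed)
#' @param seed RNG seed for the fibrosis field
#' @param params [myocyte_params()] for the myocyte nodes; defaults to the
#'   psAF-remodeled set with I_KACh enabled
#' @param D_long longitudinal diffusivity (mm^2/ms); the default reproduces a
#'   50 cm/s planar wave at 200 um spacing
#' @param Dt_ratio transverse-to-longitudinal conductivity ratio
#' @return an object of class `tissue_model`
#' @export
build_tissue <- function(size_cm = c(7, 7), h_um = 200,
                         fibrosis_fraction = 0.2, seed = 1,
                         params = myocyte_params(remodeled = TRUE),
                         D_long = DEFAULT_D_LONG, Dt_ratio = 0.5) {
  if (h_um <= 0) stopf("node spacing must be positive")
  if (fibrosis_fraction < 0 || fibrosis_fraction >= 1)
    stopf("fibrosis fraction must be in [0, 1)")
  h_mm <- h_um / 1000
  nx <- as.integer(round(size_cm[1] * 10 / h_mm)) + 1L
  ny <- as.integer(round(size_cm[2] * 10 / h_mm)) + 1L
  n <- nx * ny
  celltype <- integer(n)
  n_fib <- round(fibrosis_fraction * n)
  if (n_fib > 0) {
    idx <- with_seed(seed, sample.int(n, n_fib))
    celltype[idx] <- 1L
  }
  structure(list(
    nx = nx, ny = ny, h = h_mm, size_cm = size_cm,
    celltype = celltype, fibrosis_fraction = fibrosis_fraction, seed = seed,
    params = params, D_long = D_long, D_trans = D_long * Dt_ratio
  ), class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("2D atrial tissue: %g x %g cm (%d x %d nodes, %g um)\n",
              x$size_cm[1], x$size_cm[2], x$nx, x$ny, x$h * 1000))
  cat(sprintf("  fibrosis %.0f%% (seed %s), D_long %.4g mm^2/ms, D_t/D_l %.2f\n",
              100 * x$fibrosis_fraction, x$seed, x$D_long,
              x$D_trans / x$D_long))
  invisible(x)
}

n_nodes <- function(tissue) tissue$nx * tissue$ny

# node index from 1-based grid coordinates
node_index <- function(tissue, ix, iy) (iy - 1L) * tissue$nx + ix

# node coordinates in cm
node_xy <- function(tissue, idx) {
  ix <- (idx - 1L) %% tissue$nx
  iy <- (idx - 1L) %/% tissue$nx
  cbind(x = ix * tissue$h / 10, y = iy * tissue$h / 10)
}

# indices of nodes with coordinates inside a rectangle (cm)
rect_mask <- function(tissue, x0, x1, y0, y1) {
  xy <- node_xy(tissue, seq_len(n_nodes(tissue)))
  which(xy[, 1] >= x0 & xy[, 1] <= x1 & xy[, 2] >= y0 & xy[, 2] <= y1)
}

bottom_edge_mask <- function(tissue, rows = 2L) {
  which(rep(seq_len(tissue$ny), each = tissue$nx) <= rows)
}

left_edge_mask <- function(tissue, cols = 2L) {
  which(rep(seq_len(tissue$nx), times = tissue$ny) <= cols)
}

#' Uniform probe grid
#'
#' Evenly sampled interior probe nodes; the default 13 x 13 layout gives the
#' 169 recording points used for f-wave frequency analysis.
#'
#' @param tissue a [build_tissue()] model
#' @param n probes per side
#' @param margin_frac margin kept to the boundary, as a fraction of each side
#' @return integer node indices
#' @export
probe_grid <- function(tissue, n = 13, margin_frac = 0.05) {
  mx <- max(2L, round(tissue$nx * margin_frac))
  my <- max(2L, round(tissue$ny * margin_frac))
  ixs <- round(seq(mx, tissue$nx - mx, length.out = n))
  iys <- round(seq(my, tissue$ny - my, length.out = n))
  as.integer(outer(ixs, (iys - 1L) * tissue$nx, `+`))
}

new_protocol <- function(kind, stims, masks) {
  if (is.unsorted(stims$onset)) stims <- stims[order(stims$onset), ]
  if (any(diff(stims$onset) <= 0))
    stopf("stimulus onsets must be strictly increasing")
  structure(list(kind = kind, stims = stims, masks = masks),
            class = "stim_protocol")
}

#' Pre-pacing protocol
#'
#' A train of stimuli on the bottom edge of the tissue (default 14 stimuli at
#' a cycle length of 800 ms), used to condition the sheet before arrhythmia
#' induction.
#'
#' @param tissue tissue model
#' @param n_stimuli,cl train length and cycle length (ms)
#' @param amp,dur stimulus amplitude (pA/pF) and duration (ms)
#' @param onset time of the first stimulus (ms)
#' @param edge stimulated edge; "bottom" launches a wave along the fiber
#'   direction, "left" a transverse wave
#' @export
pre_pace_protocol <- function(tissue, n_stimuli = 14, cl = 800, amp = 40,
                              dur = 2, onset = 5,
                              edge = c("bottom", "left")) {
  edge <- match.arg(edge)
  mask <- if (edge == "bottom") bottom_edge_mask(tissue) else left_edge_mask(tissue)
  stims <- data.frame(onset = onset + (seq_len(n_stimuli) - 1) * cl,
                      duration = dur, amplitude = amp, mask_id = 1L)
  new_protocol("pre-pace", stims, list(mask))
}

#' S1-S2 cross-stimulation protocol
#'
#' Reentry induction: S1 stimuli on the bottom edge, then a premature S2 on a
#' square at the bottom-right corner (default 3.5 x 3.5 cm, the bottom-right
#' quarter of a 7 x 7 cm sheet) delivered `s2_coupling_interval` ms after the
#' last S1.  The orthogonal geometry leaves a free wave end that can curl
#' into a rotor for coupling intervals inside the vulnerable window.
#'
#' @param tissue tissue model
#' @param s2_coupling_interval S1-S2 interval (ms)
#' @param n_s1,cl number and cycle length of S1 stimuli
#' @param s2_size_cm side of the S2 square (cm)
#' @param amp,dur stimulus amplitude (pA/pF) and duration (ms)
#' @param onset time of the first S1 (ms)
#' @export
s1s2_cross_protocol <- function(tissue, s2_coupling_interval, n_s1 = 1,
                                cl = 800, s2_size_cm = 3.5, amp = 40,
                                dur = 2, onset = 5) {
  if (s2_coupling_interval <= 0) stopf("coupling interval must be positive")
  if (s2_size_cm > min(tissue$size_cm) + 1e-9)
    stopf("S2 square (%g cm) exceeds the tissue", s2_size_cm)
  s1_on <- onset + (seq_len(n_s1) - 1) * cl
  s2_on <- s1_on[n_s1] + s2_coupling_interval
  stims <- data.frame(
    onset = c(s1_on, s2_on),
    duration = dur, amplitude = amp,
    mask_id = c(rep(1L, n_s1), 2L)
  )
  s2_mask <- rect_mask(tissue,
                       tissue$size_cm[1] - s2_size_cm, tissue$size_cm[1],
                       0, s2_size_cm)
  new_protocol("s1s2-cross", stims, list(bottom_edge_mask(tissue), s2_mask))
}

#' Ectopic-train protocol
#'
#' An S1 followed by 10 premature stimuli at a focal site; the
#' inter-stimulus intervals start at 200 ms and shorten in 10 ms steps down
#' to 110 ms, so the train spans 1550 ms.
#'
#' @param tissue tissue model
#' @param site_mask node indices of the ectopic site (non-empty)
#' @param amp,dur stimulus amplitude (pA/pF) and duration (ms)
#' @param onset time of S1 (ms)
#' @export
ectopic_train_protocol <- function(tissue, site_mask, amp = 40,
                                   dur = 2, onset = 5) {
  site_mask <- as.integer(site_mask)
  if (!length(site_mask)) stopf("ectopic site mask is empty")
  if (any(site_mask < 1 | site_mask > n_nodes(tissue)))
    stopf("site mask outside the tissue")
  intervals <- seq(200, 110, by = -10)
  onsets <- onset + c(0, cumsum(intervals))
  stims <- data.frame(onset = onsets, duration = dur, amplitude = amp,
                      mask_id = 1L)
  new_protocol("ectopic-train", stims, list(site_mask))
}

# single-cell steady states used to initialize tissue runs, cached per
# parameter set / pacing protocol
.init_cache <- new.env(parent = emptyenv())

tissue_initial_states <- function(tissue, prepace_ms = 16 * 60 * 1000,
                                  cl = 800, dt = 0.02) {
  p <- tissue$params
  key <- paste(c(unlist(p, use.names = FALSE), cl, prepace_ms, dt),
               collapse = "|")
  if (!is.null(.init_cache[[key]])) return(.init_cache[[key]])
  myo <- if (prepace_ms >= cl) {
    pace_to_steady_state(p, cl = cl, duration = prepace_ms, dt = dt)$state
  } else myocyte_state()
  fb <- step_fibroblast(fibroblast_state(), 0, dt = 0.05, n = 100000) # 5 s
  out <- list(myo = myo, fb = fb)
  .init_cache[[key]] <- out
  out
}

#' Simulate the monodomain tissue
#'
#' Explicit operator-split reaction-diffusion advance with no-flux
#' boundaries.  Myocyte nodes at ACh-release sites see the ACh waveform of
#' `ach`; all other nodes see zero ACh.  Probe voltages are sampled at
#' `sample_dt`; full-field snapshots (for maps and pseudo-ECG) at
#' `snapshot_dt` if positive.
#'
#' @param tissue tissue model
#' @param protocol a stimulation protocol (or NULL for no stimulus)
#' @param ach an [ach_release()] model or NULL
#' @param duration simulated time (ms)
#' @param probes node indices to record; defaults to [probe_grid()]
#' @param sample_dt probe sampling interval (ms)
#' @param snapshot_dt full-field snapshot interval (ms); 0 disables
#' @param dt integration step (ms)
#' @param init list of `myo`/`fb` single-cell initial states, or matrices
#'   (21 x N and 4 x N) from a previous run; defaults to the 16-min paced
#'   single-cell steady state
#' @param prepace_ms single-cell pacing duration used for the default
#'   initialization
#' @return an object of class `voltage_recording`
#' @export
simulate_tissue <- function(tissue, protocol = NULL, ach = NULL, duration,
                            probes = NULL, sample_dt = 1, snapshot_dt = 0,
                            dt = 0.02, init = NULL,
                            prepace_ms = 16 * 60 * 1000) {
  stopifnot(inherits(tissue, "tissue_model"))
  if (duration <= 0) stopf("duration must be positive")
  n <- n_nodes(tissue)
  if (is.null(probes)) probes <- probe_grid(tissue)

  if (is.null(protocol)) {
    stims <- data.frame(onset = -1, duration = 0, amplitude = 0, mask_id = 1L)
    masks <- list(1L)
  } else {
    stopifnot(inherits(protocol, "stim_protocol"))
    stims <- protocol$stims
    masks <- protocol$masks
  }

  if (is.null(ach)) {
    ach_mask <- integer(n)
    ach_par <- c(0, 0, 0, 0, 0)
  } else {
    stopifnot(inherits(ach, "ach_release"))
    validate_physiological(ach, error = TRUE)
    ach_mask <- integer(n)
    ach_mask[ach$mask] <- 1L
    ach_par <- c(ach$mean, ach$delta, ach$freq, ach$phase, ach$delay)
  }

  if (is.null(init)) init <- tissue_initial_states(tissue, prepace_ms)
  if (is.matrix(init$myo)) {
    myo_init <- numeric(21); fb_init <- numeric(4)
    myo_full <- init$myo; fb_full <- init$fb
  } else {
    myo_init <- unname(init$myo); fb_init <- unname(init$fb)
    myo_full <- NULL; fb_full <- NULL
  }

  res <- cpp_tissue_run(
    tissue$celltype, tissue$nx, tissue$ny,
    tissue$D_long, tissue$D_trans, tissue$h,
    unclass(tissue$params), myo_init, fb_init, myo_full, fb_full,
    ach_mask, ach_par,
    as.matrix(stims[, c("onset", "duration", "amplitude", "mask_id")]),
    masks, duration, dt, as.integer(probes), sample_dt, snapshot_dt,
    return_state = TRUE)

  structure(list(
    t = res$t, v = res$v, probes = as.integer(probes),
    probe_xy = node_xy(tissue, probes), sample_dt = sample_dt,
    nx = tissue$nx, ny = tissue$ny, h = tissue$h,
    snapshots = if (snapshot_dt > 0) res$snapshots else NULL,
    snap_t = if (snapshot_dt > 0) res$snap_t else NULL,
    state = list(myo = res$myo_state, fb = res$fb_state),
    v_final = res$v_final
  ), class = "voltage_recording")
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("voltage recording: %d probes x %d samples (%g ms sampling)\n",
              ncol(x$v), nrow(x$v), x$sample_dt))
  if (!is.null(x$snapshots))
    cat(sprintf("  + %d full-field snapshots (%d nodes)\n",
                ncol(x$snapshots), nrow(x$snapshots)))
  invisible(x)
}

#' Measure conduction velocity
#'
#' Conduction velocity from the activation-time difference between two
#' probes, with activation defined at the maximum dV/dt.
#'
#' @param recording a [simulate_tissue()] recording of a planar wave
#' @param probe_pair indices (into the recording's probe set) of the two
#'   probes; they should be at least 2 cm apart and away from boundaries
#' @return conduction velocity (cm/s)
#' @export
measure_cv <- function(recording, probe_pair = c(1, 2)) {
  t_act <- vapply(probe_pair, function(q) {
    v <- recording$v[, q]
    dv <- diff(v)
    if (max(dv) / recording$sample_dt < 5)
      stopf("no activation detected at probe %d", q)
    recording$t[which.max(dv)]
  }, numeric(1))
  d_cm <- sqrt(sum((recording$probe_xy[probe_pair[1], ] -
                      recording$probe_xy[probe_pair[2], ])^2))
  dt_ms <- abs(diff(t_act))
  if (dt_ms <= 0) stopf("coincident activation times; probes too close")
  d_cm / dt_ms * 1000
}

# Planar-wave CV on a fibrosis-free strip along the fiber direction.
# `release` optionally holds an ach_release model (constant or sinusoidal).
strip_cv <- function(D_long, params = myocyte_params(remodeled = TRUE),
                     h_um = 200, Dt_ratio = 0.5, release = NULL,
                     length_cm = 6, width_cm = 0.2, dt = 0.02,
                     duration = 300, prepace_ms = 16 * 60 * 1000,
                     probe_y_cm = c(2, 4.5)) {
  tis <- build_tissue(size_cm = c(width_cm, length_cm), h_um = h_um,
                      fibrosis_fraction = 0, seed = 1, params = params,
                      D_long = D_long, Dt_ratio = Dt_ratio)
  mid <- as.integer(ceiling(tis$nx / 2))
  probes <- node_index(tis, mid, round(probe_y_cm * 10 / tis$h) + 1L)
  prot <- pre_pace_protocol(tis, n_stimuli = 1, onset = 5)
  rec <- simulate_tissue(tis, prot, ach = release, duration = duration,
                         probes = probes, sample_dt = 0.25, dt = dt,
                         prepace_ms = prepace_ms)
  measure_cv(rec)
}

#' Calibrate tissue conductivity
#'
#' Finds the longitudinal diffusivity that makes a planar wave on a
#' fibrosis-free, ACh-free strip travel at `target_cv` along the fiber
#' direction.  Uses the square-root scaling of conduction velocity with
#' diffusivity as a fixed-point update, refining until the measured CV is
#' within `tol` of the target.
#'
#' @param target_cv target longitudinal conduction velocity (cm/s)
#' @param params myocyte parameters of the strip
#' @param Dt_ratio transverse-to-longitudinal conductivity ratio carried into
#'   the returned pair
#' @param h_um node spacing (um)
#' @param dt integration step (ms)
#' @param D_start starting diffusivity (mm^2/ms)
#' @param tol acceptable |CV - target| (cm/s)
#' @param max_iter iteration cap
#' @return list with `D_long`, `D_trans`, achieved `cv` (cm/s) and the
#'   iteration trace
#' @export
calibrate_conductivity <- function(target_cv = 50,
                                   params = myocyte_params(remodeled = TRUE),
                                   Dt_ratio = 0.5, h_um = 200, dt = 0.02,
                                   D_start = DEFAULT_D_LONG, tol = 0.25,
                                   max_iter = 8) {
  if (target_cv <= 0) stopf("target CV must be positive")
  D <- D_start
  trace <- data.frame(D = numeric(0), cv = numeric(0))
  for (k in seq_len(max_iter)) {
    cv <- strip_cv(D, params = params, h_um = h_um, Dt_ratio = Dt_ratio, dt = dt)
    trace <- rbind(trace, data.frame(D = D, cv = cv))
    if (abs(cv - target_cv) <= tol)
      return(list(D_long = D, D_trans = D * Dt_ratio, cv = cv, trace = trace))
    D <- D * (target_cv / cv)^2
    if (D <= 0 || D > 2) stopf("calibration target unreachable (D = %g)", D)
  }
  stopf("calibration did not converge within %d iterations (last CV %.2f)",
        max_iter, cv)
}
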