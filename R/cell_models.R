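# Membrane kinetics: Courtemanche-Ramirez-Nattel atrial myocyte with
# persistent-AF remodeling and an ACh-activated potassium current, plus the
# MacCannell active fibroblast.

MYO_STATE_NAMES <- c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                     "d", "f", "fca", "u", "v", "w",
                     "Nai", "Ki", "Cai", "Caup", "Carel")
FB_STATE_NAMES <- c("V", "r", "s", "Ki")

#' ACh-activated potassium current
#'
#' Evaluates the acetylcholine-activated inward-rectifier potassium current
#' \eqn{I_{KACh}} used to model cholinergic (vagal) stimulation of atrial
#' myocytes.  The current is the product of a Hill-type dose term in the ACh
#' concentration (exponent 0.478, half-term 9.14, saturating at 10), an
#' inward-rectification term \eqn{0.05 + 5/(1 + e^{(V_m + 85)/5})}, and the
#' potassium driving force \eqn{(V_m - E_K)}.
#'
#' The current vanishes at zero dose and at zero driving force, and is outward
#' (positive) for \eqn{V_m > E_K} at positive dose.
#'
#' @param v_m membrane potential (mV)
#' @param ach ACh concentration (uM); must be non-negative
#' @param e_k potassium Nernst potential (mV)
#' @return current density (pA/pF), vectorized over the longest argument
#' @export
#' @examples
#' i_kach(-70, 0.1, -85)
#' i_kach(-70, 0, -85)    # zero dose -> 0
i_kach <- function(v_m, ach, e_k) {
  if (any(ach < 0)) stopf("ACh concentration must be non-negative")
  cpp_ikach(as.numeric(v_m), as.numeric(ach), as.numeric(e_k))
}

#' Myocyte parameter set
#'
#' Maximal conductances and pump/exchanger rates of the Courtemanche human
#' atrial myocyte (nS/pF or pA/pF; membrane capacitance in pF), with an
#' optional persistent-AF remodeling and a flag enabling \eqn{I_{KACh}}.
#' With `kach = TRUE` the current is present but contributes nothing at zero
#' ACh; in tissue only ACh-release nodes see a non-zero concentration.
#'
#' @param remodeled apply persistent-AF electrical remodeling
#'   (see [apply_psaf_remodeling()])
#' @param kach include the ACh-activated potassium current
#' @return an object of class `myocyte_params`
#' @export
myocyte_params <- function(remodeled = FALSE, kach = TRUE) {
  p <- list(
    Cm = 100, gNa = 7.8, gK1 = 0.09, gto = 0.1652,
    gKr = 0.029411765, gKs = 0.12941176, gCaL = 0.12375, gKur_sf = 1.0,
    gbCa = 0.001131, gbNa = 0.0006744375,
    ipca_max = 0.275, inak_max = 0.59933874, inaca_max = 1600,
    krel = 30, iup_max = 0.005,
    kach = isTRUE(kach), remodeled = FALSE
  )
  class(p) <- "myocyte_params"
  if (remodeled) p <- apply_psaf_remodeling(p)
  p
}

#' Apply persistent-AF electrical remodeling
#'
#' Scales four ionic conductances to represent persistent-AF electrical
#' remodeling: \eqn{g_{to}} x0.5, \eqn{g_{CaL}} x0.3, \eqn{g_{Kur}} x0.5 and
#' \eqn{g_{K1}} x2.  Applying the remodeling twice is an error (the scaling is
#' guarded, not idempotent).
#'
#' @param params a [myocyte_params()] object
#' @return the remodeled parameter set
#' @export
apply_psaf_remodeling <- function(params) {
  stopifnot(inherits(params, "myocyte_params"))
  if (isTRUE(params$remodeled))
    stopf("psAF remodeling already applied; refusing to apply it twice")
  params$gto <- params$gto * 0.5
  params$gCaL <- params$gCaL * 0.3
  params$gKur_sf <- params$gKur_sf * 0.5
  params$gK1 <- params$gK1 * 2.0
  params$remodeled <- TRUE
  params
}

#' @export
print.myocyte_params <- function(x, ...) {
  cat("Courtemanche myocyte parameters",
      if (x$remodeled) "(psAF remodeled)" else "(control)",
      if (x$kach) "+ I_KACh" else "", "\n")
  cat(sprintf("  gNa %.3g  gK1 %.3g  gto %.3g  gCaL %.3g  gKur x%.2g  Cm %g pF\n",
              x$gNa, x$gK1, x$gto, x$gCaL, x$gKur_sf, x$Cm))
  invisible(x)
}

#' Initial myocyte state
#'
#' Published resting initial conditions of the Courtemanche model: membrane
#' potential, 15 gating variables and 5 intracellular concentrations.
#'
#' @return named numeric vector of length 21
#' @export
myocyte_state <- function() {
  y <- cpp_myocyte_initial_state()
  names(y) <- MYO_STATE_NAMES
  y
}

#' Initial fibroblast state
#' @return named numeric vector (membrane potential, Kv gates, intracellular K+)
#' @export
fibroblast_state <- function() {
  y <- cpp_fibroblast_initial_state()
  names(y) <- FB_STATE_NAMES
  y
}

check_state <- function(res, nms) {
  if (res$bad_index > 0)
    stopf("state variable '%s' became non-finite", nms[res$bad_index])
  y <- res$state
  names(y) <- nms
  y
}

#' Advance a myocyte
#'
#' Steps the Courtemanche myocyte forward with Rush-Larsen gate updates and
#' forward-Euler concentration/potential updates.  `i_stim` and `ach` may be
#' scalars or per-step vectors (recycled).
#'
#' @param state myocyte state vector from [myocyte_state()]
#' @param params [myocyte_params()]
#' @param i_stim stimulus current density (pA/pF, positive depolarizes)
#' @param ach ACh concentration (uM)
#' @param dt time step (ms), at most 0.05
#' @param n number of steps
#' @param sample_dt if > 0, also return the membrane potential sampled at this
#'   interval (ms)
#' @return the state after `n` steps; if `sample_dt > 0`, a list with elements
#'   `state`, `t`, `v`
#' @export
step_myocyte <- function(state, params, i_stim = 0, ach = 0, dt = 0.02,
                         n = 1, sample_dt = 0) {
  stopifnot(inherits(params, "myocyte_params"))
  if (dt > 0.05) stopf("dt must be <= 0.05 ms for the ionic update")
  if (any(ach < 0)) stopf("ACh concentration must be non-negative")
  res <- cpp_myocyte_run(unname(state), unclass(params), i_stim, ach, dt,
                         as.integer(n), sample_dt)
  y <- check_state(res, MYO_STATE_NAMES)
  if (sample_dt > 0) list(state = y, t = res$t, v = res$v) else y
}

#' Advance a fibroblast
#'
#' Steps the MacCannell active fibroblast.  `i_coupling` (pA/pF) represents
#' gap-junctional load for a cell run in isolation; positive values are
#' outward (repolarizing), negative values depolarize.
#'
#' @inheritParams step_myocyte
#' @param i_coupling coupling current density (pA/pF), scalar or per-step
#' @export
step_fibroblast <- function(state, i_coupling = 0, dt = 0.02, n = 1,
                            sample_dt = 0) {
  if (dt > 0.05) stopf("dt must be <= 0.05 ms")
  res <- cpp_fibroblast_run(unname(state), i_coupling, dt, as.integer(n),
                            sample_dt)
  y <- check_state(res, FB_STATE_NAMES)
  if (sample_dt > 0) list(state = y, t = res$t, v = res$v) else y
}

#' Pace a myocyte to steady state
#'
#' Delivers 2-ms stimuli at a fixed cycle length and returns the end state
#' together with per-beat biomarkers.  The default duration (16 min at a cycle
#' length of 800 ms) brings the model to its pacing steady state, used to
#' initialize tissue simulations; at that duration successive-beat APD90
#' differences are below 1 ms.
#'
#' @param params [myocyte_params()]
#' @param cl cycle length (ms)
#' @param duration total paced time (ms); at least one beat
#' @param dt time step (ms)
#' @param ach constant ACh concentration (uM)
#' @param stim_amp stimulus amplitude (pA/pF); the default is roughly twice
#'   the diastolic threshold of this model (see [stimulus_threshold()])
#' @param stim_dur stimulus duration (ms)
#' @param state initial state; defaults to [myocyte_state()]
#' @param record_last record the membrane potential over the last
#'   `record_last` ms (at 0.5 ms sampling)
#' @return list with `state`, per-beat data frame `beats`
#'   (`t_up`, `apd90`, `rmp`, `dvdt_max`, `peak`, `captured`), and the
#'   recorded `t`/`v` trace
#' @export
pace_to_steady_state <- function(params, cl = 800, duration = 16 * 60 * 1000,
                                 dt = 0.02, ach = 0, stim_amp = 40,
                                 stim_dur = 2, state = NULL,
                                 record_last = 2 * cl) {
  stopifnot(inherits(params, "myocyte_params"))
  if (cl <= 0) stopf("cycle length must be positive")
  if (duration < cl) stopf("duration must cover at least one beat")
  if (is.null(state)) state <- myocyte_state()
  res <- cpp_myocyte_pace(unname(state), unclass(params), cl, duration, dt,
                          ach, stim_amp, stim_dur, 0,
                          0.5, max(0, duration - record_last))
  beats <- data.frame(
    t_up = res$beat_t_up, apd90 = res$beat_apd90, rmp = res$beat_rmp,
    dvdt_max = res$beat_dvdt_max, peak = res$beat_peak
  )
  beats$captured <- !is.na(beats$dvdt_max) & beats$dvdt_max > 10
  if (any(!beats$captured))
    stopf("loss of capture: no upstroke for %d of %d delivered stimuli",
          sum(!beats$captured), nrow(beats))
  y <- res$state
  names(y) <- MYO_STATE_NAMES
  list(state = y, beats = beats, t = res$t, v = res$v)
}

#' Diastolic stimulus threshold
#'
#' Bisection search for the minimum 2-ms stimulus amplitude that elicits an
#' upstroke (max dV/dt > 10 mV/ms) from the resting state.
#'
#' @param params [myocyte_params()]
#' @param dt time step (ms)
#' @param stim_dur stimulus duration (ms)
#' @return threshold amplitude (pA/pF)
#' @export
stimulus_threshold <- function(params, dt = 0.02, stim_dur = 2) {
  captures <- function(amp) {
    res <- cpp_myocyte_pace(unname(myocyte_state()), unclass(params),
                            1000, 100, dt, 0, amp, stim_dur, 0, 0, 0)
    isTRUE(res$beat_dvdt_max[1] > 10)
  }
  lo <- 0.5; hi <- 64
  if (!captures(hi)) stopf("no capture even at %g pA/pF", hi)
  for (k in 1:12) {
    mid <- (lo + hi) / 2
    if (captures(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Effective refractory period of a paced myocyte
#'
#' S1-S2 protocol on the single cell: after pacing to a steady state at the
#' S1 cycle length, a premature S2 is delivered at increasing coupling
#' intervals; the ERP is the shortest interval whose S2 elicits an upstroke
#' (max dV/dt > 10 mV/ms), located by bisection to 1 ms resolution.
#'
#' @param params [myocyte_params()]
#' @param cl S1 cycle length (ms)
#' @param ach constant ACh concentration (uM)
#' @param n_s1 conditioning beats
#' @param stim_amp,stim_dur stimulus amplitude (pA/pF) and duration (ms)
#' @param state initial state (defaults to the resting state)
#' @param dt time step (ms)
#' @return ERP estimate (ms)
#' @export
measure_erp <- function(params, cl = 800, ach = 0, n_s1 = 20, stim_amp = 40,
                        stim_dur = 2, state = NULL, dt = 0.02) {
  base <- pace_to_steady_state(params, cl = cl, duration = n_s1 * cl,
                               dt = dt, ach = ach, stim_amp = stim_amp,
                               stim_dur = stim_dur, state = state)
  s2_captures <- function(ci) {
    # one more S1 then the premature S2 as a short "cycle length"
    res <- cpp_myocyte_pace(unname(base$state), unclass(params), ci,
                            2 * ci, dt, ach, stim_amp, stim_dur, 0, 0, 0)
    d <- res$beat_dvdt_max
    length(d) >= 2 && !is.na(d[2]) && d[2] > 10
  }
  lo <- 20; hi <- 3 * cl / 2
  if (!s2_captures(hi)) stopf("no S2 capture even at %g ms", hi)
  while (hi - lo > 1) {
    mid <- round((lo + hi) / 2)
    if (s2_captures(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Action-potential biomarkers
#'
#' Computes APD90, resting membrane potential and maximum upstroke velocity
#' from a membrane-potential trace containing at least one captured action
#' potential.  The upstroke is located at the maximum dV/dt; APD90 runs from
#' the upstroke to 90% repolarization relative to the pre-upstroke diastolic
#' minimum.
#'
#' @param v membrane potential samples (mV)
#' @param dt sampling interval (ms)
#' @return list with `apd90` (ms), `rmp` (mV), `dvdt_max` (mV/ms)
#' @export
compute_ap_biomarkers <- function(v, dt) {
  if (length(v) < 3) stopf("trace too short")
  dvdt <- diff(v) / dt
  up <- which.max(dvdt)
  if (max(v) - min(v) < 20 || dvdt[up] <= 1)
    stopf("no action potential detected in trace")
  rmp <- min(v[seq_len(up)])
  post <- v[up:length(v)]
  peak_rel <- which.max(post)
  peak <- post[peak_rel]
  v90 <- peak - 0.9 * (peak - rmp)
  below <- which(post[-seq_len(peak_rel)] <= v90)
  if (!length(below)) stopf("action potential does not repolarize to 90%%")
  apd90 <- (peak_rel + below[1] - 1) * dt
  list(apd90 = apd90, rmp = rmp, dvdt_max = dvdt[up])
}
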