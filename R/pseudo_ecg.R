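# Equivalent-dipole unipolar pseudo-ECG from full-field snapshots, plus
# DFT-based dominant-frequency extraction.

#' Circular lead set
#'
#' Observation points for the pseudo-ECG: `n` points evenly spaced on a
#' circle in a plane `distance_cm` above the sheet, centered over the
#' tissue.  All points lie outside the tissue plane.
#'
#' @param recording_or_tissue a `voltage_recording` or `tissue_model`
#'   providing the grid geometry
#' @param n number of leads
#' @param distance_cm distance from the tissue plane (cm)
#' @param radius_cm circle radius (cm); defaults to half the tissue diagonal
#' @return matrix with columns x, y, z (cm), class `lead_set`
#' @export
lead_circle <- function(recording_or_tissue, n = 12, distance_cm = 3,
                        radius_cm = NULL) {
  g <- recording_or_tissue
  wx <- (g$nx - 1) * g$h / 10
  wy <- (g$ny - 1) * g$h / 10
  if (is.null(radius_cm)) radius_cm <- sqrt(wx^2 + wy^2) / 2
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pts <- cbind(x = wx / 2 + radius_cm * cos(th),
               y = wy / 2 + radius_cm * sin(th),
               z = distance_cm)
  structure(pts, class = c("lead_set", "matrix"))
}

#' Unipolar pseudo-ECG at external leads
#'
#' Equivalent-dipole volume-conductor sum: per lead L and snapshot, the
#' potential is \eqn{\phi_L \propto \sum_i \nabla V_m(i) \cdot
#' \nabla(1/r_{iL})} over tissue nodes (conductivity prefactor 1, arbitrary
#' units).  A spatially uniform field yields identically zero potentials.
#'
#' @param recording a `voltage_recording` carrying full-field snapshots
#' @param leads a [lead_circle()] matrix (cm); all points must be off the
#'   tissue plane or outside the sheet
#' @return object of class `lead_set_signals`: list with `t` (ms) and
#'   `v` (snapshots x leads)
#' @export
compute_pseudo_ecg <- function(recording, leads) {
  if (is.null(recording$snapshots))
    stopf("recording has no full-field snapshots (set snapshot_dt > 0)")
  nx <- recording$nx; ny <- recording$ny; h_cm <- recording$h / 10
  wx <- (nx - 1) * h_cm; wy <- (ny - 1) * h_cm
  inside <- leads[, 3] == 0 &
    leads[, 1] >= 0 & leads[, 1] <= wx & leads[, 2] >= 0 & leads[, 2] <= wy
  if (any(inside)) stopf("lead(s) inside the tissue domain")

  xs <- rep((0:(nx - 1)) * h_cm, times = ny)
  ys <- rep((0:(ny - 1)) * h_cm, each = nx)
  nlead <- nrow(leads)
  # per-lead kernels: grad(1/r) components at each node
  WX <- matrix(0, nx * ny, nlead); WY <- matrix(0, nx * ny, nlead)
  for (L in seq_len(nlead)) {
    dx <- xs - leads[L, 1]; dy <- ys - leads[L, 2]; dz <- -leads[L, 3]
    r3 <- (dx^2 + dy^2 + dz^2)^1.5
    WX[, L] <- -dx / r3
    WY[, L] <- -dy / r3
  }
  S <- ncol(recording$snapshots)
  out <- matrix(0, S, nlead)
  for (s in seq_len(S)) {
    V <- matrix(recording$snapshots[, s], nx, ny)
    gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
    gx[2:(nx - 1), ] <- (V[3:nx, ] - V[1:(nx - 2), ]) / (2 * h_cm)
    gy[, 2:(ny - 1)] <- (V[, 3:ny] - V[, 1:(ny - 2)]) / (2 * h_cm)
    out[s, ] <- as.numeric(crossprod(c(gx), WX) + crossprod(c(gy), WY))
  }
  structure(list(t = recording$snap_t, v = out, leads = leads),
            class = "lead_set_signals")
}

#' Dominant frequency of pseudo-ECG leads
#'
#' Per-lead magnitude spectrum (demeaned, Hann windowed, full-record DFT);
#' the dominant frequency is the largest-peak frequency within the search
#' band, and the returned estimate is the mean over leads.
#'
#' @param signals a [compute_pseudo_ecg()] result
#' @param band search band (Hz)
#' @return list with `f_mean` (Hz) and per-lead `f_peak`; `f_mean` is NA
#'   (reported, not an error) if all spectra are flat
#' @export
dominant_frequency_dft <- function(signals, band = c(2, 15)) {
  t <- signals$t
  if (length(t) < 4) stopf("lead signals too short")
  fs <- 1000 / diff(t[1:2])
  if ((t[length(t)] - t[1]) < 2000)
    stopf("lead duration must be at least 2 s")
  n <- nrow(signals$v)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))   # Hann
  half <- floor(n / 2)
  fr <- (1:half) * fs / n
  sel <- fr >= band[1] & fr <= band[2]
  fpk <- apply(signals$v, 2, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    X <- Mod(stats::fft((x - mean(x)) * w))[2:(half + 1)]
    if (max(X[sel]) <= 0) return(NA_real_)
    fr[sel][which.max(X[sel])]
  })
  list(f_mean = if (all(is.na(fpk))) NA_real_ else mean(fpk, na.rm = TRUE),
       f_peak = fpk)
}
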