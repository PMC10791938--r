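# Shared fixtures, computed lazily and cached for the session.

.fix <- new.env(parent = emptyenv())

# Single-cell steady state of the psAF-remodeled myocyte (short pacing is
# enough for the monotonicity and tissue tests; the full 16-min convergence
# is exercised in its own test).
paced_state <- function(n_beats = 50) {
  key <- paste0("paced", n_beats)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- pace_to_steady_state(myocyte_params(remodeled = TRUE),
                                        duration = n_beats * 800)$state
  .fix[[key]]
}

# quiescent initial states, used where pre-pacing is irrelevant
quiescent_init <- function() list(myo = myocyte_state(), fb = fibroblast_state())

# a small fibrosis-free strip along the fiber direction
small_strip <- function(length_cm = 3, width_cm = 0.2, h_um = 200, ...) {
  build_tissue(size_cm = c(width_cm, length_cm), h_um = h_um,
               fibrosis_fraction = 0, seed = 1, ...)
}

# calibrated longitudinal diffusivity (shared by the CV tests)
calibrated_D <- function() {
  if (is.null(.fix$cal)) .fix$cal <- calibrate_conductivity(50)
  .fix$cal
}

# scaled-down rotor runs (4 x 4 cm, 300 um, 20% fibrosis, 30% diffuse ACh
# release, f_r = 0.33 Hz, one modulation period), shared across criteria
rotor_fix <- function(dach) {
  key <- paste0("rotor", dach)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- rotor_experiment(
      ach_delta = dach, seed = 1,
      snapshot_dt = if (dach == 0.1) 10 else 0,
      delay_rho = if (dach == 0.1) 420 else numeric(0),
      s2_interval = .fix$rotor_ci)
    .fix$rotor_ci <- .fix[[key]]$s2_interval   # reuse the scanned interval
  }
  .fix[[key]]
}

# independent Spearman oracle: average ranks + explicit product-moment
# correlation of the rank vectors
rank_corr_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
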