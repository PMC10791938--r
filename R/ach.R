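# ACh release: spatial selection of release nodes (diffuse and
# ganglionated-plexus "octopus" configurations) and the sinusoidal temporal
# waveform.

#' ACh release model
#'
#' Couples a set of release nodes to a sinusoidal temporal waveform
#' \deqn{ACh(t) = \bar{ACh} + (\Delta ACh / 2)\,
#'   \sin(2\pi f (t - delay) + \phi).}
#' All release nodes share the waveform; non-release nodes see zero ACh.
#' Concentrations outside the physiological range 0-0.1 uM are rejected by
#' [validate_physiological()] before simulation.
#'
#' @param mask integer node indices of the release sites
#' @param mean mean concentration \eqn{\bar{ACh}} (uM)
#' @param delta peak-to-peak range \eqn{\Delta ACh} (uM)
#' @param freq modulation frequency (Hz); 0.125 Hz is the controlled
#'   respiration rate
#' @param phase phase (rad)
#' @param delay fixed activation delay (ms)
#' @param label configuration label, e.g. "D,30"
#' @return an object of class `ach_release`
#' @export
ach_release <- function(mask, mean, delta = 0, freq = 0.125, phase = 0,
                        delay = 0, label = NULL) {
  stopifnot(mean >= 0, delta >= 0, freq >= 0)
  structure(list(mask = as.integer(mask), mean = mean, delta = delta,
                 freq = freq, phase = phase, delay = delay,
                 label = label %||% sprintf("custom,%d nodes", length(mask))),
            class = "ach_release")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ach_release <- function(x, ...) {
  cat(sprintf(
    "ACh release [%s]: %d nodes, mean %.3g uM, peak-to-peak %.3g uM, %g Hz%s\n",
    x$label, length(x$mask), x$mean, x$delta, x$freq,
    if (x$delay != 0) sprintf(", delay %g ms", x$delay) else ""))
  invisible(x)
}

#' Physiological-range check
#'
#' Accepts a release model iff the full waveform range
#' \eqn{[\bar{ACh} - \Delta ACh/2,\; \bar{ACh} + \Delta ACh/2]} lies within
#' the physiological limits 0-0.1 uM.  The combination
#' \eqn{\bar{ACh} = 0.075}, \eqn{\Delta ACh = 0.1} uM is therefore rejected.
#'
#' @param model an [ach_release()] model
#' @param error raise an error instead of returning FALSE
#' @return logical
#' @export
validate_physiological <- function(model, error = FALSE) {
  lo <- model$mean - model$delta / 2
  hi <- model$mean + model$delta / 2
  ok <- lo >= 0 && hi <= 0.1 + 1e-12
  if (!ok && error)
    stopf("ACh waveform range [%.3g, %.3g] uM outside the physiological 0-0.1 uM",
          lo, hi)
  ok
}

#' ACh waveform
#'
#' Evaluates the temporal ACh concentration of a release model.
#'
#' @param t time (ms), vectorized
#' @param model an [ach_release()] model
#' @return concentration (uM)
#' @export
ach_waveform <- function(t, model) {
  model$mean + model$delta / 2 *
    sin(2 * pi * model$freq * (t - model$delay) / 1000 + model$phase)
}

#' Diffuse (spatially random) release nodes
#'
#' Uniformly randomly selects the requested fraction of nodes (exact count)
#' as ACh release sites; deterministic for a given seed.
#'
#' @param tissue tissue model
#' @param fraction fraction of nodes in [0, 1]
#' @param seed RNG seed
#' @return integer node indices
#' @export
diffuse_release_nodes <- function(tissue, fraction, seed = 1) {
  if (fraction < 0 || fraction > 1) stopf("fraction must be in [0, 1]")
  n <- n_nodes(tissue)
  k <- round(fraction * n)
  if (k == 0) return(integer(0))
  sort(with_seed(seed, sample.int(n, k)))
}

#' Octopus release specification
#'
#' Geometry of the ganglionated-plexus ("octopus") release pattern: GP core
#' disks plus straight nerve branches radiating from each core.  The shipped
#' default places five cores on a 7 x 7 cm sheet; anatomical coordinates are
#' user-supplied in general.
#'
#' @param centers n x 2 matrix of GP core centers (cm)
#' @param core_radius_cm core disk radius (cm)
#' @param branches branches per GP
#' @param branch_length_cm branch length (cm), about 2 cm for the main nerves
#' @param branch_halfwidth_cm branch half-width (cm)
#' @return an object of class `octopus_spec`
#' @export
octopus_spec <- function(centers = NULL, core_radius_cm = 0.25, branches = 8,
                         branch_length_cm = 2, branch_halfwidth_cm = 0.025) {
  if (is.null(centers))
    centers <- cbind(x = c(1.6, 5.3, 3.5, 1.7, 5.4),
                     y = c(1.6, 1.7, 3.6, 5.3, 5.4))
  if (branch_length_cm < 0) stopf("branch length must be non-negative")
  structure(list(centers = as.matrix(centers), core_radius_cm = core_radius_cm,
                 branches = branches, branch_length_cm = branch_length_cm,
                 branch_halfwidth_cm = branch_halfwidth_cm),
            class = "octopus_spec")
}

#' Octopus release nodes
#'
#' Builds the release mask as the union of the GP core disks and `branches`
#' straight branches per GP with seeded random orientations.  Branches
#' reaching outside the sheet are clipped (with a warning).
#'
#' @param tissue tissue model
#' @param spec an [octopus_spec()]
#' @param seed RNG seed for branch orientations
#' @return integer node indices
#' @export
octopus_release_nodes <- function(tissue, spec = octopus_spec(), seed = 1) {
  stopifnot(inherits(spec, "octopus_spec"))
  xy <- node_xy(tissue, seq_len(n_nodes(tissue)))
  ctr <- spec$centers
  if (any(ctr[, 1] < 0 | ctr[, 1] > tissue$size_cm[1] |
            ctr[, 2] < 0 | ctr[, 2] > tissue$size_cm[2]))
    stopf("GP centers must lie inside the tissue")
  sel <- rep(FALSE, nrow(xy))
  for (g in seq_len(nrow(ctr))) {
    d2 <- (xy[, 1] - ctr[g, 1])^2 + (xy[, 2] - ctr[g, 2])^2
    sel <- sel | d2 <= spec$core_radius_cm^2
  }
  if (spec$branch_length_cm > 0 && spec$branches > 0) {
    angles <- with_seed(seed + 1000, runif(nrow(ctr) * spec$branches, 0, 2 * pi))
    a <- 0L
    clipped <- FALSE
    for (g in seq_len(nrow(ctr))) {
      for (b in seq_len(spec$branches)) {
        a <- a + 1L
        ux <- cos(angles[a]); uy <- sin(angles[a])
        ex <- ctr[g, 1] + spec$branch_length_cm * ux
        ey <- ctr[g, 2] + spec$branch_length_cm * uy
        if (ex < 0 || ex > tissue$size_cm[1] || ey < 0 || ey > tissue$size_cm[2])
          clipped <- TRUE
        # distance of each node to the branch segment
        rx <- xy[, 1] - ctr[g, 1]; ry <- xy[, 2] - ctr[g, 2]
        s <- pmin(pmax(rx * ux + ry * uy, 0), spec$branch_length_cm)
        dx <- rx - s * ux; dy <- ry - s * uy
        sel <- sel | (dx * dx + dy * dy <= spec$branch_halfwidth_cm^2)
      }
    }
    if (clipped)
      warning("octopus branch(es) extended beyond the sheet and were clipped",
              call. = FALSE)
  }
  which(sel)
}

# Multi-source grid distance (in cm, 4-neighbor metric) from every node to
# the nearest node of `base`.
grid_distance <- function(tissue, base) {
  nx <- tissue$nx; ny <- tissue$ny
  n <- nx * ny
  d <- rep.int(NA_integer_, n)
  d[base] <- 0L
  frontier <- base
  lvl <- 0L
  while (length(frontier)) {
    lvl <- lvl + 1L
    ix <- (frontier - 1L) %% nx
    nb <- c(frontier[ix > 0L] - 1L, frontier[ix < nx - 1L] + 1L,
            frontier[frontier > nx] - nx, frontier[frontier <= n - nx] + nx)
    nb <- unique(nb[is.na(d[nb])])
    d[nb] <- lvl
    frontier <- nb
  }
  d * tissue$h / 10
}

#' Expand a release mask with radially decaying probability
#'
#' Grows a base mask (GP cores and main nerves) towards a target coverage by
#' accepting additional nodes with probability \eqn{\exp(-d/\lambda)}, where
#' d is the grid distance to the base mask.  The decay length \eqn{\lambda}
#' is auto-scaled so the expected final coverage equals the target; the base
#' mask is always retained.
#'
#' @param tissue tissue model
#' @param base_mask node indices of the base release pattern
#' @param target_fraction final coverage fraction (>= base coverage)
#' @param decay_length decay length (cm); NULL auto-scales
#' @param seed RNG seed for the acceptance draws
#' @return integer node indices
#' @export
expand_with_decay <- function(tissue, base_mask, target_fraction,
                              decay_length = NULL, seed = 1) {
  n <- n_nodes(tissue)
  base_frac <- length(base_mask) / n
  if (target_fraction < base_frac - 1e-12)
    stopf("target fraction %.3g below base coverage %.3g",
          target_fraction, base_frac)
  if (abs(target_fraction - base_frac) < 0.5 / n) return(sort(base_mask))
  d <- grid_distance(tissue, base_mask)
  outside <- which(d > 0)
  need <- target_fraction * n - length(base_mask)
  if (is.null(decay_length)) {
    f <- function(lam) sum(exp(-d[outside] / lam)) - need
    if (f(tissue$size_cm[1] * 4) < 0)
      stopf("target coverage unreachable with a decaying profile")
    decay_length <- stats::uniroot(f, c(1e-3, tissue$size_cm[1] * 4),
                                   tol = 1e-5)$root
  }
  p <- exp(-d[outside] / decay_length)
  acc <- with_seed(seed + 2000, runif(length(outside)) < p)
  sort(c(base_mask, outside[acc]))
}
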