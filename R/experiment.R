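# Experiment orchestration: configuration objects, the 2D experiment matrix
# and seeded, provenance-tracked runs.

#' Experiment configuration
#'
#' Bundles the tissue, protocol, ACh release and analysis parameters of one
#' run.  `kind = "synthetic"` analyses a generated AP grid (seconds);
#' `kind = "tissue"` runs the monodomain simulation.  Configurations whose
#' ACh waveform leaves the physiological range are rejected at construction.
#'
#' @param kind "synthetic" or "tissue"
#' @param release_fraction fraction of ACh release nodes
#' @param ach_mean,ach_delta mean and peak-to-peak ACh (uM)
#' @param ach_freq modulation frequency (Hz)
#' @param seed seed for all stochastic elements of the run
#' @param resp_freq analysis respiration rate (Hz); defaults to `ach_freq`
#' @param tissue_size_cm,h_um,fibrosis_fraction tissue geometry (tissue runs)
#' @param duration_s analysed duration (s)
#' @param synth synth overrides (list passed to [synth_spec()])
#' @param label configuration label
#' @return an object of class `experiment_config`
#' @export
experiment_config <- function(kind = c("synthetic", "tissue"),
                              release_fraction = 0.3, ach_mean = 0.05,
                              ach_delta = 0.05, ach_freq = 0.125, seed = 1,
                              resp_freq = NULL, tissue_size_cm = c(4, 4),
                              h_um = 300, fibrosis_fraction = 0.2,
                              duration_s = 8, synth = list(), label = NULL) {
  kind <- match.arg(kind)
  probe <- ach_release(integer(0), ach_mean, ach_delta, ach_freq)
  validate_physiological(probe, error = TRUE)
  cfg <- list(kind = kind, release_fraction = release_fraction,
              ach_mean = ach_mean, ach_delta = ach_delta,
              ach_freq = ach_freq, seed = seed,
              resp_freq = resp_freq %||% ach_freq,
              tissue_size_cm = tissue_size_cm, h_um = h_um,
              fibrosis_fraction = fibrosis_fraction,
              duration_s = duration_s, synth = synth,
              label = label %||% sprintf("D,%02.0f%% ACh %.3g/%.3g uM",
                                         100 * release_fraction, ach_mean,
                                         ach_delta))
  class(cfg) <- "experiment_config"
  cfg
}

#' The 2D experiment matrix
#'
#' Enumerates the 2D simulation grid: release fractions (8%, 30%) x mean ACh
#' (0.05, 0.075 uM) x peak-to-peak ACh (0, 0.05, 0.1 uM), minus the two
#' combinations (one per release fraction) whose waveform leaves the
#' physiological range (mean 0.075 with peak-to-peak 0.1), giving 10
#' configurations.
#'
#' @param kind passed to [experiment_config()]
#' @param seed base seed; each configuration gets an offset seed
#' @return list of [experiment_config()] objects
#' @export
experiment_matrix_2d <- function(kind = "synthetic", seed = 1) {
  out <- list()
  i <- 0L
  for (fr in c(0.08, 0.30))
    for (mean in c(0.05, 0.075))
      for (delta in c(0, 0.05, 0.1)) {
        probe <- ach_release(integer(0), mean, delta)
        if (!validate_physiological(probe)) next
        i <- i + 1L
        out[[i]] <- experiment_config(kind = kind, release_fraction = fr,
                                      ach_mean = mean, ach_delta = delta,
                                      seed = seed + i)
      }
  out
}

#' Run one experiment
#'
#' Executes simulate -> analyze -> report for a configuration and, if
#' `out_dir` is given, writes the pooled frequency series (TSV), the
#' analysis report (JSON) and a provenance record (config, seeds, package
#' version, config hash).  Re-running the same configuration reproduces the
#' report.
#'
#' @param config an [experiment_config()]
#' @param out_dir output directory or NULL
#' @return the analysis report (list), invisibly containing the `ff_series`
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$kind == "synthetic") {
    args <- utils::modifyList(
      list(fbar = 8, a = 3 * config$ach_delta, f_r = config$ach_freq,
           duration_s = config$duration_s, seed = config$seed),
      config$synth)
    spec <- do.call(synth_spec, args)
    rec <- synth_ap_grid(spec)
    ach_ref <- ach_release(integer(0), config$ach_mean, config$ach_delta,
                           config$ach_freq)
    res <- ff_pipeline(rec, ach = ach_ref, resp_freq = config$resp_freq)
  } else {
    sim <- rotor_experiment(
      size_cm = config$tissue_size_cm, h_um = config$h_um,
      fibrosis_fraction = config$fibrosis_fraction,
      release_fraction = config$release_fraction,
      ach_mean = config$ach_mean, ach_delta = config$ach_delta,
      ach_freq = config$ach_freq, seed = config$seed,
      duration_s = config$duration_s)
    res <- sim$ff
  }
  report <- list(label = config$label, ffbar = res$ffbar, dff = res$dff,
                 rho = res$rho, n_probes_used = res$n_probes_used,
                 resp_freq = res$resp_freq, seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    prov <- list(config_hash = unname(tools::md5sum(cfg_path)),
                 package_version = as.character(utils::packageVersion("vagalfib")),
                 seed = config$seed)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(data.frame(t_ms = res$t, ff_hz = res$ff),
                       file.path(out_dir, "ff_series.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report$ff_series <- res
  invisible(report)
}

#' Scaled-down rotor experiment
#'
#' The desk-scale analogue of the full 7 x 7 cm fibrillation runs: a rotor
#' is induced by S1-S2 cross-stimulation on a reduced sheet (default 4 x 4
#' cm at 300 um) with 20% diffuse fibrosis and diffuse ACh release, the
#' sheet is simulated over the requested window with a sinusoidal ACh
#' waveform, and the f-wave pipeline is applied to the 169-probe grid.
#'
#' The S2 coupling interval is scanned (5 ms steps across 0.7-1.1 x the
#' paced APD90) and the first interval sustaining reentry is used.
#'
#' @param size_cm,h_um,fibrosis_fraction sheet geometry
#' @param release_fraction fraction of diffuse ACh release nodes
#' @param ach_mean,ach_delta,ach_freq,ach_delay ACh waveform
#' @param seed seed (fibrosis field, release nodes)
#' @param duration_s analysed duration after induction (s)
#' @param settle_ms rotor stabilization time excluded between the S2 and the
#'   analysis window, clearing the induction wavefronts before activation
#'   intervals are interpreted as rotor cycle lengths
#' @param snapshot_dt full-field snapshot interval (ms), 0 to disable
#' @param s2_interval optional fixed S2 coupling interval (ms); skips the
#'   scan
#' @param delay_rho optional additional delays (ms) at which the Spearman
#'   correlation is re-evaluated
#' @return list with `ff` (the `ff_series`), `recording`, `s2_interval`,
#'   `rho_delayed`
#' @export
rotor_experiment <- function(size_cm = c(4, 4), h_um = 300,
                             fibrosis_fraction = 0.2,
                             release_fraction = 0.3, ach_mean = 0.05,
                             ach_delta = 0.1, ach_freq = 0.33,
                             ach_delay = 0, seed = 1, duration_s = NULL,
                             settle_ms = 500, snapshot_dt = 0,
                             s2_interval = NULL, delay_rho = numeric(0)) {
  tis <- build_tissue(size_cm = size_cm, h_um = h_um,
                      fibrosis_fraction = fibrosis_fraction, seed = seed)
  rel <- ach_release(diffuse_release_nodes(tis, release_fraction,
                                           seed = seed + 1),
                     ach_mean, ach_delta, ach_freq, delay = ach_delay,
                     label = sprintf("D,%02.0f%%", 100 * release_fraction))
  if (is.null(duration_s)) duration_s <- 1 / ach_freq
  if (is.null(s2_interval))
    s2_interval <- find_s2_interval(tis, rel)
  prot <- s1s2_cross_protocol(tis, s2_interval,
                              s2_size_cm = min(size_cm) / 2)
  s2_t <- prot$stims$onset[nrow(prot$stims)]
  settle <- settle_ms
  duration <- s2_t + settle + duration_s * 1000 + 200
  rec <- simulate_tissue(tis, prot, ach = rel, duration = duration,
                         snapshot_dt = snapshot_dt)
  # restrict the analysis to the window after rotor settling
  keep <- rec$t >= s2_t + settle
  rec_win <- rec
  rec_win$v <- rec$v[keep, , drop = FALSE]
  rec_win$t <- rec$t[keep]
  ff <- ff_pipeline(rec_win, ach = rel, resp_freq = ach_freq)
  rho_delayed <- vapply(delay_rho, function(d)
    apply_delay_and_correlate(ff$ach, ff$ff, delay = d), numeric(1))
  list(ff = ff, recording = rec, s2_interval = s2_interval,
       rho_delayed = rho_delayed, tissue = tis, release = rel)
}

#' Scan S1-S2 coupling intervals for sustained reentry
#'
#' Candidate intervals are anchored at the single-cell effective refractory
#' period under the release model's mean ACh (reentry needs an S2 close to
#' the recovery boundary) and tried in 5 ms steps.  Each candidate first
#' passes a short propagation pre-check (does the S2 wave escape the S2
#' square?); the first propagating candidate is then simulated further and
#' accepted if self-sustained activity persists (>= 4 activations at the
#' sheet center within 400-1400 ms after S2).
#'
#' @param tissue tissue model
#' @param ach [ach_release()] model active during induction
#' @param intervals candidate intervals (ms); NULL derives them from the ERP
#' @param check_ms observation window after S2 (ms)
#' @return the selected coupling interval (ms)
#' @export
find_s2_interval <- function(tissue, ach = NULL, intervals = NULL,
                             check_ms = 1400) {
  if (is.null(intervals)) {
    erp <- measure_erp(tissue$params, cl = 800,
                       ach = if (is.null(ach)) 0 else ach$mean,
                       state = tissue_initial_states(tissue)$myo)
    lo <- round((erp - 10) / 5) * 5
    intervals <- seq(lo, lo + 120, by = 5)
  }
  center <- node_index(tissue, round(tissue$nx / 2), round(tissue$ny / 2))
  # pre-check probe to the LEFT of the S2 square: leftward escape through
  # recovered tissue is the first leg of the reentrant path (upward
  # propagation is blocked by the S1 tail when the rotor forms)
  s2_size <- min(tissue$size_cm) / 2
  left <- node_index(tissue, max(2L, round(tissue$nx * 0.2)),
                     max(2L, round(tissue$ny * 0.2)))
  propagates <- function(ci) {
    prot <- s1s2_cross_protocol(tissue, ci, s2_size_cm = s2_size)
    s2_t <- prot$stims$onset[nrow(prot$stims)]
    rec <- simulate_tissue(tissue, prot, ach = ach,
                           duration = s2_t + 150, probes = left)
    any(detect_activations(rec$v[rec$t > s2_t, 1], rec$sample_dt) > 0)
  }
  sustained <- function(ci) {
    prot <- s1s2_cross_protocol(tissue, ci, s2_size_cm = s2_size)
    s2_t <- prot$stims$onset[nrow(prot$stims)]
    rec <- simulate_tissue(tissue, prot, ach = ach,
                           duration = s2_t + check_ms, probes = center)
    late <- rec$v[rec$t > s2_t + 400, 1]
    length(detect_activations(late, rec$sample_dt)) >= 4
  }
  for (ci in intervals) {
    if (!propagates(ci)) next
    if (sustained(ci)) return(ci)
  }
  stopf("no coupling interval in %s-%s ms induced sustained reentry",
        min(intervals), max(intervals))
}
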