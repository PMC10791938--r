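# Membrane kinetics: I_KACh, psAF remodeling, myocyte and fibroblast
# integration, pacing and biomarkers.

test_that("I_KACh vanishes at zero dose and zero driving force", {
  expect_identical(i_kach(-70, 0, -85), 0)
  expect_identical(i_kach(-85, 0.1, -85), 0)
  expect_error(i_kach(-70, -0.01, -85), "non-negative")
})

test_that("I_KACh matches the hand-evaluated dose/rectifier/driving product", {
  # independent scalar evaluation of the three factors
  dose <- 10 / (1 + 9.14 / 0.1^0.478)
  rect <- 0.05 + 5 / (1 + exp((-70 + 85) / 5))
  expect_equal(i_kach(-70, 0.1, -85), dose * rect * (-70 - (-85)),
               tolerance = 1e-12)
  expect_equal(i_kach(-70, 0.1, -85), 1.5125, tolerance = 1e-4)
})

test_that("I_KACh is continuous and increasing in dose above E_K", {
  doses <- seq(0, 0.1, by = 0.002)
  cur <- i_kach(rep(-70, length(doses)), doses, rep(-85, length(doses)))
  expect_true(all(diff(cur) > 0))
  expect_true(all(cur[-1] > 0))
  # continuity at zero dose
  expect_lt(i_kach(-70, 1e-9, -85), 1e-3)
})

test_that("psAF remodeling scales the four target conductances once", {
  p0 <- myocyte_params(remodeled = FALSE)
  p1 <- apply_psaf_remodeling(p0)
  expect_equal(p1$gto, 0.5 * p0$gto)
  expect_equal(p1$gCaL, 0.3 * p0$gCaL)
  expect_equal(p1$gKur_sf, 0.5 * p0$gKur_sf)
  expect_equal(p1$gK1, 2.0 * p0$gK1)
  expect_equal(p1$gNa, p0$gNa)   # untouched conductances unchanged
  expect_equal(p1$gKr, p0$gKr)
  expect_error(apply_psaf_remodeling(p1), "twice")
})

test_that("resting myocyte is stable over 1 s without stimulus", {
  y0 <- myocyte_state()
  y1 <- step_myocyte(y0, myocyte_params(remodeled = FALSE, kach = FALSE),
                     i_stim = 0, ach = 0, dt = 0.02, n = 50000)
  expect_lt(abs(y1["V"] - y0["V"]), 1)
  expect_error(step_myocyte(y0, myocyte_params(), dt = 0.1), "dt")
})

test_that("gates stay in [0,1] and concentrations positive under random stimuli", {
  set.seed(42)
  # 10 s with random 2-ms stimulus bursts
  istim <- rep(0, 500000)
  onsets <- sort(sample.int(490000, 25))
  for (o in onsets) istim[o:(o + 100)] <- runif(1, 0, 60)
  y <- step_myocyte(myocyte_state(), myocyte_params(remodeled = TRUE),
                    i_stim = istim, dt = 0.02, n = length(istim))
  gates <- y[c("m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
               "d", "f", "fca", "u", "v", "w")]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_true(all(y[c("Nai", "Ki", "Cai", "Caup", "Carel")] > 0))
  expect_true(all(is.finite(y)))
})

test_that("pacing converges: successive-beat APD90 difference < 1 ms at 16 min", {
  res <- pace_to_steady_state(myocyte_params(remodeled = TRUE),
                              cl = 800, duration = 16 * 60 * 1000)
  apd <- stats::na.omit(res$beats$apd90)
  expect_gt(length(apd), 1000)
  expect_lt(abs(diff(tail(apd, 2))), 1)
  expect_true(all(res$beats$captured))
})

test_that("single-beat pacing returns a post-beat state without convergence", {
  res <- pace_to_steady_state(myocyte_params(remodeled = TRUE),
                              cl = 800, duration = 800)
  expect_equal(nrow(res$beats), 1)
  expect_true(res$beats$captured[1])
  expect_error(pace_to_steady_state(myocyte_params(), duration = 100), "beat")
})

test_that("subthreshold stimuli raise a loss-of-capture error", {
  expect_error(
    pace_to_steady_state(myocyte_params(remodeled = TRUE),
                         duration = 3 * 800, stim_amp = 1),
    "capture")
})

test_that("default stimulus is about twice the diastolic threshold", {
  thr <- stimulus_threshold(myocyte_params(remodeled = TRUE))
  expect_gt(40, 1.3 * thr)
  expect_lt(40, 4 * thr)
})

test_that("APD90 and RMP decrease monotonically with ACh dose", {
  doses <- c(0, 0.025, 0.05, 0.075, 0.1)
  p <- myocyte_params(remodeled = TRUE, kach = TRUE)
  out <- t(vapply(doses, function(d) {
    b <- pace_to_steady_state(p, duration = 20 * 800, ach = d,
                              state = paced_state())$beats
    c(apd = tail(b$apd90, 1), rmp = tail(b$rmp, 1))
  }, numeric(2)))
  expect_true(all(diff(out[, "apd"]) < 0))
  expect_true(all(diff(out[, "rmp"]) < 0))
})

test_that("psAF remodeling shortens the steady-pacing APD", {
  apd_c <- tail(pace_to_steady_state(myocyte_params(remodeled = FALSE),
                                     duration = 20 * 800)$beats$apd90, 1)
  apd_r <- tail(pace_to_steady_state(myocyte_params(remodeled = TRUE),
                                     duration = 20 * 800)$beats$apd90, 1)
  expect_lt(apd_r, apd_c)
})

test_that("halving dt changes APD90 by less than 0.5 ms", {
  p <- myocyte_params(remodeled = TRUE)
  apd <- vapply(c(0.02, 0.01), function(dt)
    tail(pace_to_steady_state(p, duration = 10 * 800, dt = dt)$beats$apd90, 1),
    numeric(1))
  expect_lt(abs(diff(apd)), 0.5)
})

test_that("free-running fibroblast relaxes to a stable resting potential", {
  res <- step_fibroblast(fibroblast_state(), 0, dt = 0.05, n = 100000,
                         sample_dt = 10)
  v <- res$v                                  # 5 s sampled at 10 ms
  expect_lt(abs(tail(v, 1) - tail(v, 100)[1]), 0.05)   # flat over the last 1 s
  # regression fixture: converged resting potential of this formulation
  expect_equal(unname(res$state["V"]), -48.88, tolerance = 0.01)
})

test_that("depolarizing coupling shifts the fibroblast above its free rest", {
  free <- step_fibroblast(fibroblast_state(), 0, dt = 0.05, n = 100000)
  loaded <- step_fibroblast(free, -1, dt = 0.05, n = 40000)  # inward current
  expect_gt(loaded["V"], free["V"])
})

test_that("fibroblast gates stay in [0,1] under random coupling", {
  set.seed(7)
  ic <- rnorm(200000, 0, 1.5)   # 10 s at dt 0.05
  y <- step_fibroblast(fibroblast_state(), ic, dt = 0.05, n = length(ic))
  expect_true(all(y[c("r", "s")] >= 0 & y[c("r", "s")] <= 1))
  expect_true(is.finite(y["V"]))
})

test_that("biomarkers recover a rectangular pulse and reject flat traces", {
  dt <- 0.5
  width <- 120
  v <- c(rep(-80, 40), rep(20, width / dt), rep(-80, 200))
  bm <- compute_ap_biomarkers(v, dt)
  expect_equal(bm$apd90, width, tolerance = 2 * dt / width)
  expect_equal(bm$rmp, -80)
  expect_error(compute_ap_biomarkers(rep(-80, 100), dt), "no action potential")
})

test_that("Courtemanche control-beat biomarkers match the regression fixture", {
  res <- pace_to_steady_state(myocyte_params(remodeled = FALSE, kach = FALSE),
                              duration = 8 * 800)
  b <- tail(res$beats, 1)
  # frozen from the first converged run of this implementation
  expect_equal(b$apd90, 269.9, tolerance = 0.01)
  expect_equal(b$rmp, -80.48, tolerance = 0.001)
  expect_gt(b$dvdt_max, 150)
})
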