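# f-wave frequency pipeline: activation detection, instantaneous frequency,
# spectral selection, pooling, modulation magnitude and rank correlation.

test_that("activation detection recovers known upstroke instants", {
  spec <- synth_spec(fbar = 6, a = 0.5, f_r = 0.25, probes = 3,
                     duration_s = 8, seed = 2)
  grid <- synth_ap_grid(spec)
  for (q in 1:3) {
    act <- detect_activations(grid$v[, q], grid$sample_dt)
    truth <- grid$truth[[q]]
    m <- min(length(act), length(truth))
    expect_lte(abs(length(act) - length(truth)), 1)   # boundary AP at most
    expect_lt(max(abs(act[seq_len(m)] - truth[seq_len(m)])),
              1.01 * grid$sample_dt)
  }
})

test_that("constant traces yield no activations and one AP yields one", {
  expect_equal(length(detect_activations(rep(-80, 1000), 1)), 0)
  v <- c(rep(-80, 100), seq(-80, 20, length.out = 3), rep(20, 50),
         seq(20, -80, length.out = 100), rep(-80, 100))
  expect_equal(length(detect_activations(v, 1)), 1)
})

test_that("refractory separation suppresses double-counting of one upstroke", {
  v <- c(rep(-80, 50), seq(-80, 20, length.out = 6), rep(20, 30),
         rep(-80, 50))
  expect_equal(length(detect_activations(v, 1, refractory_min = 40)), 1)
})

test_that("constant activation intervals give the exact frequency", {
  f8 <- instantaneous_frequency(seq(0, 4000, by = 125))
  expect_true(all(abs(f8$f - 8) < 1e-9))
  f5 <- instantaneous_frequency(seq(0, 4000, by = 200))
  expect_true(all(abs(f5$f - 5) < 1e-9))
  expect_error(instantaneous_frequency(100), "at least 2")
})

test_that("interpolated series equals 1/interval at on-grid activation times", {
  # activation instants on the 20 Hz grid: intervals 100, 150, 200, 250 ms
  times <- cumsum(c(0, 100, 150, 200, 250, 150, 100))
  s <- instantaneous_frequency(times)
  f_true <- 1000 / diff(times)
  on_grid <- times[-1]
  idx <- match(on_grid, s$t)
  ok <- !is.na(idx)
  expect_true(any(ok))
  expect_equal(s$f[idx[ok]], f_true[ok], tolerance = 1e-9)
})

test_that("peak-conditioned selection keeps tones and rejects noise", {
  t <- seq(0, 16, by = 0.05)[-1]
  tone <- 8 + 0.2 * sin(2 * pi * 0.125 * t)
  expect_true(peak_conditioned_selection(cbind(tone))$accepted)
  # Monte-Carlo acceptance of white noise under the default threshold
  acc <- vapply(1:100, function(s) {
    set.seed(s)
    peak_conditioned_selection(cbind(rnorm(length(t))))$accepted
  }, logical(1))
  expect_lt(mean(acc), 0.05)
  # mixed pool: exactly the tonal members accepted
  set.seed(9)
  pool <- cbind(tone, rnorm(length(t)), 6 + 0.1 * sin(2 * pi * 0.2 * t),
                rnorm(length(t)))
  sel <- peak_conditioned_selection(pool)
  expect_identical(unname(sel$accepted), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("trimmed pooling is exact for identical probes and robust to outliers", {
  t <- seq(0, 8, by = 0.05)[-1]
  base <- 8 + 0.3 * sin(2 * pi * 0.125 * t)
  same <- matrix(rep(base, 12), ncol = 12)
  expect_equal(pool_ff(same), base)
  out <- cbind(same, base + 25)          # one wild probe among 13
  expect_equal(pool_ff(out, trim = 0.1), base, tolerance = 1e-9)
  expect_error(pool_ff(matrix(numeric(0), 10, 0)), "no accepted")
})

test_that("pooling phase-shifted sinusoids attenuates like the phasor mean", {
  t <- seq(0, 16, by = 0.05)[-1]
  ph <- c(0, 0.4, -0.4, 0.8, -0.8)
  mat <- sapply(ph, function(p) 8 + 0.2 * sin(2 * pi * 0.125 * t + p))
  pooled <- pool_ff(mat, trim = 0)
  expect_equal(max(pooled) - min(pooled), 2 * 0.2 * Mod(mean(exp(1i * ph))),
               tolerance = 0.01)
})

test_that("mean_ff is the plain temporal mean", {
  expect_equal(mean_ff(rep(8.23, 100)), 8.23)
  t <- seq(0.05, 16, by = 0.05)
  expect_equal(mean_ff(8 + 0.15 * sin(2 * pi * 0.125 * t)), 8,
               tolerance = 1e-3)
  expect_equal(mean_ff(seq(2, 10, length.out = 101)), 6)
  expect_error(mean_ff(numeric(0)), "empty")
})

test_that("delta_ff recovers tone amplitudes and rejects out-of-band energy", {
  t <- seq(0.05, 16, by = 0.05)
  for (A in c(0.05, 0.15, 0.30)) {
    x <- 8 + A * sin(2 * pi * 0.125 * t)
    expect_equal(delta_ff(x, 0.125), A, tolerance = 0.05)
  }
  expect_equal(delta_ff(rep(5, 400), 0.125), 0)
  x04 <- 8 + 0.3 * sin(2 * pi * 0.4 * t)
  expect_lt(delta_ff(x04, 0.125), 0.05)
  expect_error(delta_ff(rep(5, 400), 0.02), "half-band")
})

test_that("delta_ff is DC-invariant, scale-equivariant and replication-stable", {
  t <- seq(0.05, 16, by = 0.05)
  x <- 0.2 * sin(2 * pi * 0.125 * t)
  d0 <- delta_ff(5 + x, 0.125)
  expect_equal(delta_ff(9 + x, 0.125), d0, tolerance = 1e-9)
  expect_equal(delta_ff(5 + 3 * x, 0.125), 3 * d0, tolerance = 1e-9)
  d128 <- delta_ff(5 + x, 0.125, min_s = 128)
  expect_lt(abs(d128 - d0) / d0, 0.02)
})

test_that("Spearman correlation matches an independent rank oracle", {
  expect_equal(spearman_ach_ff(1:20, (1:20)^3), 1)
  expect_equal(spearman_ach_ff(1:20, exp(-(1:20))), -1)
  set.seed(31)
  x <- rnorm(160)
  y <- 0.8 * x + rnorm(160)
  expect_equal(spearman_ach_ff(x, y), rank_corr_oracle(x, y),
               tolerance = 1e-12)
  # ties handled by average ranks
  xt <- rep(1:40, each = 4); yt <- xt + rnorm(160, 0, 5)
  expect_equal(spearman_ach_ff(xt, yt), rank_corr_oracle(xt, yt),
               tolerance = 1e-12)
  expect_message(r <- spearman_ach_ff(rep(1, 20), rnorm(20)), "constant")
  expect_true(is.na(r))
  expect_error(spearman_ach_ff(1:5, 1:5), "10 samples")
})

test_that("delays shift the correlation as the phase geometry dictates", {
  t <- seq(0.05, 32, by = 0.05)
  a <- sin(2 * pi * 0.125 * t)
  f <- 8 + 0.3 * sin(2 * pi * 0.125 * t)
  expect_equal(apply_delay_and_correlate(a, f, 0), spearman_ach_ff(a, f))
  # half-period delay flips the sign
  r0 <- apply_delay_and_correlate(a, f, 0)
  r_half <- apply_delay_and_correlate(a, f, 4000)
  expect_gt(r0, 0.99)
  expect_lt(r_half, -0.95)
  # 420 ms is small against an 8 s period: |change| well under 0.1
  r420 <- apply_delay_and_correlate(a, f, 420)
  expect_lt(abs(r420 - r0), 0.1)
  expect_error(apply_delay_and_correlate(a, f, -1), "non-negative")
})

test_that("pipeline recovers modulation parameters across the study grid", {
  for (fbar in c(5, 8))
    for (a in c(0.05, 0.3))
      for (fr in c(0.125, 0.33)) {
        spec <- synth_spec(fbar = fbar, a = a, f_r = fr, probes = 16,
                           duration_s = max(16, 2 / fr), seed = 17)
        res <- ff_pipeline(synth_ap_grid(spec), resp_freq = fr)
        expect_lt(abs(res$ffbar - fbar), 0.02 * fbar)
        expect_lt(abs(res$dff - a), 0.1 * a + 0.005)
      }
})

test_that("in-phase and anti-phase modulation give opposite-signed rho", {
  mk <- function(phase) {
    spec <- synth_spec(fbar = 8, a = 0.3, f_r = 0.125, probes = 16,
                       duration_s = 16, phase = phase, seed = 5)
    ach <- ach_release(1L, 0.05, 0.1, 0.125)
    ff_pipeline(synth_ap_grid(spec), ach = ach, resp_freq = 0.125)$rho
  }
  expect_gt(mk(0), 0.9)
  expect_lt(mk(pi), -0.9)
})
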