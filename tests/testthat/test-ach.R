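# ACh release masks (diffuse, octopus, decaying expansion) and the temporal
# waveform.

test_that("the sinusoidal waveform hits mean, peak and trough", {
  m <- ach_release(1L, mean = 0.05, delta = 0.1, freq = 0.125)
  expect_equal(ach_waveform(0, m), 0.05)
  expect_equal(ach_waveform(2000, m), 0.10)   # quarter period: peak
  expect_equal(ach_waveform(6000, m), 0.00)   # three quarters: trough
  # zero peak-to-peak returns the mean everywhere
  mc <- ach_release(1L, mean = 0.075, delta = 0)
  expect_true(all(ach_waveform(seq(0, 1e4, 100), mc) == 0.075))
})

test_that("waveform mean and range over whole periods are exact", {
  m <- ach_release(1L, 0.05, 0.08, freq = 0.25, phase = 0.7)
  t <- seq(0, 8000 - 1, by = 1)          # two full periods at 1 ms
  w <- ach_waveform(t, m)
  expect_equal(mean(w), 0.05, tolerance = 1e-6)
  expect_equal(max(w) - min(w), 0.08, tolerance = 1e-6)
})

test_that("a fixed delay shifts the waveform without changing mean or range", {
  m0 <- ach_release(1L, 0.05, 0.1, freq = 0.125)
  m1 <- ach_release(1L, 0.05, 0.1, freq = 0.125, delay = 420)
  t <- seq(0, 16000 - 1, by = 1)
  w0 <- ach_waveform(t, m0); w1 <- ach_waveform(t, m1)
  expect_equal(mean(w1), mean(w0), tolerance = 1e-6)
  expect_equal(max(w1) - min(w1), max(w0) - min(w0), tolerance = 1e-6)
  expect_equal(w1[421], w0[1], tolerance = 1e-12)
})

test_that("physiological-range validation matches the 0-0.1 uM limits", {
  expect_false(validate_physiological(ach_release(1L, 0.075, 0.1)))
  expect_true(validate_physiological(ach_release(1L, 0.05, 0.1)))
  expect_true(validate_physiological(ach_release(1L, 0.075, 0.05)))
  expect_true(validate_physiological(ach_release(1L, 0.1, 0)))
  expect_error(validate_physiological(ach_release(1L, 0.075, 0.1),
                                      error = TRUE), "physiological")
})

test_that("diffuse selection is exact-count, seeded and uniform", {
  tis <- build_tissue(size_cm = c(2, 2), h_um = 200, fibrosis_fraction = 0)
  n <- tis$nx * tis$ny
  m8 <- diffuse_release_nodes(tis, 0.08, seed = 3)
  expect_equal(length(m8), round(0.08 * n))
  expect_identical(m8, diffuse_release_nodes(tis, 0.08, seed = 3))
  expect_equal(length(diffuse_release_nodes(tis, 0)), 0)
  expect_equal(length(diffuse_release_nodes(tis, 0.30, seed = 1)),
               round(0.30 * n))
  # spatial uniformity: quadrant counts balanced
  xy <- vagalfib:::node_xy(tis, m8)
  q <- table(xy[, 1] > 1, xy[, 2] > 1)
  expect_true(max(q) / min(q) < 1.3)
  expect_error(diffuse_release_nodes(tis, 1.5), "fraction")
})

test_that("octopus mask reduces to the cores at zero branch length", {
  tis <- build_tissue(size_cm = c(7, 7), h_um = 400, fibrosis_fraction = 0)
  spec <- octopus_spec(centers = cbind(3.5, 3.5), core_radius_cm = 0.5,
                       branch_length_cm = 0)
  m <- octopus_release_nodes(tis, spec)
  xy <- vagalfib:::node_xy(tis, seq_len(tis$nx * tis$ny))
  d <- sqrt((xy[, 1] - 3.5)^2 + (xy[, 2] - 3.5)^2)
  expect_setequal(m, which(d <= 0.5))
})

test_that("a 2 cm branch at 200 um spacing spans about 100 nodes", {
  tis <- build_tissue(size_cm = c(7, 7), h_um = 200, fibrosis_fraction = 0)
  spec <- octopus_spec(centers = cbind(3.5, 3.5), core_radius_cm = 0.1,
                       branches = 1, branch_length_cm = 2,
                       branch_halfwidth_cm = 0.011)
  m <- octopus_release_nodes(tis, spec, seed = 5)
  # mask length along the branch: core (~1 node wide) + ~100 branch nodes
  expect_gt(length(m), 80)
  expect_lt(length(m), 250)
})

test_that("default octopus layout covers about 8% of the 7x7 cm sheet", {
  tis <- build_tissue(size_cm = c(7, 7), h_um = 300, fibrosis_fraction = 0)
  m <- suppressWarnings(octopus_release_nodes(tis, octopus_spec(), seed = 1))
  frac <- length(m) / (tis$nx * tis$ny)
  expect_gt(frac, 0.06)
  expect_lt(frac, 0.10)
  expect_error(octopus_release_nodes(
    tis, octopus_spec(centers = cbind(9, 3))), "inside")
})

test_that("decaying expansion reaches the target coverage and keeps the base", {
  tis <- build_tissue(size_cm = c(7, 7), h_um = 300, fibrosis_fraction = 0)
  base <- suppressWarnings(octopus_release_nodes(tis, octopus_spec(), seed = 1))
  m <- expand_with_decay(tis, base, 0.30, seed = 4)
  n <- tis$nx * tis$ny
  expect_lt(abs(length(m) / n - 0.30), 0.005 + 3 * sqrt(0.3 * 0.7 / n))
  expect_true(all(base %in% m))
  # target equal to base coverage: unchanged
  expect_identical(expand_with_decay(tis, base, length(base) / n), sort(base))
  expect_error(expand_with_decay(tis, base, 0.01), "below base")
})

test_that("expansion acceptance decreases with distance from the base", {
  tis <- build_tissue(size_cm = c(7, 7), h_um = 300, fibrosis_fraction = 0)
  base <- suppressWarnings(octopus_release_nodes(tis, octopus_spec(), seed = 1))
  m <- expand_with_decay(tis, base, 0.30, seed = 4)
  d <- vagalfib:::grid_distance(tis, base)
  added <- setdiff(m, base)
  near <- which(d > 0 & d <= 0.3)
  far <- which(d > 0.6 & d <= 1.2)
  acc_near <- mean(near %in% added)
  acc_far <- mean(far %in% added)
  expect_gt(acc_near, acc_far)
})
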