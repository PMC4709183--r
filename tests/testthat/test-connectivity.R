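test_that("Hilbert phase advances linearly for a cosine", {
  fs <- 250
  t <- seq(0, 2, by = 1 / fs)[-1]
  data <- array(0, dim = c(1, 2, length(t)))
  data[1, 1, ] <- cos(2 * pi * 5 * t)
  data[1, 2, ] <- sin(2 * pi * 5 * t)
  ph <- instantaneous_phase(fake_epochs(data, fs = fs))
  expect_true(all(ph$phases > -pi & ph$phases <= pi))
  interior <- 100:400
  d <- diff(ph$phases[1, 1, interior])
  d <- (d + pi) %% (2 * pi) - pi
  slope_hz <- mean(d) * fs / (2 * pi)
  expect_lt(abs(slope_hz - 5) / 5, 0.01)
  # cos leads sin by pi/2
  dphi <- ph$phases[1, 1, interior] - ph$phases[1, 2, interior]
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_equal(mean(dphi), pi / 2, tolerance = 0.01)
  # phase is invariant to positive scaling
  data2 <- data * 3.7
  ph2 <- instantaneous_phase(fake_epochs(data2, fs = fs))
  expect_equal(ph$phases, ph2$phases, tolerance = 1e-9)
})

test_that("all-zero signals are rejected as degenerate", {
  data <- array(rnorm(2 * 2 * 100), dim = c(2, 2, 100))
  data[2, 1, ] <- 0
  expect_error(instantaneous_phase(fake_epochs(data)), "degenerate")
})

test_that("19 channels index 171 pairs", {
  ph <- fake_phase_tensor(array(runif(3 * 19 * 10, -pi, pi),
                                dim = c(3, 19, 10)))
  plv <- plv_timecourse(ph)
  expect_identical(nrow(plv$plv), 171L)
  expect_identical(nrow(plv$pairs), 171L)
  expect_true(all(plv$pairs[, 1] < plv$pairs[, 2]))
})

test_that("pipeline PLV matches the brute-force complex-sum oracle", {
  set.seed(61)
  for (dims in list(c(6, 4, 20), c(3, 3, 15), c(2, 4, 8))) {
    ph <- array(runif(prod(dims), -pi, pi), dim = dims)
    plv <- plv_timecourse(fake_phase_tensor(ph))
    expect_lt(max(abs(plv$plv - brute_plv(ph))), 1e-12)
    expect_true(all(plv$plv >= 0 & plv$plv <= 1 + 1e-15))
  }
})

test_that("PLV is 1 for identical or constant-offset phases and is
           invariant to a common phase function", {
  set.seed(62)
  ph <- array(0, dim = c(5, 2, 30))
  base <- matrix(runif(5 * 30, -pi, pi), 5)
  ph[, 1, ] <- base
  ph[, 2, ] <- base
  plv <- plv_timecourse(fake_phase_tensor(ph))
  expect_equal(max(abs(plv$plv - 1)), 0, tolerance = 1e-12)
  # constant per-trial offset still gives PLV 1 at every t
  ph[, 2, ] <- base + 0.8
  plv2 <- plv_timecourse(fake_phase_tensor(ph))
  expect_equal(max(abs(plv2$plv - 1)), 0, tolerance = 1e-12)
  # adding a common phase function to both channels changes nothing
  ph3 <- array(runif(5 * 2 * 30, -pi, pi), dim = c(5, 2, 30))
  common <- matrix(runif(5 * 30, -pi, pi), 5)
  ph4 <- ph3
  ph4[, 1, ] <- ph4[, 1, ] + common
  ph4[, 2, ] <- ph4[, 2, ] + common
  expect_equal(plv_timecourse(fake_phase_tensor(ph3))$plv,
               plv_timecourse(fake_phase_tensor(ph4))$plv,
               tolerance = 1e-12)
  expect_error(plv_timecourse(fake_phase_tensor(ph3[1, , , drop = FALSE])),
               "at least 2 trials")
})

test_that("independent uniform phases reach the Rayleigh resultant level", {
  set.seed(63)
  tr <- 100
  ph <- array(runif(tr * 2 * 500, -pi, pi), dim = c(tr, 2, 500))
  plv <- plv_timecourse(fake_phase_tensor(ph))
  # E[PLV] ~ sqrt(pi)/2 / sqrt(Tr) = 0.0886 at Tr = 100
  expect_lt(abs(mean(plv$plv) - sqrt(pi) / 2 / sqrt(tr)), 0.01)
  # E[PLV^2] = 1/Tr exactly
  expect_lt(abs(mean(plv$plv^2) - 1 / tr), 0.002)
})

test_that("surrogates preserve amplitude spectra exactly", {
  set.seed(64)
  x <- matrix(rnorm(500 * 3), 500)
  y <- phase_randomize(x, seed = 8)
  for (c in 1:3) {
    a0 <- Mod(fft(x[, c]))
    a1 <- Mod(fft(y[, c]))
    keep <- a0 > 1e-8
    expect_lt(max(abs(a1[keep] - a0[keep]) / a0[keep]), 1e-9)
  }
  expect_false(isTRUE(all.equal(x, y)))
  expect_identical(phase_randomize(x, seed = 8), y)
})

test_that("surrogates destroy perfect coupling", {
  set.seed(65)
  fs <- 250
  tr <- 30
  t <- seq_len(250) / fs
  data <- array(0, dim = c(tr, 2, 250))
  for (k in seq_len(tr)) {
    ph0 <- runif(1, 0, 2 * pi)
    s <- cos(2 * pi * 6 * t + ph0)
    data[k, 1, ] <- s + rnorm(250, sd = 0.05)
    data[k, 2, ] <- s + rnorm(250, sd = 0.05)
  }
  ep <- fake_epochs(data, fs = fs)
  obs <- window_average(plv_timecourse(ep))
  expect_gt(mean_plv_feature(obs), 0.95)
  surr <- make_surrogates(ep, n_surrogates = 200, seed = 9)
  expect_lt(mean(surr$plv_surr), 0.2)
  # determinism under a fixed seed
  surr2 <- make_surrogates(ep, n_surrogates = 200, seed = 9)
  expect_identical(surr$plv_surr, surr2$plv_surr)
})

test_that("edge decisions follow the add-one rank formula", {
  labels <- paste0("C", 1:3)
  g <- window_average(plv_timecourse(fake_phase_tensor(
    array(runif(4 * 3 * 100, -pi, pi), dim = c(4, 3, 100)), fs = 250)))
  n <- 200
  surr <- structure(list(
    plv_surr = matrix(runif(n * 3, 0.2, 0.4), n), pairs = g$pairs,
    window = c(200, 500), n_surrogates = n, alpha = 0.01),
    class = "surrogate_distribution")
  # pair 1 beats every surrogate -> p = 1/201 < 0.01 -> edge retained;
  # pair 2 sits below the surrogate median -> rejected
  g$pair_weights <- c(0.99, 0.25, 0.41)
  out <- significant_edges(g, surr, alpha = 0.01)
  p <- out$pvalues[out$pairs]
  expect_equal(p[1], 1 / 201)
  expect_true(out$adjacency[1, 2])
  expect_false(out$adjacency[1, 3])
  expect_gt(p[2], 0.5)
  expect_equal(out$edge_count, sum(out$adjacency) / 2)
  expect_true(all(out$adjacency == t(out$adjacency)))
  expect_true(all(!diag(out$adjacency)))
})

test_that("window averaging produces symmetric zero-diagonal matrices", {
  set.seed(66)
  ph <- fake_phase_tensor(array(runif(5 * 4 * 250, -pi, pi),
                                dim = c(5, 4, 250)), fs = 250)
  plv <- plv_timecourse(ph)
  g <- window_average(plv, c(200, 500))
  expect_true(isSymmetric(g$weights))
  expect_true(all(diag(g$weights) == 0))
  expect_true(all(g$weights >= 0 & g$weights <= 1))
  # constant PLV c over the epoch averages to c for every pair
  plv$plv[] <- 0.37
  gc <- window_average(plv, c(200, 500))
  expect_equal(unname(gc$weights[gc$pairs]), rep(0.37, 6))
  expect_error(window_average(plv, c(1100, 1200)), "outside the epoch")
})

test_that("mean PLV feature summarises the upper triangle invariantly", {
  w <- matrix(0.5, 4, 4); diag(w) <- 0
  g <- list(pair_weights = w[upper.tri(w)])
  expect_equal(mean_plv_feature(g), 0.5)
  g0 <- list(pair_weights = rep(0, 6))
  expect_equal(mean_plv_feature(g0), 0)
  # permutation of channel labels leaves the mean unchanged
  set.seed(67)
  v <- runif(6)
  expect_equal(mean_plv_feature(list(pair_weights = v)),
               mean_plv_feature(list(pair_weights = sample(v))))
})

test_that("condition contrast behaves at both extremes", {
  same <- rep(c(1, 2, 3, 4, 5), 2)
  ct <- condition_contrast(same, same)
  expect_gt(ct$p_value, 0.9)
  sep <- condition_contrast(11:20, 1:10)
  expect_lt(sep$p_value, 0.001)
  expect_error(condition_contrast(1:3, 1:10), "at least 5")
})

test_that("optional PLV baseline normalization standardises the baseline", {
  set.seed(68)
  ep <- fake_epochs(array(rnorm(6 * 3 * 250), dim = c(6, 3, 250)),
                    fs = 250)
  plv <- plv_timecourse(ep)
  nz <- normalize_plv(plv)
  bi <- plv$time_ms >= -200 & plv$time_ms < 0
  expect_equal(rowMeans(nz$plv[, bi]), rep(0, 3), tolerance = 1e-10)
})
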