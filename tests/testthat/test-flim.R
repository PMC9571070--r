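test_that("simulated decays have the requested photon budget and determinism", {
  h1 <- simulate_decay(3.99, n_photons = 1e5, seed = 11)
  h2 <- simulate_decay(3.99, n_photons = 1e5, seed = 11)
  expect_identical(h1, h2)
  expect_equal(sum(h1$counts), 1e5)
  expect_true(all(h1$counts >= 0 & h1$counts == round(h1$counts)))
  expect_equal(sum(h1$irf), 1, tolerance = 1e-12)
})

test_that("the empirical tail decay constant matches the simulated lifetime", {
  h <- simulate_decay(3.99, n_photons = 1e6, seed = 5)
  t <- h$bin_times
  # log-linear regression on the clean tail (past the IRF, well above wrap)
  use <- t > 4 & t < 16 & h$counts > 0
  tau_tail <- -1 / coef(lm(log(h$counts[use]) ~ t[use]))[2]
  expect_equal(unname(tau_tail), 3.99, tolerance = 0.01 / 3.99)
})

test_that("a zero-amplitude second component reproduces the mono-exponential curve", {
  h1 <- simulate_decay(3.0, n_photons = 1e5, seed = 2, poisson = FALSE)
  h2 <- simulate_decay(c(3.0, 1.0), c(1, 0), n_photons = 1e5, seed = 2,
                       poisson = FALSE)
  expect_equal(h1$counts, h2$counts, tolerance = 1e-12)
})

test_that("degenerate and unresolvable inputs are rejected", {
  expect_error(simulate_decay(300, n_photons = 1e4), "resolved")
  expect_error(simulate_decay(-1, n_photons = 1e4), "positive")
  expect_error(simulate_decay(3.99, n_photons = 0), ">= 1")
})

test_that("the pre-pulse baseline equals the periodic steady-state residual", {
  # for tau = 4 ns and a 25 ns period the wrapped tail before the pulse is
  # exp(-25/4)/(1-exp(-25/4)) of the post-pulse peak decay level
  h <- simulate_decay(4, n_photons = 2e6, irf_center = 5, seed = 9)
  t <- h$bin_times
  pre <- mean(h$counts[t > 2 & t < 4])    # just before the pulse at 5 ns
  post <- mean(h$counts[t > 7 & t < 9])   # ~2-4 ns after the pulse
  # analytic ratio of the periodic decay at the same phases
  ratio_expected <- exp(-mean(c(22, 24)) / 4) / exp(-mean(c(2, 4)) / 4)
  expect_equal(pre / post, ratio_expected, tolerance = 0.05)
})

test_that("reconvolution fitting inverts the noise-free forward model", {
  h <- simulate_decay(3.99, n_photons = 1e6, poisson = FALSE)
  f <- fit_decay(h, 1)
  expect_equal(f$lifetimes, 3.99, tolerance = 1e-3)
  expect_equal(f$tau_avg, f$lifetimes)
  expect_lt(abs(f$shift), 0.01)
})

test_that("lifetimes are recovered across a tau and photon-budget grid", {
  for (tau in c(0.5, 1, 2, 4)) {
    for (np in c(1e4, 1e5)) {
      h <- simulate_decay(tau, n_photons = np,
                          seed = round(tau * 1000 + log10(np)))
      f <- suppressWarnings(fit_decay(h, 1))
      tol <- if (np >= 1e5) 0.02 else 0.06
      expect_equal(f$lifetimes, tau, tolerance = tol,
                   label = sprintf("tau=%g photons=%g", tau, np))
    }
  }
})

test_that("biexponential lifetimes and tau_avg are recovered within tolerance", {
  # intensity fractions 0.6 / 0.4: the photon share of component i is
  # a_i * tau_i, so the pre-exponential amplitudes are f_i / tau_i
  amps <- c(0.6 / 3.99, 0.4 / 1.2)
  truth_avg <- sum(c(0.6, 0.4) * c(3.99, 1.2))  # intensity-weighted mean
  errs <- t(vapply(1:50, function(s) {
    h <- simulate_decay(c(3.99, 1.2), amps, n_photons = 1e6, seed = s)
    f <- fit_decay(h, 2)
    c(abs(f$lifetimes - c(3.99, 1.2)) / c(3.99, 1.2),
      abs(f$tau_avg - truth_avg) / truth_avg)
  }, numeric(3)))
  expect_lt(max(errs[, 1]), 0.05)
  expect_lt(max(errs[, 2]), 0.05)
  expect_lt(max(errs[, 3]), 0.02)
})

test_that("overparameterizing a mono-exponential decay leaves tau_avg intact", {
  h <- simulate_decay(3.99, n_photons = 1e6, seed = 31)
  f1 <- fit_decay(h, 1)
  f2 <- fit_decay(h, 2)
  expect_equal(f2$tau_avg, f1$tau_avg, tolerance = 0.01)
  # second component is negligible or indistinct
  expect_true(min(f2$amplitudes) < 0.05 ||
                abs(diff(f2$lifetimes)) / max(f2$lifetimes) < 0.1)
})

test_that("low-count histograms trigger a warning", {
  h <- simulate_decay(3, n_photons = 500, seed = 1)
  expect_warning(fit_decay(h, 1), "unreliable")
})

test_that("intensity-weighted average lifetime follows its closed form", {
  expect_equal(average_lifetime(list(amplitudes = c(1, 1),
                                     lifetimes = c(4, 2))), 10 / 3)
  expect_equal(average_lifetime(list(amplitudes = c(1, 0),
                                     lifetimes = c(4, 2))), 4)
  expect_equal(average_lifetime(list(amplitudes = 1, lifetimes = 3.2)), 3.2)
  expect_error(average_lifetime(list(amplitudes = c(0, 0),
                                     lifetimes = c(4, 2))), "zero")
})

test_that("lifetime-derived efficiency is antitone with a fixed point at zero", {
  expect_equal(efficiency_from_lifetimes(3.99, 3.99), 0)
  expect_equal(efficiency_from_lifetimes(3.40, 3.99), 1 - 3.40 / 3.99)
  expect_equal(efficiency_from_lifetimes(3.54, 3.99), 1 - 3.54 / 3.99)
  taus <- seq(1, 3.99, 0.25)
  expect_true(all(diff(efficiency_from_lifetimes(taus, 3.99)) < 0))
  expect_lt(efficiency_from_lifetimes(4.2, 3.99), 0)  # reported as-is
  expect_error(efficiency_from_lifetimes(0, 3.99), "positive")
})

test_that("excess quenching is supported only beyond the binary limit", {
  d <- rep(3.99, 5)
  b1 <- rep(3.54, 5); b2 <- rep(3.60, 5)
  # ternary equal to the binary minimum: delta = 0, not supported
  r0 <- ternary_excess_quenching(rep(3.54, 5), b1, b2, d)
  expect_equal(r0$delta_ns, 0)
  expect_equal(r0$decision, "not supported")
  # ternary equal to the donor-only set: delta < 0
  r_neg <- ternary_excess_quenching(d, b1, b2, d)
  expect_lt(r_neg$delta_ns, 0)
  expect_equal(r_neg$decision, "not supported")
  # the quenching regime reported for the ternary complex: supported
  set.seed(12)
  r_pos <- ternary_excess_quenching(rnorm(20, 3.40, 0.05),
                                    rnorm(20, 3.54, 0.05),
                                    rnorm(20, 3.54, 0.05),
                                    rnorm(20, 3.99, 0.05))
  expect_equal(r_pos$decision, "supported")
  # population delta is 3.54 - 3.40 = 0.14 ns; allow 0.05 ns absolute for
  # sampling error of the set means (SE ~ 0.011 each) and the min-bias of
  # taking the smaller binary mean
  expect_lt(abs(r_pos$delta_ns - 0.14), 0.05)
  expect_error(ternary_excess_quenching(c(3.4, 3.4), b1, b2, d), "at least 3")
})

test_that("decay CSV round trip preserves the histogram", {
  h <- simulate_decay(3.5, n_photons = 1e4, seed = 3, n_bins = 128)
  dpath <- tempfile(fileext = ".csv"); ipath <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_ns = h$bin_times, counts = h$counts), dpath,
            row.names = FALSE)
  write.csv(data.frame(time_ns = h$bin_times, irf = h$irf), ipath,
            row.names = FALSE)
  h2 <- suppressWarnings(read_decay_csv(dpath, ipath))
  expect_equal(h2$counts, h$counts)
  expect_equal(h2$irf, h$irf, tolerance = 1e-12)
})
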