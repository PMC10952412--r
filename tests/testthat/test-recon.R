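sim_uniform_series <- function(fB_hz, echo_times, r2 = 30, w = 1,
                               d = c(3, 3, 2)) {
  lab <- array(1L, d)
  fx <- toy_anatomy(lab, array(w, d), array(0, d), array(r2, d))
  simulate_echoes(fx$props, array(r2, d), array(fB_hz, d),
                  protocol("custom", echo_times = echo_times))
}

test_that("temporal unwrapping recovers linear phase ramps through wraps", {
  te <- seq_len(5) * 2.3e-3

  # within Nyquist: phases already unwrapped are untouched
  f_small <- 80  # |f| * dTE = 0.18 < 0.5
  true_ph <- 2 * pi * f_small * te
  wrapped <- (true_ph + pi) %% (2 * pi) - pi
  P <- array(rep(wrapped, each = 4), c(2, 2, 1, 5))
  U <- temporal_unwrap(P, te)
  expect_equal(as.vector(U[1, 1, 1, ]), true_ph, tolerance = 1e-10)

  incr <- c(0.3, 0.8, 1.2, 1.6, 2.0)  # increments within (-pi, pi]
  P2 <- array(rep(incr, each = 4), c(2, 2, 1, 5))
  expect_equal(temporal_unwrap(P2, te), P2)

  # fB = 200 Hz with 2.3 ms spacing wraps between echoes
  f_big <- 200
  true_big <- 2 * pi * f_big * te
  wrapped_big <- (true_big + pi) %% (2 * pi) - pi
  expect_false(isTRUE(all.equal(wrapped_big, true_big)))
  P3 <- array(rep(wrapped_big, each = 4), c(2, 2, 1, 5))
  U3 <- temporal_unwrap(P3, te)
  expect_equal(as.vector(U3[2, 2, 1, ]), true_big, tolerance = 1e-10)

  expect_warning(temporal_unwrap(array(1, c(2, 2, 1, 1)), te[1]),
                 "single echo")
})

test_that("multi-echo fieldmap fit is exact on noiseless water-only data", {
  te <- 1.8e-3 + (0:5) * 1.56e-3
  e <- sim_uniform_series(57.3, te)
  fit <- fit_fieldmap(e)
  expect_lt(max(abs(fit$field$field - 57.3)), 1e-6)
  expect_true(all(fit$reliable))

  # constant initial phase, zero field: intercept absorbs the offset
  d <- c(3, 3, 2)
  lab <- array(1L, d)
  fx <- toy_anatomy(lab, array(1, d), array(0, d), array(20, d))
  e0 <- simulate_echoes(fx$props, array(20, d), array(0, d),
                        protocol("custom", echo_times = te),
                        initial_phase = array(0.7, d))
  fit0 <- fit_fieldmap(e0)
  expect_lt(max(abs(fit0$field$field)), 1e-9)
  expect_equal(as.vector(fit0$phi0), rep(0.7, prod(d)), tolerance = 1e-9)

  # all-zero voxel is flagged unreliable with fB = 0
  fx2 <- toy_anatomy(lab, array(0, d), array(0, d), array(0, d))
  ez <- simulate_echoes(fx2$props, array(0, d), array(10, d),
                        protocol("custom", echo_times = te))
  fz <- fit_fieldmap(ez)
  expect_true(all(!fz$reliable))
  expect_true(all(fz$field$field == 0))
})

test_that("fieldmap noise performance improves with echo count", {
  d <- c(10, 10, 2)   # 200 voxels
  lab <- array(1L, d)
  fx <- toy_anatomy(lab, array(1, d), array(0, d), array(40, d))
  f_true <- 23
  rmse <- sapply(c(3, 6), function(K) {
    te <- 1.8e-3 + (0:(K - 1)) * 1.56e-3
    e <- simulate_echoes(fx$props, array(40, d), array(f_true, d),
                         protocol("custom", echo_times = te))
    errs <- sapply(1:20, function(s) {
      ns <- add_complex_noise(e, peak_snr = 100, seed = s)
      fit_fieldmap(ns)$field$field - f_true
    })
    c(bias = mean(errs), rmse = sqrt(mean(errs^2)))
  })
  # bias below the single-estimate noise floor
  expect_lt(abs(rmse["bias", 2]), rmse["rmse", 2])
  # more echoes reduce the error
  expect_lt(rmse["rmse", 2], rmse["rmse", 1])
})

test_that("fidelity weight reduces to magnitude limits and the hand-computed case", {
  d <- c(2, 2, 1)
  lab <- array(1L, d)
  # constant magnitude m across echoes -> W = m
  fx <- toy_anatomy(lab, array(0.8, d), array(0, d), array(0, d))
  e <- simulate_echoes(fx$props, array(0, d), array(5, d),
                       protocol("custom", echo_times = c(1e-3, 2e-3, 3e-3)))
  expect_equal(fidelity_weight(e), array(0.8, d), tolerance = 1e-12)

  # single echo -> W = |S(TE1)|
  e1 <- simulate_echoes(fx$props, array(30, d), array(0, d),
                        protocol("custom", echo_times = 4e-3))
  expect_equal(fidelity_weight(e1), array(0.8 * exp(-30 * 4e-3), d),
               tolerance = 1e-12)

  # magnitudes (2, 1) at TEs (1, 2) ms -> (4*1 + 1*2) / (2*1 + 1*2) = 1.5
  sig <- array(0 + 0i, c(1, 1, 1, 2))
  sig[1, 1, 1, ] <- c(2 + 0i, 1 + 0i)
  e2 <- qsmphantom:::new_echo_series(
    sig, protocol("custom", echo_times = c(1e-3, 2e-3)))
  expect_equal(as.vector(fidelity_weight(e2)), 1.5)

  # zero-magnitude voxel maps to zero weight
  z <- qsmphantom:::new_echo_series(
    array(0 + 0i, c(1, 1, 1, 2)),
    protocol("custom", echo_times = c(1e-3, 2e-3)))
  expect_equal(as.vector(fidelity_weight(z)), 0)
})

test_that("TKD inversion is linear, null-preserving, and inverts a sphere roughly", {
  mask <- array(TRUE, c(16, 16, 16))
  zero <- new_field_map_for_test(array(0, c(16, 16, 16)))
  expect_true(all(tkd_inversion(zero, mask) == 0))

  set.seed(6)
  f <- array(rnorm(16^3), c(16, 16, 16))
  x1 <- tkd_inversion(new_field_map_for_test(f), mask)
  x2 <- tkd_inversion(new_field_map_for_test(3 * f), mask)
  expect_equal(x2, 3 * x1, tolerance = 1e-10)

  expect_error(tkd_inversion(zero, mask, threshold = 0), "threshold")
  expect_error(tkd_inversion(zero, mask, threshold = 0.9), "threshold")

  # forward-then-invert a centered sphere: class-mean error < 20%
  n <- 48; R <- 5
  sp <- sphere_setup(n, R)
  chi <- 0.5 * sp$chi
  fld <- forward_field(chi, kernel_mode = "continuous", b0 = 3,
                       gamma = GAMMA)
  body <- sp$r <= 3 * R
  est <- tkd_inversion(fld, body, threshold = 0.1,
                       kernel_mode = "continuous")
  ref <- demean(chi, body)
  inside <- sp$chi > 0
  expect_lt(abs(mean(est[inside]) - mean(ref[inside])), 0.2 * 0.5)

  # round-trip error decreases monotonically with the threshold
  errs <- sapply(c(0.3, 0.2, 0.1), function(thr) {
    nrmse(tkd_inversion(fld, body, threshold = thr,
                        kernel_mode = "continuous"), ref, body)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("log-linear R2* fitting is exact for water and biased for fat", {
  d <- c(3, 3, 2)
  lab <- array(1L, d)
  te <- 1.8e-3 + (0:5) * 1.56e-3
  fx <- toy_anatomy(lab, array(1, d), array(0, d), array(100, d))
  e <- simulate_echoes(fx$props, array(100, d), array(0, d),
                       protocol("custom", echo_times = te))
  fit <- fit_r2star_loglinear(e)
  expect_equal(fit$r2star, array(100, d), tolerance = 1e-9)
  expect_true(all(fit$reliable))

  # constant magnitude: slope 0
  e0 <- simulate_echoes(fx$props, array(0, d), array(0, d),
                        protocol("custom", echo_times = te))
  expect_true(all(fit_r2star_loglinear(e0)$r2star == 0))

  # fat-containing voxel: spectral modulation biases the estimate
  fxf <- toy_anatomy(lab, array(0.5, d), array(0.5, d), array(100, d))
  ef <- simulate_echoes(fxf$props, array(100, d), array(0, d),
                        protocol("custom", echo_times = te))
  fitf <- fit_r2star_loglinear(ef)
  expect_gt(abs(fitf$r2star[1, 1, 1] - 100), 5)
})
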