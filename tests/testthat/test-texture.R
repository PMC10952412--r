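test_that("normalize_unit rescales to [0, 1] and flags degenerate ranges", {
  v <- array(0, c(3, 1, 1)); v[] <- c(2, 4, 6)
  m <- array(TRUE, c(3, 1, 1))
  expect_equal(as.vector(normalize_unit(v, m)), c(0, 0.5, 1))

  const <- array(5, c(3, 1, 1))
  expect_warning(out <- normalize_unit(const, m), "constant")
  expect_true(all(out == 0))

  # masked-out voxels are zeroed
  m2 <- m; m2[2, 1, 1] <- FALSE
  expect_equal(normalize_unit(v, m2)[2, 1, 1], 0)

  fx <- small_anatomy()
  body <- fx$labels$labels != 0
  n <- normalize_unit(fx$props$r2star_exp, body)
  expect_equal(min(n[body]), 0)
  expect_equal(max(n[body]), 1)
})

test_that("class statistics are whole-mask means of the normalized volumes", {
  lab <- array(1L, c(2, 1, 1)); lab[2, 1, 1] <- 2L
  w <- array(c(0, 1), c(2, 1, 1))
  fx <- toy_anatomy(lab, w, w, array(c(10, 20), c(2, 1, 1)))
  # class 1 normalized water value 0, class 2 value 1 (min-max over body)
  st <- class_statistics(fx$props, fx$labels)
  expect_equal(st$mean_rhoW_norm, c(0, 1))
  expect_equal(st$n_voxels, c(1L, 1L))

  both <- array(1L, c(2, 1, 1))
  fx2 <- toy_anatomy(both, w, w, array(c(10, 20), c(2, 1, 1)))
  st2 <- class_statistics(fx2$props, fx2$labels)
  expect_equal(st2$mean_rhoW_norm, 0.5)

  expect_error(class_statistics(fx$props, fx$labels, class_ids = 7),
               "empty mask")

  big <- small_anatomy()
  stats <- class_statistics(big$props, big$labels)
  cols <- c("mean_r2_norm", "mean_rhoW_norm", "mean_rhoF_norm")
  for (cl in cols) expect_true(all(stats[[cl]] >= 0 & stats[[cl]] <= 1))
})

test_that("per-class susceptibility preserves the assigned class mean exactly", {
  fx <- small_anatomy()
  params <- tissue_parameters("HS")
  stats <- class_statistics(fx$props, fx$labels)

  # modulation off: constant map at the class mean
  flat <- toy_params(5, chi_mean = 0.15)
  chi0 <- synth_susceptibility_class(5, fx$props, stats, flat)
  expect_true(all(chi0 == 0.15))

  # liver with HS texture weights: mean over the liver mask = 0.150 ppm
  chi <- synth_susceptibility_class(5, fx$props, stats, params)
  liver <- fx$labels$labels == 5
  expect_equal(mean(chi[liver]), 0.150, tolerance = 1e-12)

  # every textured class keeps its assigned mean to machine precision
  for (id in intersect(params$class_id, unique(as.integer(fx$labels$labels)))) {
    p <- params[params$class_id == id, ]
    if (p$a_ppm == 0 && p$b_ppm == 0 && p$c_ppm == 0) next
    ci <- synth_susceptibility_class(id, fx$props, stats, params)
    expect_equal(mean(ci[fx$labels$labels == id]), p$chi_mean_ppm,
                 tolerance = 1e-10)
  }
})

test_that("a one-voxel class evaluates to its assigned mean", {
  lab <- array(1L, c(4, 4, 4)); lab[2, 2, 2] <- 2L
  set.seed(11)
  w <- array(runif(64), c(4, 4, 4))
  fx <- toy_anatomy(lab, w, w * 0.5, w * 30)
  stats <- class_statistics(fx$props, fx$labels)
  params <- rbind(toy_params(1, chi_mean = 0.1, a = 0.2, b = 0.3, cc = 0.4),
                  toy_params(2, chi_mean = 0.7, a = 0.2, b = 0.3, cc = 0.4))
  chi <- synth_susceptibility_class(2, fx$props, stats, params)
  expect_equal(chi[2, 2, 2], 0.7)
})

test_that("partial-volume mixing is normalized, convex, and matches a 1D oracle", {
  # single class covering the grid: mixing is the identity
  lab <- array(1L, c(8, 8, 8))
  set.seed(3)
  chi1 <- array(rnorm(512), c(8, 8, 8))
  labels <- qsmphantom:::new_tissue_labels(lab)
  mix1 <- partial_volume_mix(list("1" = chi1), labels, toy_params(1),
                             sigma = 0.5)
  expect_equal(mix1$chi, chi1)

  # two-class 1D step, chi 0 and 1
  n <- 40
  lab2 <- array(1L, c(n, 9, 9))
  lab2[(n / 2 + 1):n, , ] <- 2L
  labels2 <- qsmphantom:::new_tissue_labels(lab2)
  chis <- list("1" = array(0, dim(lab2)), "2" = array(1, dim(lab2)))
  params2 <- rbind(toy_params(1), toy_params(2))

  # sigma = 0: piecewise per-class assembly
  mix0 <- partial_volume_mix(chis, labels2, params2, sigma = 0)
  expect_equal(mix0$chi, (lab2 == 2) * 1)

  mix <- partial_volume_mix(chis, labels2, params2, sigma = 0.5)
  # independent 1D convolution oracle, evaluated away from y/z borders
  r <- ceiling(4 * 0.5)
  kern <- dnorm(seq(-r, r), sd = 0.5); kern <- kern / sum(kern)
  m1 <- as.numeric(seq_len(n) <= n / 2)
  conv1d <- function(m) {
    sapply(seq_len(n), function(i) {
      js <- (i - r):(i + r)
      ok <- js >= 1 & js <= n
      sum(kern[ok] * m[js[ok]])
    })
  }
  s1 <- conv1d(m1); s2 <- conv1d(1 - m1)
  oracle <- s2 / (s1 + s2)
  profile <- mix$chi[, 5, 5]
  expect_equal(profile, oracle, tolerance = 1e-12)
  expect_true(all(diff(profile) >= -1e-12))
  edge <- c(n / 2, n / 2 + 1)
  expect_true(all(profile[edge] > 0 & profile[edge] < 1))
  # convexity: mixed values within the contributing range
  expect_true(all(mix$chi >= 0 & mix$chi <= 1))
})

test_that("mixing weights sum to one at every body voxel of a generated anatomy", {
  fx <- small_anatomy()
  scen <- build_scenario(fx$labels, fx$props, scenario_config("HS"))
  total <- Reduce(`+`, scen$pv_weights)
  expect_equal(max(abs(total / scen$pv_total - 1)), 0)
  expect_true(all(scen$pv_total > 0))
})

test_that("synthetic R2* copies the experimental map unless a class is modified", {
  fx <- small_anatomy()
  stats <- class_statistics(fx$props, fx$labels)
  params <- tissue_parameters("HS")
  r2 <- synth_r2star(fx$props, fx$labels, stats, params)
  expect_identical(r2, fx$props$r2star_exp)

  # modified class with a_r2 = 0: constant assigned mean
  params2 <- params
  params2$modify_r2[params2$class_id == 5] <- 1
  params2$r2_mean_hz[params2$class_id == 5] <- 80
  params2$a_r2_hz[params2$class_id == 5] <- 0
  r2b <- synth_r2star(fx$props, fx$labels, stats, params2)
  liver <- fx$labels$labels == 5
  expect_true(all(r2b[liver] == 80))
  expect_identical(r2b[!liver], fx$props$r2star_exp[!liver])

  # zero-mean texture keeps the assigned mean exactly
  params2$a_r2_hz[params2$class_id == 5] <- 50
  r2c <- synth_r2star(fx$props, fx$labels, stats, params2)
  expect_equal(mean(r2c[liver]), 80, tolerance = 1e-10)

  params2$r2_mean_hz[params2$class_id == 5] <- -5
  expect_error(synth_r2star(fx$props, fx$labels, stats, params2),
               "non-negative")
})

test_that("texture-weight least squares recovers known weights and handles rank deficiency", {
  fx <- small_anatomy()
  stats <- class_statistics(fx$props, fx$labels)
  truth <- c(a = 0.3, b = -0.8, c = 1.1)
  params <- toy_params(5, chi_mean = 0.15, a = truth["a"], b = truth["b"],
                       cc = truth["c"])
  target <- synth_susceptibility_class(5, fx$props, stats, params)
  est <- fit_texture_weights(target, fx$props, stats, fx$labels, 5,
                             chi_mean = 0.15)
  expect_equal(est, truth, tolerance = 1e-8)

  # constant target at the class mean: all-zero weights
  flat <- array(0.15, dim(target))
  est0 <- fit_texture_weights(flat, fx$props, stats, fx$labels, 5,
                              chi_mean = 0.15)
  expect_equal(unname(est0), c(0, 0, 0))

  # duplicated modulators: minimum-norm solution matches the
  # pseudo-inverse oracle and splits the coefficient equally
  props2 <- fx$props
  props2$rhoF_norm <- props2$rhoW_norm
  st2 <- class_statistics(props2, fx$labels)
  m <- fx$labels$labels == 5
  y <- 0.5 * (props2$rhoW_norm[m] - mean(props2$rhoW_norm[m]))
  tgt <- array(0, dim(target)); tgt[m] <- y
  est2 <- fit_texture_weights(tgt, props2, st2, fx$labels, 5, chi_mean = 0)
  X <- cbind(props2$r2_norm[m] - mean(props2$r2_norm[m]),
             props2$rhoW_norm[m] - mean(props2$rhoW_norm[m]),
             props2$rhoF_norm[m] - mean(props2$rhoF_norm[m]))
  oracle <- as.numeric(MASS::ginv(X) %*% y)
  expect_equal(unname(est2), oracle, tolerance = 1e-8)
  expect_equal(est2[["b"]], est2[["c"]], tolerance = 1e-8)
})
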