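test_that("noiseless NMR titration round-trips the true K to 0.1%", {
  ser <- nh_series(5150)
  fit <- fit_nmr_titration(ser)
  expect_equal(fit$K, 5150, tolerance = 1e-3)
  expect_equal(fit$signal_params$delta_free, 8.0, tolerance = 1e-6)
  expect_equal(fit$signal_params$delta_bound, 10.0, tolerance = 1e-4)
  expect_true(fit$fit_diagnostics$converged)
  expect_equal(fit$dG, K_to_free_energy(fit$K))
})

test_that("global fit shares one K across host and guest signals", {
  sc <- nmr_scenario(
    K_true = 800, equivalents = seq(0.5, 12, length.out = 14),
    signals = list(NH = list(owner = "host", delta_free = 8.0, delta_bound = 10.0),
                   CH3 = list(owner = "guest", delta_free = 3.1, delta_bound = 2.6)),
    noise_sd = 0)
  fit <- fit_nmr_titration(generate_nmr_titration(sc))
  expect_equal(fit$K, 800, tolerance = 1e-3)
  expect_equal(nrow(fit$signal_params), 2L)
  expect_equal(fit$signal_params$delta_bound[fit$signal_params$signal == "CH3"],
               2.6, tolerance = 1e-3)
})

test_that("flat titrations are rejected as K-unidentifiable", {
  ser <- titration_series(rep(1.6e-3, 6), seq(0, 8, length.out = 6) * 1.6e-3,
                          data.frame(NH = rep(8.00, 6)), "host")
  expect_error(fit_nmr_titration(ser), "unidentifiable")
  tiny <- titration_series(rep(1.6e-3, 3), c(0, 1e-3, 2e-3),
                           data.frame(NH = c(8, 8.5, 8.8)), "host")
  expect_error(fit_nmr_titration(tiny), "free parameters")
})

test_that("adding a constant offset to one signal changes only that signal's limiting shifts", {
  sc <- nmr_scenario(
    K_true = 2000,
    signals = list(NH = list(owner = "host", delta_free = 8.0, delta_bound = 10.0),
                   CH = list(owner = "host", delta_free = 5.8, delta_bound = 6.3)),
    noise_sd = 0.004, seed = 7)
  ser <- generate_nmr_titration(sc)
  f1 <- fit_nmr_titration(ser)
  ser2 <- ser
  ser2$shifts$CH <- ser2$shifts$CH + 1.5
  f2 <- fit_nmr_titration(ser2)
  expect_equal(f2$K, f1$K, tolerance = 1e-8)
  i <- which(f1$signal_params$signal == "CH")
  expect_equal(f2$signal_params$delta_free[i],
               f1$signal_params$delta_free[i] + 1.5, tolerance = 1e-8)
  j <- which(f1$signal_params$signal == "NH")
  expect_equal(f2$signal_params$delta_free[j], f1$signal_params$delta_free[j],
               tolerance = 1e-8)
})

test_that("fitted K is nearly unbiased across decades at the standard sampling density", {
  for (K in c(1e2, 1e3, 1e4)) {
    Ks <- vapply(1:8, function(s) {
      sc <- nmr_scenario(K_true = K, noise_sd = 0.005, seed = 1000 + s)
      fit_nmr_titration(generate_nmr_titration(sc))$K
    }, 0)
    expect_lt(abs(median(Ks) - K) / K, 0.05)
  }
})

test_that("noiseless ITC thermogram round-trips (K, dH) to 0.1%, with or without floating n", {
  exp0 <- generate_itc(itc_scenario(K_true = 1.41e5, dH_true = -5, noise_sd = 0))
  fit <- fit_itc(exp0)
  expect_equal(fit$K, 1.41e5, tolerance = 1e-3)
  expect_equal(fit$dH, -5, tolerance = 1e-3)
  expect_equal(fit$n, 1)
  expect_true(fit$fit_diagnostics$converged)
  fitn <- fit_itc(exp0, float_n = TRUE)
  expect_equal(fitn$K, 1.41e5, tolerance = 1e-3)
  expect_equal(fitn$n, 1, tolerance = 1e-3)
})

test_that("degenerate ITC inputs are flagged, not silently fitted", {
  exp0 <- generate_itc(itc_scenario(K_true = 1.41e5, noise_sd = 0))
  exp0$heats <- rep(0, length(exp0$heats))
  fit <- fit_itc(exp0)
  expect_false(fit$fit_diagnostics$converged)
  expect_equal(fit$dH, 0)
  expect_true(is.na(fit$K))
  short <- itc_experiment(2e-4, 1.4e-3, 1.4e-3, rep(3e-6, 4), rep(-1e-8, 4))
  expect_error(fit_itc(short), "5 usable")
})

test_that("a poorly conditioned isotherm (c outside 1..1000) triggers a warning", {
  sc <- itc_scenario(K_true = 2e3, dH_true = -5, noise_sd = 0)  # c = 0.4
  exp0 <- generate_itc(sc)
  expect_warning(fit_itc(exp0), "c-parameter")
})

test_that("residual bootstrap is seed-deterministic and consistent with asymptotic errors", {
  sc <- nmr_scenario(K_true = 5150, noise_sd = 0.008, seed = 11)
  fit <- fit_nmr_titration(generate_nmr_titration(sc))
  b1 <- bootstrap_uncertainty(fit, n_boot = 60, seed = 5)
  b2 <- bootstrap_uncertainty(fit, n_boot = 60, seed = 5)
  expect_identical(b1, b2)
  # same order of magnitude as the covariance-based error (factor of 2)
  ratio <- b1$K_sigma / fit$K_sigma
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  expect_error(bootstrap_uncertainty(fit, n_boot = 5), "n_boot")
})

test_that("bootstrap on noiseless data collapses to zero spread", {
  fit <- fit_nmr_titration(nh_series(5150))
  b <- bootstrap_uncertainty(fit, n_boot = 20, seed = 1)
  expect_lt(b$K_sigma / fit$K, 1e-4)
})
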