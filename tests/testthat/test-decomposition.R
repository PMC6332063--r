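const <- thermo_constants()
br <- function(host, guest, K, sigma = 0) {
  calixchpi:::binding_result(host, guest, K = K, K_sigma = sigma,
                             method = "NMR", const = const)
}

test_that("double-difference energies recompute the tabulated CH-pi values from the constants", {
  d1e <- delta_delta_G(br("1e", "2a", 1.41e5), br("1a", "2a", 72.2))
  expect_equal(round(-d1e$ddG, 2), 4.49)
  d1b <- delta_delta_G(br("1b", "2b", 82.1), br("1a", "2b", 8.91))
  expect_equal(round(-d1b$ddG, 2), 1.32)
  same <- delta_delta_G(br("1a", "2a", 72.2), br("1a", "2a", 72.2))
  expect_equal(same$ddG, 0)
})

test_that("ddG is antisymmetric and combines uncertainties in quadrature", {
  a <- br("1e", "2a", 1.41e5, 1e4)
  b <- br("1a", "2a", 72.2, 14)
  fwd <- delta_delta_G(a, b)
  rev <- delta_delta_G(b, a)
  expect_equal(fwd$ddG, -rev$ddG)
  expect_equal(fwd$ddG_sigma, sqrt(a$dG_sigma^2 + b$dG_sigma^2))
  expect_error(delta_delta_G(br("1e", "2a", 1.41e5), br("1a", "2b", 8.91)),
               "guest mismatch")
})

test_that("per-contact energy is an exact division, including the four-wall mean case", {
  expect_equal(per_contact_energy(4.4, 4), 1.1)
  expect_equal(per_contact_energy(0, 4), 0)
  expect_equal(per_contact_energy(3.0, 2), 1.5)
  expect_error(per_contact_energy(4.4, 0), "n_contacts")
  # mean four-wall magnitude for the N-oxide guest, recomputed from K
  ddg <- vapply(c("1e" = 1.41e5, "1f" = 1.06e5), function(K) {
    -delta_delta_G(br("x", "2a", K), br("1a", "2a", 72.2))$ddG
  }, 0)
  expect_equal(round(mean(ddg), 1), 4.4)
  expect_equal(round(mean(ddg) / 4, 1), 1.1)
})

test_that("the pseudo-Hammett regression matches closed-form OLS and flags degeneracy", {
  esp <- c(-20.7, -12.9, -2.0)
  y <- c(2.51, 2.36, 2.52)
  lf <- lfer_regression(esp, y)
  slope_cf <- sum((esp - mean(esp)) * (y - mean(y))) / sum((esp - mean(esp))^2)
  expect_equal(lf$slope, slope_cf, tolerance = 1e-12)
  expect_lt(abs(lf$slope), 0.02)
  expect_gt(lf$p_slope, 0.05)
  # two points: exact interpolation
  lf2 <- lfer_regression(c(-20.7, -2.0), c(2.51, 2.52))
  expect_equal(lf2$slope, (2.52 - 2.51) / (-2.0 + 20.7))
  expect_true(is.na(lf2$p_slope))
  # constant response
  lf3 <- lfer_regression(esp, c(2.4, 2.4, 2.4))
  expect_equal(lf3$slope, 0)
  expect_equal(lf3$intercept, 2.4)
  expect_error(lfer_regression(c(-2, -2, -2), y), "rank-deficient")
  # inverse-variance weighting is accepted and changes nothing for equal sigmas
  lfw <- lfer_regression(esp, y, ddG_sigma = rep(0.1, 3), weighted = TRUE)
  expect_equal(lfw$slope, lf$slope, tolerance = 1e-12)
})

test_that("the assembled binding table reproduces all printed free energies to 2 dp", {
  tab <- reproduce_table1()
  expect_equal(nrow(tab), 12L)
  expect_equal(round(tab$minus_dG, 2), tab$minus_dG_printed)
  # -dG column for the N-oxide guest in host order
  g2a <- tab[tab$guest_id == "2a", ]
  expect_equal(round(g2a$minus_dG, 2), c(2.53, 5.06, 4.89, 5.01, 7.02, 6.85))
  # four-wall CH-pi energies for 2a are nearly double the two-wall ones
  expect_gt(min(g2a$minus_ddG[g2a$n_walls == 4]),
            max(g2a$minus_ddG[g2a$n_walls == 2]))
  expect_gt(min(g2a$minus_ddG[g2a$n_walls == 4]) /
              max(g2a$minus_ddG[g2a$n_walls == 2]), 1.7)
})

test_that("build_table1 is order-insensitive and demands a reference per guest", {
  scen <- study_scenarios()
  fits <- lapply(scen, function(sc) br(sc$host_id, sc$guest_id, sc$K_true))
  hosts <- lapply(unique(vapply(scen, `[[`, "", "host_id")), function(h) {
    sc <- scen[[which(vapply(scen, `[[`, "", "host_id") == h)[1]]]
    host_record(h, sc$n_walls, sc$esp, sc$substituent)
  })
  t1 <- build_table1(unname(fits), hosts)
  set.seed(1)
  t2 <- build_table1(unname(fits)[sample(length(fits))], rev(hosts))
  expect_identical(t1, t2)
  # reference-only input: empty ddG column
  solo <- build_table1(list(br("1a", "2a", 72.2)),
                       list(host_record("1a", 0)))
  expect_true(all(is.na(solo$minus_ddG)))
  # dropping the reference for one guest names it
  no_ref <- unname(fits)[!(vapply(fits, `[[`, "", "host_id") == "1a" &
                             vapply(fits, `[[`, "", "guest_id") == "2b")]
  expect_error(build_table1(no_ref, hosts), "2b")
})
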