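# Transfer-matrix optics: magnet conversions, element matrices, Twiss
# propagation and quadrupole-scan reconstruction.

test_that("magnet conversions follow the excitation and rigidity relations", {
  expect_equal(current_to_gradient(1), 0.057)
  expect_equal(current_to_gradient(0), 0)
  expect_equal(current_to_gradient(240), 13.68)
  expect_equal(current_to_gradient(-10), -0.57)  # sign preserved

  expect_equal(gradient_to_K(1, 300), 1)
  expect_equal(gradient_to_K(0, 150), 0)
  expect_equal(gradient_to_K(13.68, 201), 300 * 13.68 / 201)
  # round trip
  expect_equal(K_to_gradient(gradient_to_K(7.3, 201), 201), 7.3)

  expect_error(current_to_gradient(NaN), class = "vhee_invalid_argument")
  expect_error(gradient_to_K(1, 0), class = "vhee_invalid_argument")
  expect_error(gradient_to_K(1, -5), class = "vhee_invalid_argument")
})

test_that("quadrupole and drift matrices have the closed forms and unit determinant", {
  # drift limit of the quad
  expect_equal(unclass(quad_transfer(0, 0.25, "x")),
               matrix(c(1, 0, 0.25, 1), 2, 2))
  expect_equal(unclass(drift_transfer(0)), diag(2))
  expect_equal(drift_transfer(0.25)[1, 2], 0.25)

  # thick-lens closed form in the focusing plane
  M <- quad_transfer(20.42, 0.226, "x")
  w <- sqrt(20.42)
  expect_equal(M[1, 1], cos(w * 0.226))
  expect_equal(M[1, 2], sin(w * 0.226) / w)
  expect_equal(M[2, 1], -w * sin(w * 0.226))
  # defocusing plane of the same magnet
  My <- quad_transfer(20.42, 0.226, "y")
  expect_equal(My[1, 1], cosh(w * 0.226))

  # symplecticity across sign, plane and strength
  for (K in c(-25, -3, 0, 1e-12, 4, 22)) {
    for (pl in c("x", "y")) {
      expect_lt(abs(det(quad_transfer(K, 0.3, pl)) - 1), 1e-9)
    }
  }
  # K -> 0 converges elementwise to the drift
  expect_equal(unclass(quad_transfer(1e-12, 0.4, "x")),
               unclass(drift_transfer(0.4)), tolerance = 1e-9)

  expect_error(drift_transfer(-0.1), class = "vhee_invalid_argument")
  expect_error(quad_transfer(5, 0, "x"), class = "vhee_invalid_argument")
})

test_that("composition is ordered, additive for drifts, and reaches the thin-lens limit", {
  M <- quad_transfer(7, 0.2, "x")
  expect_equal(unclass(compose_transfer(list(diag(2), M))), unclass(M))
  expect_equal(unclass(compose_transfer(list(M, solve(M)))), diag(2),
               tolerance = 1e-12)
  expect_equal(unclass(compose_transfer(list(drift_transfer(0.3),
                                             drift_transfer(0.45)))),
               unclass(drift_transfer(0.75)))
  # thin-lens limit: K*L = 1/f fixed, L -> 0
  f <- 0.5
  Mthin <- quad_transfer(1 / (f * 1e-4), 1e-4, "x")
  expect_equal(Mthin[2, 1], -1 / f, tolerance = 1e-4)
  expect_equal(Mthin[1, 1], 1, tolerance = 1e-4)
  expect_error(compose_transfer(list()), class = "vhee_invalid_argument")
})

test_that("Twiss propagation matches drift closed forms and conserves emittance", {
  tw <- twiss(alpha = 0, beta = 2, emittance = 5e-8)
  expect_equal(propagate_twiss(tw, diag(2))$beta, 2)
  # beta(L) = beta0 + L^2/beta0 through a drift from a waist
  out <- propagate_twiss(tw, drift_transfer(3))
  expect_equal(out$beta, 2 + 9 / 2)
  # general drift formula beta(s) = b0 - 2 a0 s + g0 s^2
  tw2 <- twiss(alpha = 0.7, beta = 4, emittance = 1e-7)
  out2 <- propagate_twiss(tw2, drift_transfer(1.3))
  expect_equal(out2$beta, 4 - 2 * 0.7 * 1.3 + tw2$gamma * 1.3^2)
  # emittance invariant under arbitrary symplectic maps
  for (K in c(-9, 3, 17)) {
    expect_equal(propagate_twiss(tw2, quad_transfer(K, 0.3, "y"))$emittance,
                 1e-7)
  }
  expect_equal(beam_sigma(twiss(0, 1, 1e-6)), 1e-3)
  expect_equal(beam_sigma(twiss(0, 2, 1e-6)) / beam_sigma(twiss(0, 1, 1e-6)),
               sqrt(2))
})

test_that("twiss constructor validates its domain", {
  expect_error(twiss(0, -1, 1e-8), class = "vhee_invalid_argument")
  expect_error(twiss(0, 1, -1e-8), class = "vhee_invalid_argument")
  expect_equal(twiss(1.5, 2, 1e-8)$gamma, (1 + 1.5^2) / 2)
})

test_that("quad-scan reconstruction inverts the synthetic forward model", {
  geom <- list(quad_length = 0.226, drift = 1.5)
  truth <- twiss(alpha = 0.5, beta = 2, emittance = 5e-8)
  for (plane in c("x", "y")) {
    sc <- gen_quad_scan_data(truth, geom, seq(-10, 10, length.out = 9),
                             plane = plane)
    rec <- twiss_from_quad_scan(sc, geom)
    expect_equal(rec$alpha, truth$alpha, tolerance = 1e-6)
    expect_equal(rec$beta, truth$beta, tolerance = 1e-6)
    expect_equal(rec$emittance, truth$emittance, tolerance = 1e-6)
  }
})

test_that("quad-scan reconstruction degrades gracefully", {
  geom <- list(quad_length = 0.226, drift = 1.5)
  truth <- twiss(0.5, 2, 5e-8)
  two <- gen_quad_scan_data(truth, geom, c(-5, 0, 5))[1:2, ]
  expect_error(twiss_from_quad_scan(two, geom),
               class = "vhee_underdetermined_fit")
  # repeated strengths are degenerate even if n >= 3
  rep3 <- gen_quad_scan_data(truth, geom, c(4, 4, 4))
  expect_error(twiss_from_quad_scan(rep3, geom),
               class = "vhee_underdetermined_fit")
  # 1% noise, 20 points: recovery within 5% (seeded)
  noisy <- gen_quad_scan_data(truth, geom, seq(-10, 10, length.out = 20),
                              noise_rel = 0.01, seed = 7)
  rec <- twiss_from_quad_scan(noisy, geom)
  expect_lt(abs(rec$beta / truth$beta - 1), 0.05)
  expect_lt(abs(rec$emittance / truth$emittance - 1), 0.05)
  expect_lt(abs(rec$alpha - truth$alpha), 0.05 * (1 + abs(truth$alpha)))
})
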