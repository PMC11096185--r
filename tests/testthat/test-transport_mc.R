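# Monte Carlo transport: bunch sampling, scattering model, collimation and
# the equivalence with matrix optics in vacuum.

test_that("sampled bunches reproduce the Twiss moments and are seed-reproducible", {
  twx <- twiss(0, 5, 5e-8)
  twy <- twiss(0.8, 3, 2e-8)
  b <- sample_bunch(twx, twy, 201, 2, 1e5, seed = 42)
  expect_equal(sd(b$x), beam_sigma(twx), tolerance = 0.02)
  expect_equal(sd(b$y), beam_sigma(twy), tolerance = 0.02)
  expect_equal(sd(b$xp), sqrt(twx$emittance * twx$gamma), tolerance = 0.02)
  # correlation <y y'> = -emittance * alpha
  expect_lt(abs(mean(b$y * b$yp) - (-twy$emittance * twy$alpha)),
            0.05 * twy$emittance)
  expect_equal(sd(b$energy), 2, tolerance = 0.02)
  b2 <- sample_bunch(twx, twy, 201, 2, 1e5, seed = 42)
  expect_identical(b$x, b2$x)
  expect_identical(b$energy, b2$energy)
  b0 <- sample_bunch(twx, twy, 201, 0, 100, seed = 1)
  expect_true(all(b0$energy == 201))
  expect_error(sample_bunch(twx, twy, 201, 2, 0), class = "vhee_invalid_argument")
})

test_that("scatter_step matches the Highland formula and is ballistic in vacuum", {
  b <- sample_bunch(twiss(0, 1, 1e-18), twiss(0, 1, 1e-18), 201, 0, 4e4,
                    seed = 5)
  v <- scatter_step(b, material("vacuum"), 0.1)
  expect_equal(v$x, b$x + 0.1 * b$xp)
  expect_equal(v$xp, b$xp)
  expect_equal(v$energy, b$energy)

  set.seed(11)
  s <- scatter_step(b, material("water"), 0.12)
  th0 <- vheefocus:::highland_theta0(201, 0.12, material("water")$radiation_length_cm)
  se <- th0 / sqrt(2 * 4e4)  # standard error of an rms over n samples
  expect_lt(abs(sd(s$xp) - th0), 3 * se)
  expect_lt(abs(sd(s$yp) - th0), 3 * se)
  # displacement variance dz^2 theta0^2 / 3 and correlation sqrt(3)/2
  expect_equal(sd(s$x), 0.12 * th0 / sqrt(3), tolerance = 0.05)
  expect_equal(cor(s$x, s$xp), sqrt(3) / 2, tolerance = 0.05)
  # energy reduced by collisional + radiative loss
  expect_lt(max(s$energy), 201)
  expect_error(scatter_step(b, material("water"), 0),
               class = "vhee_invalid_argument")
})

test_that("two half steps accumulate the variance of one full step", {
  b <- sample_bunch(twiss(0, 1, 1e-18), twiss(0, 1, 1e-18), 201, 0, 4e4,
                    seed = 6)
  set.seed(21)
  one <- scatter_step(b, material("water"), 0.06)
  set.seed(22)
  half <- scatter_step(scatter_step(b, material("water"), 0.03),
                       material("water"), 0.03)
  # angular variances agree within stochastic tolerance (3 combined SEs)
  v1 <- var(one$xp); v2 <- var(half$xp)
  se <- sqrt(2 / 4e4) * (v1 + v2) / 2 * sqrt(2)
  expect_lt(abs(v1 - v2), 3 * se + 0.1 * v1)  # log-term subdivision bias < 10%
})

test_that("circular aperture absorbs at and beyond the boundary", {
  st <- list(x = c(0, 0.019, 0.02, 0.015, -0.025), y = c(0, 0, 0, 0.015, 0),
             xp = numeric(5), yp = numeric(5), energy = rep(201, 5),
             alive = rep(TRUE, 5))
  out <- apply_aperture(st, 0.02)
  expect_equal(out$alive, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(apply_aperture(st, 0), class = "vhee_invalid_argument")
})

test_that("aperture survival matches the bivariate Gaussian mass oracle", {
  sig <- 0.02
  b <- sample_bunch(twiss(0, 1, sig^2), twiss(0, 1, sig^2), 201, 0, 1e5,
                    seed = 9)
  out <- apply_aperture(b, 0.02)
  # circularly symmetric Gaussian: P(r < R) = 1 - exp(-R^2 / (2 sig^2))
  p <- 1 - exp(-0.02^2 / (2 * sig^2))
  expect_equal(mean(out$alive), p, tolerance = 0.01)
})

test_that("vacuum transport equals per-particle matrix optics to 1e-9", {
  bl <- vacuum_test_line(K = c(10, -12, 8))
  b <- sample_bunch(bl$beam$twiss_x, bl$beam$twiss_y, 201, 2, 150, seed = 3)
  res <- transport_bunch(b, bl, score = FALSE)
  oracle <- matrix_track_oracle(b, bl)
  expect_lt(max(abs(res$bunch$x - oracle$x)), 1e-9)
  expect_lt(max(abs(res$bunch$xp - oracle$xp)), 1e-9)
  expect_lt(max(abs(res$bunch$y - oracle$y)), 1e-9)
  expect_lt(max(abs(res$bunch$yp - oracle$yp)), 1e-9)
})

test_that("with quads off, vacuum transport is a free drift", {
  bl <- vacuum_test_line(K = c(0, 0, 0))
  b <- sample_bunch(bl$beam$twiss_x, bl$beam$twiss_y, 201, 0, 50, seed = 4)
  L <- beamline_length(bl)
  res <- transport_bunch(b, bl, score = FALSE)
  expect_equal(res$bunch$x, b$x + L * b$xp, tolerance = 1e-12)
  expect_equal(res$bunch$yp, b$yp)
})

test_that("rms envelope through a vacuum lattice follows propagate_twiss", {
  bl <- vacuum_test_line(K = c(6, -7, 5),
                         beam = list(energy_MeV = 201,
                                     energy_spread_rms_MeV = 0,
                                     twiss_x = twiss(0, 10, 2e-8),
                                     twiss_y = twiss(0, 10, 2e-8)))
  b <- sample_bunch(bl$beam$twiss_x, bl$beam$twiss_y, 201, 0, 1e5, seed = 8)
  res <- transport_bunch(b, bl, mc_settings(record_envelope = TRUE),
                         score = FALSE)
  # prediction at the beamline end
  mats_x <- list(); mats_y <- list()
  for (el in bl$elements) {
    if (el$kind == "quad" && abs(el$K) > 0) {
      mats_x <- c(mats_x, list(quad_transfer(el$K, el$length, "x")))
      mats_y <- c(mats_y, list(quad_transfer(el$K, el$length, "y")))
    } else {
      mats_x <- c(mats_x, list(drift_transfer(el$length)))
      mats_y <- c(mats_y, list(drift_transfer(el$length)))
    }
  }
  sx_pred <- beam_sigma(propagate_twiss(bl$beam$twiss_x,
                                        compose_transfer(mats_x)))
  sy_pred <- beam_sigma(propagate_twiss(bl$beam$twiss_y,
                                        compose_transfer(mats_y)))
  tailrow <- res$envelope[nrow(res$envelope), ]
  expect_lt(abs(tailrow$sigma_x_m - sx_pred), 3 * sx_pred / sqrt(2 * 1e5))
  expect_lt(abs(tailrow$sigma_y_m - sy_pred), 3 * sy_pred / sqrt(2 * 1e5))
})

test_that("pencil-beam spread in water matches the Fermi-Eyges moment oracle", {
  bl <- water_slab_line(0.12)
  b <- sample_bunch(bl$beam$twiss_x, bl$beam$twiss_y, 201, 0, 1e5, seed = 11)
  res <- transport_bunch(b, bl, mc_settings(record_envelope = TRUE),
                         score = FALSE)
  pred <- fermi_eyges_oracle_sigma(12)
  got <- res$envelope$sigma_x_m[nrow(res$envelope)]
  expect_lt(abs(got - pred), 3 * pred / sqrt(2 * 1e5))
})

test_that("energy deposited in the phantom never exceeds the energy carried in", {
  bl <- build_beamline("compact", pipe_radius_cm = 4)
  bl <- set_quad_K(bl, c(12, -14, 10, -11, 13))
  b <- sample_bunch(bl$beam$twiss_x, bl$beam$twiss_y, 201, 2, 2e4, seed = 12)
  res <- transport_bunch(b, bl)
  expect_true(all(res$dose$deposit >= 0))
  expect_lt(sum(res$dose$deposit), res$dose$energy_in_MeV)
  expect_gt(sum(res$dose$deposit), 0)
})

test_that("shrinking the beampipe never increases survival", {
  sol_K <- c(12, -14, 10, -11, 13)
  alive <- sapply(c(1.9, 3.9, 6.9), function(r) {
    bl <- set_quad_K(build_beamline("compact", pipe_radius_cm = r), sol_K)
    b <- sample_bunch(bl$beam$twiss_x, bl$beam$twiss_y, 201, 2, 2e4,
                      seed = 13)
    transport_bunch(b, bl, score = FALSE)$n_alive
  })
  expect_true(all(diff(alive) >= 0))
})

test_that("full polarity inversion swaps the x/y envelope histories exactly", {
  bl <- vacuum_test_line(K = c(9, -11, 7), pipe_radius = 0.03)
  b <- sample_bunch(twiss(0, 10, 2e-8), twiss(0, 10, 2e-8), 201, 2, 5e3,
                    seed = 14)
  res1 <- transport_bunch(b, bl, mc_settings(record_envelope = TRUE),
                          score = FALSE)
  # mirrored bunch through the polarity-inverted lattice
  bsw <- b
  bsw$x <- b$y; bsw$xp <- b$yp; bsw$y <- b$x; bsw$yp <- b$xp
  bl2 <- invert_polarity(bl, last_n = length(quad_indices(bl)))
  res2 <- transport_bunch(bsw, bl2, mc_settings(record_envelope = TRUE),
                          score = FALSE)
  expect_equal(res2$envelope$sigma_x_m, res1$envelope$sigma_y_m,
               tolerance = 1e-12)
  expect_equal(res2$envelope$sigma_y_m, res1$envelope$sigma_x_m,
               tolerance = 1e-12)
  expect_identical(res2$envelope$n_alive, res1$envelope$n_alive)
})
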