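# Film dosimetry: optical density, calibration fitting, dose maps,
# maximum localisation, HWHM and uncertainty combination.

red_params <- c(a = 5.05, b = 82.86, c = -5.08)  # red-channel reference fit

test_that("optical density follows the log ratio", {
  expect_equal(optical_density(48000, 48000), 0)
  expect_equal(optical_density(4800, 48000), 1)
  expect_equal(optical_density(30000, 60000), log10(2))
  expect_equal(optical_density(c(1, 10), c(10, 10)), c(1, 0))
  expect_error(optical_density(0, 100), class = "vhee_invalid_argument")
  expect_error(optical_density(100, -1), class = "vhee_invalid_argument")
})

test_that("calibration fit recovers generating parameters on noiseless data", {
  doses <- c(0.5, 1, 2, 4, 8, 12, 20, 30, 40)
  cal <- gen_calibration_set(red_params["a"], red_params["b"],
                             red_params["c"], doses)
  cv <- fit_calibration(cal)
  expect_equal(cv$a, unname(red_params["a"]), tolerance = 1e-6)
  expect_equal(cv$b, unname(red_params["b"]), tolerance = 1e-6)
  expect_equal(cv$c, unname(red_params["c"]), tolerance = 1e-6)
  expect_lt(cv$reduced_chi2, 1e-12)
  expect_gt(cv$adjusted_R2, 1 - 1e-9)
  # query at OD = 0 gives a + c
  expect_equal(dose_from_od(cv, 0), cv$a + cv$c, ignore_attr = TRUE)
  expect_equal(dose_from_od(cv, 1), cv$a * cv$b + cv$c, ignore_attr = TRUE)
  expect_error(fit_calibration(cal[1:3, ]),
               class = "vhee_underdetermined_fit")
})

test_that("calibration fit stays close under seeded noise", {
  doses <- seq(0.5, 40, length.out = 15)
  cal <- gen_calibration_set(5.05, 82.86, -5.08, doses, noise_rel = 0.01,
                             seed = 31)
  cv <- fit_calibration(cal)
  # doses back out within a few percent across the fitted range
  d_hat <- dose_from_od(cv, od_from_dose(list(a = 5.05, b = 82.86, c = -5.08),
                                         doses))
  expect_lt(max(abs(d_hat - doses) / doses), 0.15)
})

test_that("dose_from_od is monotone and flags extrapolation", {
  cal <- gen_calibration_set(5.05, 82.86, -5.08, c(0.5, 1, 5, 10, 20, 40))
  cv <- fit_calibration(cal)
  od <- seq(cv$od_range[1], cv$od_range[2], length.out = 50)
  expect_true(all(diff(dose_from_od(cv, od)) > 0))
  flagged <- attr(dose_from_od(cv, c(-1, od[25], 99)), "extrapolated")
  expect_equal(flagged, c(TRUE, FALSE, TRUE))
})

test_that("channel policy flags a markedly worse channel", {
  doses <- seq(0.5, 40, length.out = 12)
  mk <- function(ch, noise, seed) {
    g <- gen_calibration_set(5.05, 82.86, -5.08, doses, noise_rel = noise,
                             seed = seed)
    data.frame(channel = ch, OD = g$OD, dose_Gy = g$dose_Gy)
  }
  tab <- rbind(mk("red", 0.002, 1), mk("green", 0.002, 2),
               mk("blue", 0.08, 3))
  curves <- fit_calibration_channels(tab)
  expect_setequal(names(curves), c("red", "green", "blue"))
  expect_true("blue" %in% attr(curves, "flagged"))
  expect_false("red" %in% attr(curves, "flagged"))
})

test_that("maximum localisation finds a Gaussian centre and ignores rescaling", {
  m <- gaussian_dose_map(r0 = 71, c0 = 44, sigma_px = 15)
  dm <- dose_map(m, pitch_mm = 25.4 / 300)
  at <- locate_max_dose(dm)
  expect_lte(abs(at["row"] - 71), 1)
  expect_lte(abs(at["col"] - 44), 1)
  at2 <- locate_max_dose(dose_map(m * 1e3, pitch_mm = 25.4 / 300))
  # invariant under global rescaling (up to plateau ties on symmetric spots)
  expect_true(all(abs(as.integer(at2) - as.integer(at)) <= 1))
  expect_error(locate_max_dose(dose_map(matrix(0, 20, 20), 0.1)),
               class = "vhee_no_signal")
})

test_that("maximum localisation converges quickly on unimodal maps and tie-breaks low", {
  set.seed(40)
  for (k in 1:5) {
    m <- gaussian_dose_map(nrow = 256, ncol = 256,
                           r0 = sample(40:216, 1), c0 = sample(40:216, 1),
                           sigma_px = runif(1, 8, 40))
    at <- locate_max_dose(dose_map(m, 0.1), max_iter = 10)
    expect_true(all(is.finite(at)))
  }
  # two exactly equal maxima: the lowest linear index wins
  m2 <- matrix(1, 30, 30)
  m2[10, 10] <- 5; m2[20, 20] <- 5
  at <- locate_max_dose(dose_map(m2, 0.1), window = 1)
  expect_equal(as.integer(at), c(10L, 10L))
})

test_that("profile HWHM matches the Gaussian closed form and top-hat width", {
  sigma_px <- 10
  m <- gaussian_dose_map(r0 = 60, c0 = 60, sigma_px = sigma_px)
  dm <- dose_map(m, pitch_mm = 25.4 / 300)
  at <- locate_max_dose(dm)
  hw <- hwhm_from_profile(dm, at, "x")
  expect_lt(abs(hw - sqrt(2 * log(2)) * sigma_px * 25.4 / 300), 0.1)
  # unbiased within half a pixel across a range of widths
  for (s in c(3, 8, 18, 30)) {
    mm <- gaussian_dose_map(nrow = 220, ncol = 220, r0 = 110, c0 = 110,
                            sigma_px = s)
    dmm <- dose_map(mm, pitch_mm = 1)
    hws <- hwhm_from_profile(dmm, c(110, 110), "y")
    expect_lt(abs(hws - sqrt(2 * log(2)) * s), 0.5)
  }
  # top-hat of half-width 7 px at 1 mm pitch
  th <- matrix(0, 50, 50); th[25, 18:32] <- 1; th[24:26, ] <- th[rep(25, 3), ]
  hw_th <- hwhm_from_profile(dose_map(th, 1), c(25, 25), "x")
  expect_equal(hw_th, 7.5, tolerance = 0.1)
  flat <- dose_map(matrix(1, 20, 20), 1)
  expect_error(hwhm_from_profile(flat, c(10, 10), "x"),
               class = "vhee_unresolved_width")
})

test_that("patch average agrees with the smoothed maximum on broad spots", {
  dm <- dose_map(matrix(7, 40, 40), 1)
  chk <- patch_average_check(dm, c(20, 20))
  expect_equal(chk$percent_diff, 0)
  broad <- dose_map(gaussian_dose_map(nrow = 200, ncol = 200, r0 = 100,
                                      c0 = 100, sigma_px = 50), 1)
  chk2 <- patch_average_check(broad, c(100, 100))
  expect_lt(chk2$percent_diff, 1)
  # narrow spike: a lightly smoothed maximum disagrees with the raw
  # 10 x 10 block mean, flagging non-representative maxima
  spike <- dose_map(gaussian_dose_map(nrow = 60, ncol = 60, r0 = 30,
                                      c0 = 30, sigma_px = 2), 1)
  expect_gt(patch_average_check(spike, c(30, 30), window = 3)$percent_diff,
            5)
  expect_error(patch_average_check(dm, c(2, 2)),
               class = "vhee_invalid_argument")
})

test_that("uncertainty components combine in quadrature", {
  expect_equal(combine_uncertainty_quadrature(c(3, 4))$percent, 5)
  expect_equal(combine_uncertainty_quadrature(7.3)$percent, 7.3)
  q <- combine_uncertainty_quadrature(c(4, 3.5, 0.6))
  expect_equal(q$percent, sqrt(4^2 + 3.5^2 + 0.6^2))
  expect_equal(q$percent, 5.3488, tolerance = 1e-4)
  expect_equal(q$rounded, 5)
  expect_error(combine_uncertainty_quadrature(c(3, -1)),
               class = "vhee_invalid_argument")
})
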