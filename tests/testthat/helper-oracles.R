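# Shared fixtures and independent oracles used across the test files.

# an all-vacuum lattice (quads + drifts + vacuum phantom) for tests that
# compare the Monte Carlo against exact matrix optics
vacuum_test_line <- function(K = c(10, -12, 8), pipe_radius = NA_real_,
                             quad_len = 0.2, drift_len = 0.3,
                             phantom_len = 0.2, beam = NULL) {
  els <- list()
  for (i in seq_along(K)) {
    els <- c(els, list(
      beamline_element("quad", quad_len, "vacuum", K = K[i],
                       polarity = sign(K[i]) + (K[i] == 0),
                       pipe_radius = pipe_radius),
      beamline_element("drift", drift_len, "vacuum",
                       pipe_radius = pipe_radius)
    ))
  }
  els <- c(els, list(beamline_element("phantom", phantom_len, "vacuum",
                                      half_x = 0.5, half_y = 0.5)))
  if (is.null(beam)) {
    beam <- list(energy_MeV = 201, energy_spread_rms_MeV = 2,
                 twiss_x = twiss(0, 10, 2e-8), twiss_y = twiss(0.3, 8, 3e-8))
  }
  vheefocus:::new_beamline(els, beam, name = "vacuum-test")
}

# water-slab-only beamline (pencil-beam scattering studies)
water_slab_line <- function(length_m = 0.12, medium = "water",
                            energy = 201, spread = 0, eps = 1e-18) {
  vheefocus:::new_beamline(
    list(beamline_element("phantom", length_m, medium,
                          half_x = 0.25, half_y = 0.25)),
    list(energy_MeV = energy, energy_spread_rms_MeV = spread,
         twiss_x = twiss(0, 1, eps), twiss_y = twiss(0, 1, eps)))
}

# independent per-particle matrix-optics oracle: track (u, u') through the
# lattice with closed-form 2x2 maps, using the same chromatic K scaling
matrix_track_oracle <- function(bunch, beamline) {
  E0 <- bunch$energy_nominal
  n <- bunch$n
  out <- list(x = numeric(n), xp = numeric(n),
              y = numeric(n), yp = numeric(n))
  for (i in seq_len(n)) {
    sx <- c(bunch$x[i], bunch$xp[i])
    sy <- c(bunch$y[i], bunch$yp[i])
    for (el in beamline$elements) {
      if (el$length <= 0) next
      if (el$kind == "quad" && abs(el$K) > 1e-30) {
        Keff <- el$K * E0 / bunch$energy[i]
        sx <- quad_transfer(Keff, el$length, "x") %*% sx
        sy <- quad_transfer(Keff, el$length, "y") %*% sy
      } else {
        sx <- drift_transfer(el$length) %*% sx
        sy <- drift_transfer(el$length) %*% sy
      }
    }
    out$x[i] <- sx[1]; out$xp[i] <- sx[2]
    out$y[i] <- sy[1]; out$yp[i] <- sy[2]
  }
  out
}

# Fermi-Eyges discrete moment oracle for a pencil beam in a uniform medium:
# accumulates the per-step Highland variance contributions analytically,
# with the same CSDA energy degradation the transport applies
fermi_eyges_oracle_sigma <- function(depth_cm, E0 = 201, medium = "water",
                                     step_cm = 0.1) {
  mat <- material(medium)
  n <- round(depth_cm / step_cm)
  dz_m <- step_cm / 100
  E <- E0
  v <- 0
  zend <- n * dz_m
  for (k in seq_len(n)) {
    th2 <- vheefocus:::highland_theta0(E, dz_m, mat$radiation_length_cm)^2
    R <- zend - k * dz_m
    v <- v + th2 * (dz_m^2 / 3 + R * dz_m + R^2)
    E <- E - mat$stopping_power_MeV_cm * step_cm -
      E * step_cm / mat$radiation_length_cm
  }
  sqrt(v)
}

# planar Gaussian dose spot (rows = y, cols = x), peak dose in Gy
gaussian_dose_map <- function(nrow = 120, ncol = 120, r0 = 60, c0 = 60,
                              sigma_px = 12, peak = 20) {
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  peak * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma_px^2))
}
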