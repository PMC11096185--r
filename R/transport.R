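# Condensed-history Monte Carlo transport of an electron bunch through a
# magnet lattice, with multiple Coulomb scattering (Highland formula with the
# standard correlated angle/displacement step sampling), continuous
# slowing-down energy loss, beampipe collimation, and voxelised scoring of
# the collisional energy deposit in the phantom.
#
# All particle-state operations are vectorised over the bunch; dead particles
# are frozen in place and never scored again.

ELECTRON_MASS_MEV <- 0.51099895

#' Monte Carlo run settings
#'
#' @param step_water_cm Step length in condensed media (water, PMMA), cm.
#' @param step_air_cm Step length in air, cm.
#' @param step_vacuum_cm Sub-step length inside beampipe-bearing vacuum
#'   elements (used only for aperture checks; vacuum dynamics are exact).
#' @param voxel_cm Dose-grid voxel size (isotropic), cm.
#' @param lateral_half_cm Half-width of the scored lateral region, cm.
#' @param column_half_cm Half-width of the on-axis column; the default
#'   0.15 cm gives the central 0.3 cm x 0.3 cm column.
#' @param energy_cutoff_MeV Particles below this kinetic energy are stopped.
#' @param record_envelope Record rms beam sizes at every step.
#' @param keep_records Keep per-step phantom deposit records (memory-heavy;
#'   intended for small bunches and [score_dose()]).
#' @return A list of settings.
#' @export
mc_settings <- function(step_water_cm = 0.1, step_air_cm = 0.5,
                        step_vacuum_cm = 5, voxel_cm = 0.1,
                        lateral_half_cm = 5, column_half_cm = 0.15,
                        energy_cutoff_MeV = 1, record_envelope = FALSE,
                        keep_records = FALSE) {
  list(step_water_cm = step_water_cm, step_air_cm = step_air_cm,
       step_vacuum_cm = step_vacuum_cm, voxel_cm = voxel_cm,
       lateral_half_cm = lateral_half_cm, column_half_cm = column_half_cm,
       energy_cutoff_MeV = energy_cutoff_MeV,
       record_envelope = record_envelope, keep_records = keep_records)
}

#' Sample a Gaussian bunch from Twiss parameters
#'
#' Draws (u, u') per plane from the correlated Gaussian defined by
#' (alpha, beta, emittance): `u = sigma * g1`,
#' `u' = sqrt(emittance/beta) * (g2 - alpha * g1)`, which reproduces
#' `var(u) = emittance*beta`, `var(u') = emittance*gamma`,
#' `cov = -emittance*alpha`. Energies are Gaussian about the nominal.
#'
#' @param twiss_x,twiss_y [twiss()] objects per plane.
#' @param energy Nominal kinetic energy, MeV.
#' @param energy_spread_rms RMS energy spread, MeV.
#' @param n Number of particles (>= 1).
#' @param seed Integer RNG seed (the bunch is fully reproducible given it).
#' @return A `bunch`: list of vectors `x, xp, y, yp, energy, alive` plus
#'   `n`, `seed`, `energy_nominal`.
#' @export
sample_bunch <- function(twiss_x, twiss_y, energy, energy_spread_rms, n,
                         seed = 1L) {
  stop_invalid(n >= 1, "n must be >= 1")
  stop_invalid(energy > 0, "energy must be positive")
  set.seed(seed)
  draw_plane <- function(tw) {
    g1 <- stats::rnorm(n); g2 <- stats::rnorm(n)
    sig <- beam_sigma(tw)
    sigp <- sqrt(tw$emittance / tw$beta)
    list(u = sig * g1, up = sigp * (g2 - tw$alpha * g1))
  }
  px <- draw_plane(twiss_x)
  py <- draw_plane(twiss_y)
  E <- if (energy_spread_rms > 0) {
    stats::rnorm(n, energy, energy_spread_rms)
  } else rep(energy, n)
  structure(list(x = px$u, xp = px$up, y = py$u, yp = py$up,
                 energy = E, alive = rep(TRUE, n), n = as.integer(n),
                 seed = as.integer(seed), energy_nominal = energy),
            class = "bunch")
}

#' @export
print.bunch <- function(x, ...) {
  cat(sprintf("<bunch> n=%d (alive %d), seed=%d, <E>=%.1f MeV\n",
              x$n, sum(x$alive), x$seed, mean(x$energy[x$alive])))
  invisible(x)
}

# Highland rms scattering angle per plane [rad] for a path dz_m through a
# medium of radiation length X0_cm; E is kinetic energy in MeV (vectorised).
highland_theta0 <- function(E, dz_m, X0_cm) {
  t <- (dz_m * 100) / X0_cm
  Etot <- E + ELECTRON_MASS_MEV
  pc <- sqrt(pmax(Etot^2 - ELECTRON_MASS_MEV^2, 1e-12))
  beta_pc <- pc^2 / Etot
  (13.6 / beta_pc) * sqrt(t) * (1 + 0.038 * log(t))
}

#' Single condensed-history scattering step
#'
#' Advances the bunch ballistically over `dz` and, in a non-vacuum medium,
#' applies a multiple-Coulomb-scattering kick per plane: the angle kick is
#' `theta0 * g2` with `theta0` from the Highland formula, and the correlated
#' lateral displacement is `dz * theta0 * (g1/sqrt(12) + g2/2)`
#' (displacement variance `dz^2 theta0^2 / 3`, angle-displacement correlation
#' `sqrt(3)/2`). Kinetic energy is reduced by the collisional stopping power
#' times the path plus the radiative loss `E * dz / X0` (radiated photons are
#' assumed to escape and are not deposited locally).
#'
#' @param state A `bunch` (or any list with `x, xp, y, yp, energy, alive`).
#' @param medium A [material()].
#' @param dz Step length in metres (> 0).
#' @return The updated state; attribute `"edep_MeV"` carries the per-particle
#'   collisional deposit for alive particles (zero in vacuum).
#' @export
scatter_step <- function(state, medium, dz) {
  stop_invalid(is.finite(dz) && dz > 0, "dz must be positive")
  m <- as.numeric(state$alive)
  state$x <- state$x + state$xp * dz * m
  state$y <- state$y + state$yp * dz * m
  if (is_vacuum(medium)) {
    attr(state, "edep_MeV") <- numeric(length(m))
    return(state)
  }
  n <- length(state$x)
  th0 <- highland_theta0(state$energy, dz, medium$radiation_length_cm)
  g1 <- stats::rnorm(n); g2 <- stats::rnorm(n)
  state$x <- state$x + dz * th0 * (g1 / sqrt(12) + g2 / 2) * m
  state$xp <- state$xp + th0 * g2 * m
  g3 <- stats::rnorm(n); g4 <- stats::rnorm(n)
  state$y <- state$y + dz * th0 * (g3 / sqrt(12) + g4 / 2) * m
  state$yp <- state$yp + th0 * g4 * m
  dz_cm <- dz * 100
  ecoll <- pmin(medium$stopping_power_MeV_cm * dz_cm, state$energy) * m
  erad <- state$energy * (dz_cm / medium$radiation_length_cm) * m
  state$energy <- pmax(state$energy - ecoll - erad, 0)
  attr(state, "edep_MeV") <- ecoll
  state
}

#' Collimate a bunch on a circular aperture
#'
#' Particles at radius `sqrt(x^2 + y^2) >= inner_radius` are absorbed
#' (marked dead, boundary inclusive); others pass unchanged.
#'
#' @param state A `bunch`.
#' @param inner_radius Aperture inner radius in metres (> 0).
#' @return The state with `alive` updated.
#' @export
apply_aperture <- function(state, inner_radius) {
  stop_invalid(is.finite(inner_radius) && inner_radius > 0,
               "inner_radius must be positive")
  hit <- (state$x^2 + state$y^2) >= inner_radius^2
  state$alive <- state$alive & !hit
  state
}

# exact thick-lens quadrupole map over dz, per particle (chromatic: the
# per-particle strength is K * E_nominal / E). All Keff share the sign of K.
quad_map_step <- function(state, K, dz, E0, mask) {
  if (abs(K) < 1e-30) {
    state$x <- state$x + state$xp * dz * mask
    state$y <- state$y + state$yp * dz * mask
    return(state)
  }
  Keff <- K * E0 / pmax(state$energy, 1e-6)
  w <- sqrt(abs(Keff))
  phi <- w * dz
  # focusing branch (cos/sin) and defocusing branch (cosh/sinh)
  cF <- cos(phi);  sF <- sin(phi) / w;  qF <- -w * sin(phi)
  cD <- cosh(phi); sD <- sinh(phi) / w; qD <- w * sinh(phi)
  upd <- function(u, up, c1, s1, q1) {
    list(u = (c1 * u + s1 * up) * mask + u * (1 - mask),
         up = (q1 * u + c1 * up) * mask + up * (1 - mask))
  }
  if (K > 0) {  # focuses x, defocuses y
    rx <- upd(state$x, state$xp, cF, sF, qF)
    ry <- upd(state$y, state$yp, cD, sD, qD)
  } else {
    rx <- upd(state$x, state$xp, cD, sD, qD)
    ry <- upd(state$y, state$yp, cF, sF, qF)
  }
  state$x <- rx$u; state$xp <- rx$up
  state$y <- ry$u; state$yp <- ry$up
  state
}

empty_dose_grid <- function(phantom_length_m, settings) {
  dxy <- settings$voxel_cm
  nhalf <- floor(settings$lateral_half_cm / dxy)
  nx <- 2L * nhalf + 1L
  nz <- max(1L, as.integer(round(phantom_length_m * 100 / dxy)))
  structure(list(
    deposit = array(0, dim = c(nx, nx, nz)),
    dx = dxy, dy = dxy, dz = dxy,
    x_centers = (seq_len(nx) - (nx + 1) / 2) * dxy,
    y_centers = (seq_len(nx) - (nx + 1) / 2) * dxy,
    z_centers = (seq_len(nz) - 0.5) * dxy,
    n_primary = 0L, energy_in_MeV = 0
  ), class = "dose_grid")
}

# deposit energies (MeV) at positions given in cm (x, y lateral; depth from
# phantom entrance); positions outside the scored region are dropped.
deposit_into_grid <- function(grid, x_cm, y_cm, depth_cm, edep) {
  dims <- dim(grid$deposit)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ix <- floor(x_cm / grid$dx + 0.5) + (nx + 1) %/% 2
  iy <- floor(y_cm / grid$dy + 0.5) + (ny + 1) %/% 2
  iz <- floor(depth_cm / grid$dz) + 1L
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny & iz >= 1 & iz <= nz &
    edep > 0
  if (!any(ok)) return(grid)
  idx <- (ix[ok] - 1L) + (iy[ok] - 1L) * nx + (iz[ok] - 1L) * nx * ny + 1L
  w <- edep[ok]
  if (length(unique(w)) == 1L) {
    counts <- tabulate(idx, nbins = nx * ny * nz)
    grid$deposit <- grid$deposit + w[1] * counts
  } else {
    agg <- rowsum(w, idx)
    at <- as.integer(rownames(agg))
    grid$deposit[at] <- grid$deposit[at] + agg[, 1]
  }
  grid
}

#' Score phantom step records onto a voxel grid
#'
#' @param records Data frame with columns `x_cm`, `y_cm`, `depth_cm` (step
#'   midpoints) and `edep_MeV`.
#' @param phantom_length_m Phantom thickness in metres.
#' @param settings [mc_settings()] controlling voxel size and extents.
#' @return A `dose_grid`.
#' @export
score_dose <- function(records, phantom_length_m, settings = mc_settings()) {
  if (is.null(records) || nrow(records) == 0 || all(records$edep_MeV <= 0)) {
    stop(errorCondition("no energy deposited in the phantom",
                        class = c("vhee_empty_dose", "error", "condition")))
  }
  grid <- empty_dose_grid(phantom_length_m, settings)
  deposit_into_grid(grid, records$x_cm, records$y_cm, records$depth_cm,
                    records$edep_MeV)
}

#' Transport a bunch through a beamline
#'
#' Particles advance element by element. Inside quadrupoles the exact
#' thick-lens map is applied per particle with the chromatically scaled
#' strength `K * E_nominal / E`; vacuum transport is therefore identical to
#' matrix optics. In material media, [scatter_step()] is applied per step.
#' The beampipe aperture, where present, is checked at every step (particles
#' reaching the inner wall are absorbed). Steps inside the phantom deposit
#' their collisional energy loss at the step midpoint into the dose grid.
#'
#' @param bunch A [sample_bunch()] bunch.
#' @param beamline A [build_beamline()] beamline.
#' @param settings [mc_settings()].
#' @param score Score the phantom dose grid (default `TRUE`).
#' @return A list of class `transport_result` with `bunch` (final state),
#'   `dose` (a `dose_grid` or `NULL`), `envelope` (data frame of
#'   `z_m, sigma_x_m, sigma_y_m, n_alive` when requested), `records`
#'   (phantom step records when `keep_records`), and `n_alive`.
#' @export
transport_bunch <- function(bunch, beamline, settings = mc_settings(),
                            score = TRUE) {
  stop_invalid(inherits(beamline, "beamline"), "need a beamline object")
  stop_invalid(length(beamline$elements) >= 1, "beamline is empty")
  st <- bunch
  E0 <- bunch$energy_nominal
  z <- 0
  grid <- NULL
  env <- if (settings$record_envelope) {
    list(z = numeric(0), sx = numeric(0), sy = numeric(0), na = integer(0))
  } else NULL
  recs <- if (settings$keep_records) {
    list(x = numeric(0), y = numeric(0), d = numeric(0), e = numeric(0))
  } else NULL
  mat_cache <- list()
  get_mat <- function(name) {
    if (is.null(mat_cache[[name]])) mat_cache[[name]] <<- material(name)
    mat_cache[[name]]
  }

  for (el in beamline$elements) {
    if (el$length <= 0) next
    med <- get_mat(el$medium)
    vac <- is_vacuum(med)
    is_phantom <- el$kind == "phantom"
    step_m <- if (is_phantom || el$medium %in% c("water", "pmma")) {
      settings$step_water_cm / 100
    } else if (el$medium == "air") {
      settings$step_air_cm / 100
    } else if (vac) {
      if (is.na(el$pipe_radius)) el$length else settings$step_vacuum_cm / 100
    } else el$length  # thin windows: single step
    nstep <- max(1L, as.integer(ceiling(el$length / step_m - 1e-9)))
    dz <- el$length / nstep
    if (is_phantom) {
      phantom_z0 <- z
      if (score && is.null(grid)) {
        grid <- empty_dose_grid(el$length, settings)
        grid$n_primary <- bunch$n
        grid$energy_in_MeV <- sum(st$energy[st$alive])
      }
    }
    for (k in seq_len(nstep)) {
      mask <- as.numeric(st$alive)
      x_pre <- st$x; y_pre <- st$y
      if (el$kind == "quad") {
        st <- quad_map_step(st, el$K, dz, E0, mask)
        if (!vac) {
          # scattering kick on top of the magnetic map (thin-medium quads)
          st <- add_scatter_only(st, med, dz, mask)
        }
      } else {
        st <- scatter_step(st, med, dz)
      }
      if (!vac) {
        ecoll <- pmin(med$stopping_power_MeV_cm * dz * 100, st$energy) * mask
        if (el$kind == "quad") {
          erad <- st$energy * (dz * 100 / med$radiation_length_cm) * mask
          st$energy <- pmax(st$energy - ecoll - erad, 0)
        } else {
          ecoll <- attr(st, "edep_MeV")
        }
        low <- st$alive & (st$energy < settings$energy_cutoff_MeV)
        if (any(low)) st$alive[low] <- FALSE
      } else {
        # vacuum phantom: score unit weights (fluence proxy, films-in-vacuum)
        ecoll <- mask
      }
      if (!is.na(el$pipe_radius)) st <- apply_aperture(st, el$pipe_radius)
      if (is_phantom) {
        xm <- (x_pre + st$x) / 2 * 100
        ym <- (y_pre + st$y) / 2 * 100
        depth <- (z + (k - 0.5) * dz - phantom_z0) * 100
        alive_now <- st$alive
        ed <- ecoll * as.numeric(alive_now)
        if (score) {
          grid <- deposit_into_grid(grid, xm[alive_now], ym[alive_now],
                                    rep(depth, sum(alive_now)), ed[alive_now])
        }
        if (!is.null(recs)) {
          recs$x <- c(recs$x, xm[alive_now]); recs$y <- c(recs$y, ym[alive_now])
          recs$d <- c(recs$d, rep(depth, sum(alive_now)))
          recs$e <- c(recs$e, ed[alive_now])
        }
      }
      if (!is.null(env)) {
        a <- st$alive
        env$z <- c(env$z, z + k * dz)
        env$sx <- c(env$sx, if (sum(a) > 1) stats::sd(st$x[a]) else NA_real_)
        env$sy <- c(env$sy, if (sum(a) > 1) stats::sd(st$y[a]) else NA_real_)
        env$na <- c(env$na, sum(a))
      }
    }
    z <- z + el$length
  }
  structure(list(
    bunch = st,
    dose = grid,
    envelope = if (!is.null(env)) {
      data.frame(z_m = env$z, sigma_x_m = env$sx, sigma_y_m = env$sy,
                 n_alive = env$na)
    } else NULL,
    records = if (!is.null(recs)) {
      data.frame(x_cm = recs$x, y_cm = recs$y, depth_cm = recs$d,
                 edep_MeV = recs$e)
    } else NULL,
    n_alive = sum(st$alive)
  ), class = "transport_result")
}

# scattering displacement/angle/energy-independent kick without the ballistic
# advance (used inside quadrupole steps, where the magnetic map advances the
# particle); energy loss is applied by the caller.
add_scatter_only <- function(state, medium, dz, mask) {
  n <- length(state$x)
  th0 <- highland_theta0(state$energy, dz, medium$radiation_length_cm)
  g1 <- stats::rnorm(n); g2 <- stats::rnorm(n)
  state$x <- state$x + dz * th0 * (g1 / sqrt(12) + g2 / 2) * mask
  state$xp <- state$xp + th0 * g2 * mask
  g3 <- stats::rnorm(n); g4 <- stats::rnorm(n)
  state$y <- state$y + dz * th0 * (g3 / sqrt(12) + g4 / 2) * mask
  state$yp <- state$yp + th0 * g4 * mask
  state
}
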