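# Canned studies: the two headline experiments of the package, with the
# preset-specific optimiser configuration fixed in one place so that
# interactive use, the test suite and the acceptance script all run the
# same conditions.

#' Compact-lattice deep-focus study
#'
#' Optimises the five-quadrupole compact lattice for a deep on-axis focus
#' (default 15 cm into the 30 cm water phantom, with a 6 cm inner-radius
#' beampipe), then runs the Monte Carlo at the optimised strengths for a
#' set of beampipe radii with identical seed. The widest-pipe rows show the
#' deep-focus operating point; the series shows how beampipe collimation
#' limits the achievable focal depth and raises the entrance dose.
#'
#' @param target_depth_cm Requested on-axis peak depth, cm.
#' @param optimize_radius_cm Beampipe radius assumed during optimisation.
#' @param radii_cm Radii for the Monte Carlo study.
#' @param n Particles per Monte Carlo run.
#' @param seed RNG seed.
#' @param settings [mc_settings()].
#' @return List with `solution` (the `focus_solution`) and `study` (data
#'   frame from [pipe_radius_study()]).
#' @export
compact_focus_study <- function(target_depth_cm = 15,
                                optimize_radius_cm = 6,
                                radii_cm = c(2, 5, 6),
                                n = 2e5, seed = 1L,
                                settings = mc_settings()) {
  bl <- build_beamline("compact", pipe_radius_cm = optimize_radius_cm)
  sol <- optimize_strengths(bl, target_depth_cm)
  study <- pipe_radius_study(sol, radii_cm, preset = "compact",
                             n = n, seed = seed, settings = settings)
  list(solution = sol, study = study)
}

#' CLEAR-like final-quadrupole scan study
#'
#' Reconstructs the final-quadrupole scan experiment on the six-quadrupole
#' CLEAR-like preset: the final quadrupole is pinned to its 240 A strength
#' (via the magnet excitation constant and the 201 MeV rigidity), the five
#' upstream quadrupoles are optimised for a single-plane focus at the
#' preset operating depth, and the Monte Carlo is re-run with the final
#' quadrupole at each scan current. A straight line is fitted to peak depth
#' versus current.
#'
#' The focused plane is driven by the final quadrupole; the other plane is
#' kept small and non-diverging (its entrance reward is off), and the
#' focused plane's entrance size saturates at the few-mm film scale.
#'
#' @param currents_A Scan currents, amperes.
#' @param target_depth_cm Operating peak depth at the reference current
#'   (middle of the scan).
#' @param n Particles per Monte Carlo point.
#' @param seed RNG seed (shared across scan points).
#' @param settings [mc_settings()].
#' @return List with `solution`, `scan` (data frame) and `fit`
#'   (a `linear_fit`).
#' @export
clear_quad_scan_study <- function(currents_A = c(230, 240, 250),
                                  target_depth_cm = 5.2,
                                  n = 1e5, seed = 1L,
                                  settings = mc_settings()) {
  bl <- build_beamline("clear_like")
  E <- bl$beam$energy_MeV
  ref <- currents_A[ceiling(length(currents_A) / 2)]
  nq <- length(quad_indices(bl))
  Kfix <- -abs(current_to_K(ref, E))  # final quad focuses the y-plane
  sol <- optimize_strengths(bl, target_depth_cm, weight_x = 0.4,
                            entrance_weight = c(0, 1),
                            entrance_cap_m = 0.003,
                            fixed = stats::setNames(Kfix, nq))
  scan <- scan_final_quad(sol, currents_A, n = n, seed = seed,
                          settings = settings)
  list(solution = sol, scan = scan, fit = fit_peak_linear(scan))
}
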