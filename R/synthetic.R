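# Synthetic-data generators. Every generator is seeded, bit-reproducible,
# and stores its ground truth alongside the output, so that every analysis
# stage can be tested by round-trip without external data.

#' Generate a synthetic quadrupole-scan table
#'
#' Computes the screen beam size as a function of the scan-quadrupole
#' strength from a known ground-truth Twiss state via the transfer-matrix
#' model (the same forward model [twiss_from_quad_scan()] inverts), then
#' applies optional multiplicative Gaussian noise.
#'
#' @param truth A [twiss()] object at the reconstruction plane (the scan
#'   quadrupole entrance).
#' @param geometry List with `quad_length` and `drift` (m), as in
#'   [twiss_from_quad_scan()].
#' @param strengths Vector of at least 3 scan strengths K, 1/m^2.
#' @param noise_rel Relative sigma noise (0 = noiseless).
#' @param seed RNG seed.
#' @param plane `"x"` or `"y"`.
#' @return Data frame `plane, K, sigma_m` with attribute `"ground_truth"`.
#' @export
gen_quad_scan_data <- function(truth, geometry, strengths, noise_rel = 0,
                               seed = 1L, plane = "x") {
  stop_invalid(length(strengths) >= 3, "need at least 3 strengths")
  sig <- vapply(strengths, function(k) {
    M <- compose_transfer(list(quad_transfer(k, geometry$quad_length, plane),
                               drift_transfer(geometry$drift)))
    beam_sigma(propagate_twiss(truth, M))
  }, numeric(1))
  if (noise_rel > 0) {
    set.seed(seed)
    sig <- sig * (1 + noise_rel * stats::rnorm(length(sig)))
  }
  out <- data.frame(plane = plane, K = strengths, sigma_m = sig)
  attr(out, "ground_truth") <- truth
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic film calibration set
#'
#' Inverts the calibration model to obtain `OD = log_b((D - c)/a)` for the
#' requested doses, then applies optional multiplicative Gaussian noise to
#' the OD values.
#'
#' @param a,b,c Ground-truth calibration parameters (Gy, -, Gy).
#' @param doses Doses in Gy; each must satisfy `(dose - c)/a > 0`.
#' @param noise_rel Relative OD noise (0 = noiseless).
#' @param seed RNG seed.
#' @return Data frame `OD, dose_Gy` with attribute `"ground_truth"`.
#' @export
gen_calibration_set <- function(a, b, c, doses, noise_rel = 0, seed = 1L) {
  curve <- list(a = a, b = b, c = c)
  od <- od_from_dose(curve, doses)
  if (noise_rel > 0) {
    set.seed(seed)
    od <- od * (1 + noise_rel * stats::rnorm(length(od)))
  }
  out <- data.frame(OD = od, dose_Gy = doses)
  attr(out, "ground_truth") <- c(a = a, b = b, c = c)
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic stack of irradiated films
#'
#' For each planar dose distribution, inverts the calibration curve per
#' pixel (`OD = log_b((D - c)/a)`, `PV = PV0 * 10^-OD`), adds Gaussian pixel
#' noise, and quantises to 16 bits. Doses outside the invertible range are
#' clamped and the affected films flagged. Geometry defaults to the
#' experimental films: 35 x 35 mm scanned at 300 dpi, stack spacing 5 mm.
#'
#' @param dose_maps List of dose matrices (Gy), one per film plane, or a
#'   single matrix.
#' @param curves Either one `calibration_curve` applied to every channel or
#'   a named list with `red`, `green`, `blue`.
#' @param pv0 Unexposed pixel values per channel (length 3).
#' @param dpi Scan resolution.
#' @param noise_sd_frac Pixel noise sigma as a fraction of PV0 (default
#'   0.5%).
#' @param seed RNG seed.
#' @param spacing_mm Film-to-film spacing recorded as `depth_mm` metadata.
#' @return List of `film_image`s; each carries attributes `depth_mm`,
#'   `clamped` (logical) and `ground_truth_dose`.
#' @export
gen_film_stack <- function(dose_maps, curves, pv0 = c(48000, 45000, 42000),
                           dpi = 300, noise_sd_frac = 0.005, seed = 1L,
                           spacing_mm = 5) {
  if (is.matrix(dose_maps)) dose_maps <- list(dose_maps)
  if (inherits(curves, "calibration_curve") ||
      (!is.null(curves$a) && is.null(curves$red))) {
    curves <- list(red = curves, green = curves, blue = curves)
  }
  set.seed(seed)
  films <- vector("list", length(dose_maps))
  for (i in seq_along(dose_maps)) {
    D <- dose_maps[[i]]
    px <- array(0, dim = c(nrow(D), ncol(D), 3))
    clamped <- FALSE
    for (ch in 1:3) {
      cv <- curves[[c("red", "green", "blue")[ch]]]
      arg <- (D - cv$c) / cv$a
      if (any(arg <= 0)) {
        clamped <- TRUE
        arg <- pmax(arg, 1e-6)
      }
      od <- log(arg, base = cv$b)
      pv <- pv0[ch] * 10^(-od)
      if (noise_sd_frac > 0) {
        pv <- pv + stats::rnorm(length(pv), 0, noise_sd_frac * pv0[ch])
      }
      px[, , ch] <- pmin(pmax(round(pv), 0), 65535)
    }
    f <- film_image(px, dpi = dpi, pv0 = pv0)
    attr(f, "depth_mm") <- (i - 1) * spacing_mm
    attr(f, "clamped") <- clamped
    attr(f, "ground_truth_dose") <- D
    films[[i]] <- f
  }
  if (clamped_any <- any(vapply(films, attr, logical(1), "clamped"))) {
    warning("some film doses fell outside the invertible calibration range and were clamped")
  }
  films
}

#' Extract planar dose maps from a scored dose grid
#'
#' Samples lateral x-y dose distributions at the requested depths (nearest
#' voxel layer), rescaled so that the stack maximum equals `peak_dose_Gy` —
#' a convenience for generating synthetic film stacks from Monte Carlo
#' output.
#'
#' @param grid A `dose_grid`.
#' @param depths_cm Depths of the film planes.
#' @param peak_dose_Gy Physical dose assigned to the stack maximum.
#' @return List of dose matrices (rows = y, columns = x) with attribute
#'   `"pitch_mm"` (the voxel size).
#' @export
dose_planes_from_grid <- function(grid, depths_cm, peak_dose_Gy = 20) {
  planes <- lapply(depths_cm, function(d) {
    iz <- which.min(abs(grid$z_centers - d))
    t(grid$deposit[, , iz])  # rows = y, cols = x
  })
  mx <- max(vapply(planes, max, numeric(1)))
  stop_invalid(mx > 0, "no dose in the requested planes")
  planes <- lapply(planes, function(p) p / mx * peak_dose_Gy)
  attr(planes, "pitch_mm") <- grid$dx * 10
  planes
}
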