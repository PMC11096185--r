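# Radiochromic-film (EBT-XD type) dosimetry: optical density, exponential
# dose calibration D = a * b^OD + c with fit statistics, dose-map maximum
# localisation by alternating coordinate search on a smoothed map, profile
# HWHM extraction, and quadrature combination of uncertainty components.

#' Optical density from pixel values
#'
#' `OD = -log10(PV / PV0)`, comparing an exposed pixel value `pv` with the
#' unexposed reference `pv0` (vectorised).
#'
#' @param pv Exposed pixel value(s), > 0.
#' @param pv0 Unexposed pixel value(s), > 0.
#' @return Optical density (0 when `pv == pv0`).
#' @export
optical_density <- function(pv, pv0) {
  stop_invalid(all(pv > 0) && all(pv0 > 0), "pixel values must be positive")
  -log10(pv / pv0)
}

#' Fit the film calibration curve D = a * b^OD + c
#'
#' Nonlinear least squares (Levenberg-Marquardt) with unit weights. The fit
#' is initialised from `c0 = -max(D)` and a log-linear regression of
#' `log(D - c0)` on OD (the exponential model is ill-conditioned: `a` and `c`
#' are strongly anti-correlated, with `a` close to `-c` in practice), with
#' deterministic restarts at perturbed growth rates. Reported statistics:
#' reduced chi-squared `RSS / (n - 3)` (residual-variance units, since no
#' per-point measurement uncertainties are supplied) and the adjusted
#' R-squared with the degrees-of-freedom penalty.
#'
#' @param pairs Data frame with columns `OD` and `dose_Gy` (>= 4 points
#'   spanning a nonzero OD range).
#' @param channel Optional channel label stored on the result.
#' @return A `calibration_curve`: list with `a`, `b`, `c` (Gy, -, Gy),
#'   `reduced_chi2`, `adjusted_R2`, `od_range`, `n`, `channel`.
#' @export
fit_calibration <- function(pairs, channel = NA_character_) {
  od <- pairs$OD
  D <- pairs$dose_Gy
  if (length(od) < 4) {
    stop(errorCondition("calibration fit needs at least 4 (OD, dose) pairs",
                        class = c("vhee_underdetermined_fit", "error",
                                  "condition")))
  }
  stop_invalid(diff(range(od)) > 0, "OD values must span a nonzero range")
  c0 <- -max(D)
  lg <- stats::lm(log(D - c0) ~ od)
  b0 <- exp(unname(stats::coef(lg)[2]))
  a0 <- exp(unname(stats::coef(lg)[1]))
  df <- data.frame(od = od, D = D)
  fit <- NULL
  for (fac in c(1, 0.5, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(D ~ a * b^od + c, data = df,
                        start = list(a = a0, b = b0 * fac, c = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop(errorCondition("calibration fit did not converge from any start",
                        class = c("vhee_fit_failed", "error", "condition")))
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((D - mean(D))^2)
  n <- length(D); p <- 3
  structure(list(
    a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
    channel = channel,
    reduced_chi2 = rss / (n - p),
    adjusted_R2 = 1 - (rss / (n - p)) / (tss / (n - 1)),
    od_range = range(od), n = n
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  ch <- if (is.na(x$channel)) "" else sprintf("  [%s]", x$channel)
  cat(sprintf("D = %.3f * %.2f^OD + %.3f Gy%s  red.chi2 = %.3g, adj.R2 = %.6f\n",
              x$a, x$b, x$c, ch, x$reduced_chi2, x$adjusted_R2))
  invisible(x)
}

#' Fit all three colour channels and flag poor ones
#'
#' Fits [fit_calibration()] per channel; a channel is flagged unusable when
#' its reduced chi-squared exceeds `flag_factor` times the best channel's
#' (the criterion under which a markedly worse blue channel is rejected).
#'
#' @param table Data frame with columns `channel`, `OD`, `dose_Gy`.
#' @param flag_factor Rejection threshold on the reduced chi-squared ratio.
#' @return Named list of `calibration_curve`s with attribute `"flagged"`.
#' @export
fit_calibration_channels <- function(table, flag_factor = 5) {
  chans <- unique(table$channel)
  curves <- lapply(chans, function(ch) {
    fit_calibration(table[table$channel == ch, , drop = FALSE], channel = ch)
  })
  names(curves) <- chans
  chi2 <- vapply(curves, `[[`, numeric(1), "reduced_chi2")
  flagged <- names(chi2)[chi2 > flag_factor * min(chi2)]
  attr(curves, "flagged") <- flagged
  curves
}

#' Evaluate the calibration curve
#'
#' @param curve A `calibration_curve`.
#' @param od Optical density value(s).
#' @return Dose in Gy (`a * b^OD + c`); the result carries attribute
#'   `"extrapolated"` marking values outside the fitted OD range.
#' @export
dose_from_od <- function(curve, od) {
  d <- curve$a * curve$b^od + curve$c
  attr(d, "extrapolated") <- od < curve$od_range[1] | od > curve$od_range[2]
  d
}

#' Invert the calibration curve (dose to optical density)
#'
#' @param curve A `calibration_curve` (or list with `a`, `b`, `c`).
#' @param dose Dose in Gy; must satisfy `(dose - c)/a > 0`.
#' @return `OD = log_b((dose - c) / a)`.
#' @export
od_from_dose <- function(curve, dose) {
  arg <- (dose - curve$c) / curve$a
  stop_invalid(all(arg > 0), "dose outside the invertible range of the curve")
  log(arg, base = curve$b)
}

#' Dose map container
#'
#' @param dose Matrix of doses in Gy (rows = y, columns = x).
#' @param pitch_mm Pixel pitch in mm (25.4 / dpi for scanned film).
#' @return A `dose_map` object.
#' @export
dose_map <- function(dose, pitch_mm) {
  stop_invalid(is.matrix(dose) && all(is.finite(dose)),
               "dose must be a finite matrix")
  stop_invalid(pitch_mm > 0, "pitch must be positive")
  structure(list(dose = dose, pitch_mm = pitch_mm), class = "dose_map")
}

# separable moving-average smoothing of a matrix (window in pixels,
# truncated at the edges)
smooth_map <- function(m, window = 10) {
  sm <- apply(m, 2, moving_average, w = window)
  t(apply(sm, 1, moving_average, w = window))
}

#' Locate the maximum-dose pixel by alternating coordinate search
#'
#' The map is smoothed with a separable moving average (default window
#' 10 pixels) and the maximum is located by searching along x (columns) at
#' the current row, then along y (rows) at the found column, repeating until
#' neither coordinate changes. Ties break to the lowest index. The search is
#' invariant under global dose rescaling.
#'
#' @param map A `dose_map` (or plain matrix).
#' @param window Smoothing window in pixels.
#' @param max_iter Safety cap on alternations.
#' @return Integer vector `c(row, col)` on the unsmoothed grid, with
#'   attribute `"smoothed_value"`.
#' @export
locate_max_dose <- function(map, window = 10, max_iter = 50) {
  m <- if (inherits(map, "dose_map")) map$dose else map
  if (all(m <= 0)) {
    stop(errorCondition("dose map contains no signal",
                        class = c("vhee_no_signal", "error", "condition")))
  }
  S <- smooth_map(m, window)
  r <- arrayInd(which.max(S), dim(S))[1]
  cc <- -1L
  for (i in seq_len(max_iter)) {
    c_new <- which.max(S[r, ])
    r_new <- which.max(S[, c_new])
    if (c_new == cc && r_new == r) break
    r <- r_new; cc <- c_new
  }
  structure(c(row = r, col = cc), smoothed_value = S[r, cc])
}

#' HWHM of the dose profile through a point
#'
#' Takes the profile through `through` along the requested axis, finds the
#' full width at half maximum by linear interpolation of the half-max
#' crossings, and returns half of it in millimetres.
#'
#' @param map A `dose_map`.
#' @param through Integer `c(row, col)`, usually from [locate_max_dose()].
#' @param axis `"x"` (profile along the row) or `"y"` (along the column).
#' @return HWHM in mm.
#' @export
hwhm_from_profile <- function(map, through, axis = c("x", "y")) {
  axis <- match.arg(axis)
  prof <- if (axis == "x") map$dose[through[1], ] else map$dose[, through[2]]
  pos <- (seq_along(prof) - 1) * map$pitch_mm
  fwhm_interp(pos, prof) / 2
}

#' Compare the smoothed maximum with a raw patch average
#'
#' Returns the smoothed dose at `at`, the mean of the unsmoothed
#' `patch x patch` pixel square centred there, and their relative difference
#' in percent — the internal consistency check for the film maximum-dose
#' read-out.
#'
#' @param map A `dose_map`.
#' @param at Integer `c(row, col)`.
#' @param window Smoothing window in pixels.
#' @param patch Patch edge length in pixels.
#' @return List `smoothed_max`, `patch_mean`, `percent_diff`.
#' @export
patch_average_check <- function(map, at, window = 10, patch = 10) {
  m <- map$dose
  half_lo <- (patch - 1) %/% 2
  half_hi <- patch - 1 - half_lo
  r <- at[1]; cc <- at[2]
  stop_invalid(r - half_lo >= 1 && r + half_hi <= nrow(m) &&
                 cc - half_lo >= 1 && cc + half_hi <= ncol(m),
               "patch extends outside the dose map")
  pm <- mean(m[(r - half_lo):(r + half_hi), (cc - half_lo):(cc + half_hi)])
  sv <- smooth_map(m, window)[r, cc]
  list(smoothed_max = sv, patch_mean = pm,
       percent_diff = 100 * abs(sv - pm) / pm)
}

#' Combine relative uncertainties in quadrature
#'
#' @param components Non-negative uncertainty components in percent.
#' @return List with `percent` (`sqrt(sum(components^2))`) and `rounded`
#'   (nearest integer).
#' @export
combine_uncertainty_quadrature <- function(components) {
  stop_invalid(all(is.finite(components)) && all(components >= 0),
               "components must be non-negative")
  q <- sqrt(sum(components^2))
  list(percent = q, rounded = round(q))
}

# ---- film image container and I/O -------------------------------------

#' Film image container
#'
#' @param pixels Integer array `height x width x 3` (RGB) of 16-bit pixel
#'   values in `[0, 65535]`.
#' @param dpi Scan resolution in dots per inch.
#' @param pv0 Named or ordered numeric of unexposed pixel values per channel
#'   (red, green, blue).
#' @return A `film_image`.
#' @export
film_image <- function(pixels, dpi = 300, pv0) {
  stop_invalid(length(dim(pixels)) == 3 && dim(pixels)[3] == 3,
               "pixels must be an H x W x 3 array")
  stop_invalid(all(pixels >= 0) && all(pixels <= 65535),
               "pixel values must lie in [0, 65535]")
  stop_invalid(dpi > 0, "dpi must be positive")
  stop_invalid(length(pv0) == 3 && all(pv0 > 0), "pv0 must be 3 positive values")
  structure(list(pixels = pixels, dpi = dpi,
                 pv0 = stats::setNames(as.numeric(pv0),
                                       c("red", "green", "blue"))),
            class = "film_image")
}

#' Write a film image as 16-bit TIFF plus sidecar metadata
#'
#' @param film A `film_image`.
#' @param path Output TIFF path; a JSON sidecar `<path>.json` records `dpi`,
#'   per-channel `pv0` and any `depth_mm` attribute.
#' @return `path`, invisibly.
#' @export
write_film <- function(film, path) {
  tiff::writeTIFF(film$pixels / 65535, path, bits.per.sample = 16)
  meta <- list(dpi = film$dpi, pv0 = as.list(film$pv0))
  if (!is.null(attr(film, "depth_mm"))) meta$depth_mm <- attr(film, "depth_mm")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a film image written by [write_film()]
#'
#' @param path TIFF path with sidecar `<path>.json`.
#' @return A `film_image` (with `depth_mm` attribute when present).
#' @export
read_film <- function(path) {
  px <- tiff::readTIFF(path)
  stop_invalid(length(dim(px)) == 3 && dim(px)[3] >= 3,
               "film TIFF must be RGB")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  f <- film_image(round(px[, , 1:3] * 65535), dpi = meta$dpi,
                  pv0 = unlist(meta$pv0))
  if (!is.null(meta$depth_mm)) attr(f, "depth_mm") <- meta$depth_mm
  f
}

#' Convert a film image to a dose map
#'
#' Computes the optical density per pixel against the unexposed reference of
#' the chosen channel and evaluates the calibration curve.
#'
#' @param film A `film_image`.
#' @param curve A `calibration_curve`.
#' @param channel `"red"` (default read-out channel), `"green"` or `"blue"`.
#' @return A `dose_map` (Gy), pixel pitch `25.4 / dpi` mm.
#' @export
film_dose_map <- function(film, curve, channel = "red") {
  ich <- match(channel, c("red", "green", "blue"))
  stop_invalid(!is.na(ich), "channel must be red, green or blue")
  pv <- pmax(film$pixels[, , ich], 1)
  od <- optical_density(pv, film$pv0[[channel]])
  d <- curve$a * curve$b^od + curve$c
  dose_map(pmax(d, 0), pitch_mm = 25.4 / film$dpi)
}

#' Summarise one film: on-axis dose and HWHMs
#'
#' The on-axis dose is the smoothed maximum of the dose map (the value at
#' the located maximum); HWHMs are taken from the unsmoothed profiles
#' through that point.
#'
#' @param map A `dose_map`.
#' @param window Smoothing window in pixels.
#' @return List `on_axis_dose_Gy`, `at` (row, col), `hwhm_x_mm`,
#'   `hwhm_y_mm` (NA when unresolved).
#' @export
analyze_film_map <- function(map, window = 10) {
  at <- locate_max_dose(map, window)
  hw <- function(ax) tryCatch(hwhm_from_profile(map, at, ax),
                              error = function(e) NA_real_)
  list(on_axis_dose_Gy = attr(at, "smoothed_value"),
       at = as.integer(at), hwhm_x_mm = hw("x"), hwhm_y_mm = hw("y"))
}
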