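# Depth-dose and lateral-profile analysis of a scored dose grid.

# truncated moving average: window w samples, edges averaged over the
# in-range part of the window.
moving_average <- function(v, w) {
  if (w <= 1 || length(v) < 2) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  half_lo <- (w - 1) %/% 2
  half_hi <- w - 1 - half_lo
  lo <- pmax(seq_len(n) - half_lo, 1)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' On-axis percentage depth-dose curve
#'
#' Sums the deposit in the central on-axis column (default the central
#' 0.3 cm x 0.3 cm block of voxels) per depth bin and normalises the curve to
#' 100 at its maximum.
#'
#' @param grid A `dose_grid` from [transport_bunch()] or [score_dose()].
#' @param column_half_cm Half-width of the on-axis column in cm.
#' @return Data frame with `depth_cm` (voxel-centre depths) and `percent`;
#'   the maximum of `percent` is exactly 100.
#' @export
depth_dose_curve <- function(grid, column_half_cm = 0.15) {
  stop_invalid(inherits(grid, "dose_grid"), "need a dose_grid")
  sel_x <- abs(grid$x_centers) <= column_half_cm + 1e-9
  sel_y <- abs(grid$y_centers) <= column_half_cm + 1e-9
  col_dose <- apply(grid$deposit[sel_x, sel_y, , drop = FALSE], 3, sum)
  if (all(col_dose <= 0)) {
    stop(errorCondition("on-axis column received no dose",
                        class = c("vhee_empty_dose", "error", "condition")))
  }
  data.frame(depth_cm = grid$z_centers,
             percent = 100 * col_dose / max(col_dose))
}

#' Peak depth and entrance dose of a depth-dose curve
#'
#' The peak depth is the depth of the maximum of the curve smoothed with a
#' moving average of width `smooth_cm` (default 5 mm, the film spacing used
#' experimentally); ties resolve to the shallower depth. The entrance dose is
#' the mean percentage over the first 1 cm of depth. With `refine = TRUE` the
#' smoothed argmax is refined to sub-voxel precision by the vertex of a
#' quadratic fitted to the raw curve within `refine_half_cm` of the argmax
#' (falling back to the argmax when the fit is degenerate).
#'
#' @param curve Data frame from [depth_dose_curve()].
#' @param smooth_cm Smoothing window in cm.
#' @param entrance_cm Depth range defining the entrance region, cm.
#' @param refine Quadratic-vertex sub-voxel refinement of the peak depth.
#' @param refine_half_cm Half-width of the fit region around the argmax.
#' @return List with `peak_depth_cm` and `entrance_percent`.
#' @export
peak_and_entrance <- function(curve, smooth_cm = 0.5, entrance_cm = 1,
                              refine = FALSE, refine_half_cm = 1.5) {
  stop_invalid(nrow(curve) >= 1, "empty curve")
  dz <- if (nrow(curve) > 1) stats::median(diff(curve$depth_cm)) else smooth_cm
  w <- max(1L, as.integer(round(smooth_cm / dz)))
  sm <- moving_average(curve$percent, w)
  i <- which.max(sm)
  peak <- curve$depth_cm[i]
  if (refine) {
    sel <- abs(curve$depth_cm - peak) <= refine_half_cm + 1e-9
    if (sum(sel) >= 5) {
      # the moving average preserves a quadratic's vertex, so fitting the
      # smoothed series reduces noise without biasing the peak location
      df <- data.frame(depth_cm = curve$depth_cm[sel], percent = sm[sel])
      cf <- stats::coef(stats::lm(percent ~ depth_cm + I(depth_cm^2),
                                  data = df))
      v <- -cf[2] / (2 * cf[3])
      if (is.finite(v) && cf[3] < 0 && abs(v - peak) <= refine_half_cm) {
        peak <- unname(v)
      }
    }
  }
  ent <- curve$percent[curve$depth_cm <= entrance_cm + 1e-9]
  list(peak_depth_cm = peak,
       entrance_percent = if (length(ent)) mean(ent) else NA_real_)
}

# half-max crossings of a 1-D profile by linear interpolation; returns the
# full width, or signals when the profile never falls below half maximum on
# either side of the peak.
fwhm_interp <- function(pos, val) {
  if (max(val) <= 0 || length(val) < 3) {
    stop(errorCondition("profile has no positive maximum",
                        class = c("vhee_unresolved_width", "error", "condition")))
  }
  i <- which.max(val)
  half <- val[i] / 2
  left <- NA_real_
  if (i >= 2) {
    for (j in i:2) {
      if (val[j - 1] < half && val[j] >= half) {
        f <- (half - val[j - 1]) / (val[j] - val[j - 1])
        left <- pos[j - 1] + f * (pos[j] - pos[j - 1])
        break
      }
    }
  }
  right <- NA_real_
  if (i < length(val)) {
    for (j in seq(i, length(val) - 1)) {
      if (val[j] >= half && val[j + 1] < half) {
        f <- (val[j] - half) / (val[j] - val[j + 1])
        right <- pos[j] + f * (pos[j + 1] - pos[j])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) {
    stop(errorCondition("profile does not fall below half maximum within range",
                        class = c("vhee_unresolved_width", "error", "condition")))
  }
  right - left
}

#' Lateral half-width-at-half-maximum at a given depth
#'
#' Extracts the lateral profile through the maximum voxel of the slice at
#' `depth_cm` along the requested plane, locates the two half-maximum
#' crossings by linear interpolation, and returns half their separation.
#'
#' @param grid A `dose_grid`.
#' @param depth_cm Depth of the slice, cm.
#' @param plane `"x"` or `"y"`.
#' @return HWHM in cm.
#' @export
lateral_hwhm <- function(grid, depth_cm, plane = c("x", "y")) {
  plane <- match.arg(plane)
  iz <- which.min(abs(grid$z_centers - depth_cm))
  slice <- grid$deposit[, , iz]
  if (max(slice) <= 0) {
    stop(errorCondition("slice has no dose",
                        class = c("vhee_unresolved_width", "error", "condition")))
  }
  im <- arrayInd(which.max(slice), dim(slice))
  if (plane == "x") {
    fwhm_interp(grid$x_centers, slice[, im[2]]) / 2
  } else {
    fwhm_interp(grid$y_centers, slice[im[1], ]) / 2
  }
}

#' HWHM of the lateral dose profile as a function of depth
#'
#' @param grid A `dose_grid`.
#' @param depths_cm Depths to evaluate (default every voxel layer).
#' @return Data frame `depth_cm, hwhm_x_cm, hwhm_y_cm` (NA where the width
#'   is unresolved).
#' @export
hwhm_vs_depth <- function(grid, depths_cm = grid$z_centers) {
  hw <- function(d, pl) {
    tryCatch(lateral_hwhm(grid, d, pl), error = function(e) NA_real_)
  }
  data.frame(depth_cm = depths_cm,
             hwhm_x_cm = vapply(depths_cm, hw, numeric(1), pl = "x"),
             hwhm_y_cm = vapply(depths_cm, hw, numeric(1), pl = "y"))
}
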