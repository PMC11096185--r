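# Linear transfer-matrix optics for quadrupole beamlines.
#
# Conventions: per transverse plane the state is (u, u') with u in metres and
# u' in radians; a transfer matrix is a real 2x2 symplectic (unit-determinant)
# matrix. Positive quadrupole strength K [1/m^2] focuses in x and defocuses
# in y; inverting magnet polarity negates K.

#' Twiss (Courant-Snyder) parameters for one transverse plane
#'
#' @param alpha Dimensionless correlation parameter (positive = converging).
#' @param beta Beta function in metres; must be positive.
#' @param emittance Geometric emittance in metre-radians; must be positive
#'   (zero is tolerated only for degenerate pencil beams).
#'
#' @return An object of class `twiss` with fields `alpha`, `beta`,
#'   `emittance` and the derived `gamma = (1 + alpha^2) / beta`.
#' @examples
#' tw <- twiss(alpha = 0, beta = 5, emittance = 5e-8)
#' beam_sigma(tw)  # rms beam size, 0.5 mm
#' @export
twiss <- function(alpha, beta, emittance) {
  stop_invalid(is.finite(alpha), "alpha must be finite")
  stop_invalid(is.finite(beta) && beta > 0, "beta must be positive")
  stop_invalid(is.finite(emittance) && emittance >= 0,
               "emittance must be non-negative")
  structure(
    list(alpha = alpha, beta = beta, emittance = emittance,
         gamma = (1 + alpha^2) / beta),
    class = "twiss"
  )
}

#' @export
print.twiss <- function(x, ...) {
  cat(sprintf("Twiss: alpha = %.4g, beta = %.4g m, emittance = %.4g m rad (sigma = %.4g m)\n",
              x$alpha, x$beta, x$emittance, beam_sigma(x)))
  invisible(x)
}

#' RMS beam size from Twiss parameters
#'
#' @param tw A [twiss()] object.
#' @return sigma = sqrt(emittance * beta), in metres.
#' @export
beam_sigma <- function(tw) {
  sqrt(tw$emittance * tw$beta)
}

#' Convert quadrupole current to field gradient
#'
#' Uses the CLEAR magnet excitation constant: 1 A corresponds to 0.057 T/m.
#' Negative currents denote reversed polarity and map to negative gradients.
#'
#' @param current Coil current in amperes (vectorised).
#' @return Field gradient in tesla/metre.
#' @export
current_to_gradient <- function(current) {
  stop_invalid(all(is.finite(current)), "current must be finite")
  0.057 * current
}

#' Convert field gradient to normalised quadrupole strength
#'
#' The magnetic rigidity relation for electrons gives
#' `g [T/m] = E [MeV] * K [1/m^2] / 300`, so `K = 300 g / E`.
#'
#' @param gradient Field gradient in T/m (vectorised).
#' @param energy Beam kinetic energy in MeV; must be positive.
#' @return Normalised strength K in 1/m^2.
#' @export
gradient_to_K <- function(gradient, energy) {
  stop_invalid(all(is.finite(gradient)), "gradient must be finite")
  stop_invalid(is.finite(energy) && energy > 0, "energy must be positive")
  300 * gradient / energy
}

#' @rdname gradient_to_K
#' @param K Normalised strength in 1/m^2.
#' @export
K_to_gradient <- function(K, energy) {
  stop_invalid(is.finite(energy) && energy > 0, "energy must be positive")
  energy * K / 300
}

#' Normalised strength directly from coil current
#'
#' @inheritParams current_to_gradient
#' @inheritParams gradient_to_K
#' @return K in 1/m^2.
#' @export
current_to_K <- function(current, energy) {
  gradient_to_K(current_to_gradient(current), energy)
}

#' Thick-lens quadrupole transfer matrix for one plane
#'
#' Positive K focuses in x (cos/sin branch in x, cosh/sinh in y). The K -> 0
#' limit reduces to a field-free drift.
#'
#' @param K Normalised strength in 1/m^2 (signed).
#' @param length Magnetic length in metres; must be positive.
#' @param plane `"x"` or `"y"`.
#' @return A 2x2 transfer matrix (class `transfer_matrix`).
#' @export
quad_transfer <- function(K, length, plane = c("x", "y")) {
  plane <- match.arg(plane)
  stop_invalid(is.finite(length) && length > 0, "length must be positive")
  stop_invalid(is.finite(K), "K must be finite")
  Keff <- if (plane == "x") K else -K
  m <- if (abs(Keff) < 1e-30) {
    matrix(c(1, 0, length, 1), 2, 2)
  } else if (Keff > 0) {
    w <- sqrt(Keff)
    phi <- w * length
    matrix(c(cos(phi), -w * sin(phi), sin(phi) / w, cos(phi)), 2, 2)
  } else {
    w <- sqrt(-Keff)
    phi <- w * length
    matrix(c(cosh(phi), w * sinh(phi), sinh(phi) / w, cosh(phi)), 2, 2)
  }
  structure(m, class = c("transfer_matrix", "matrix"))
}

#' Drift-space transfer matrix
#'
#' @param length Drift length in metres; must be non-negative.
#' @return The 2x2 matrix `[[1, L], [0, 1]]`.
#' @export
drift_transfer <- function(length) {
  stop_invalid(is.finite(length) && length >= 0, "length must be non-negative")
  structure(matrix(c(1, 0, length, 1), 2, 2),
            class = c("transfer_matrix", "matrix"))
}

#' Compose a sequence of transfer matrices
#'
#' The first element of the list is applied to the beam first, i.e. the
#' result is `M_n %*% ... %*% M_2 %*% M_1`.
#'
#' @param matrices Non-empty list of 2x2 transfer matrices.
#' @return The composed 2x2 transfer matrix.
#' @export
compose_transfer <- function(matrices) {
  stop_invalid(is.list(matrices) && length(matrices) >= 1,
               "need a non-empty list of matrices")
  out <- diag(2)
  for (m in matrices) out <- m %*% out
  structure(out, class = c("transfer_matrix", "matrix"))
}

#' Propagate Twiss parameters through a transfer matrix
#'
#' Standard Courant-Snyder propagation of (beta, alpha, gamma); the geometric
#' emittance is invariant under any symplectic map.
#'
#' @param tw A [twiss()] object.
#' @param M A 2x2 transfer matrix.
#' @return The propagated [twiss()] object.
#' @export
propagate_twiss <- function(tw, M) {
  m11 <- M[1, 1]; m12 <- M[1, 2]; m21 <- M[2, 1]; m22 <- M[2, 2]
  beta  <- m11^2 * tw$beta - 2 * m11 * m12 * tw$alpha + m12^2 * tw$gamma
  alpha <- -m11 * m21 * tw$beta + (m11 * m22 + m12 * m21) * tw$alpha -
    m12 * m22 * tw$gamma
  twiss(alpha = alpha, beta = beta, emittance = tw$emittance)
}

#' Reconstruct Twiss parameters from a quadrupole scan
#'
#' Fits the measured rms beam sizes on a downstream screen as a function of
#' the scan-quadrupole strength K. The squared size on the screen is linear
#' in the beam sigma-matrix elements at the reconstruction plane (taken at
#' the scan-quadrupole entrance):
#' `sigma_screen^2 = M11^2 s11 + 2 M11 M12 s12 + M12^2 s22`,
#' with `M(K) = drift(d) %*% quad(K, L)`. Ordinary least squares on
#' sigma^2 gives (s11, s12, s22), from which
#' `emittance = sqrt(s11 s22 - s12^2)`, `beta = s11/emittance`,
#' `alpha = -s12/emittance`.
#'
#' @param points Data frame with columns `K` (1/m^2), `sigma_m` (metres) and
#'   optionally `plane` (all rows must share one plane).
#' @param geometry List with `quad_length` (m) and `drift` (m), the distance
#'   from scan-quadrupole exit to the screen.
#' @param plane `"x"` or `"y"`; defaults to the `plane` column if present.
#' @return A [twiss()] object with attribute `"sigma_matrix"`.
#' @export
twiss_from_quad_scan <- function(points, geometry, plane = NULL) {
  if (is.null(plane)) {
    plane <- if (!is.null(points$plane)) as.character(points$plane[1]) else "x"
  }
  stop_invalid(plane %in% c("x", "y"), "plane must be 'x' or 'y'")
  if (!is.null(points$plane) && !all(points$plane == plane)) {
    stop_invalid(FALSE, "scan points mix planes; fit one plane at a time")
  }
  K <- points$K
  sig <- points$sigma_m
  stop_invalid(all(sig > 0), "measured sigmas must be positive")
  if (length(K) < 3 || length(unique(K)) < 3) {
    stop(errorCondition("quadrupole scan needs at least 3 distinct strengths",
                        class = c("vhee_underdetermined_fit", "error", "condition")))
  }
  X <- t(vapply(K, function(k) {
    M <- compose_transfer(list(quad_transfer(k, geometry$quad_length, plane),
                               drift_transfer(geometry$drift)))
    c(M[1, 1]^2, 2 * M[1, 1] * M[1, 2], M[1, 2]^2)
  }, numeric(3)))
  fit <- stats::lm.fit(X, sig^2)
  s <- unname(fit$coefficients)
  if (any(!is.finite(s))) {
    stop(errorCondition("degenerate quadrupole-scan design",
                        class = c("vhee_underdetermined_fit", "error", "condition")))
  }
  det_s <- s[1] * s[3] - s[2]^2
  if (!is.finite(det_s) || det_s <= 0 || s[1] <= 0) {
    stop(errorCondition("fitted sigma matrix is non-physical (emittance^2 <= 0)",
                        class = c("vhee_nonphysical_fit", "error", "condition")))
  }
  eps <- sqrt(det_s)
  tw <- twiss(alpha = -s[2] / eps, beta = s[1] / eps, emittance = eps)
  attr(tw, "sigma_matrix") <- c(s11 = unname(s[1]), s12 = unname(s[2]),
                                s22 = unname(s[3]))
  tw
}

#' Read a quadrupole-scan table
#'
#' @param path CSV file with columns `plane`, `K`, `sigma_m`.
#' @return A data frame.
#' @export
read_quad_scan <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_invalid(all(c("plane", "K", "sigma_m") %in% names(df)),
               "quad-scan CSV needs columns plane, K, sigma_m")
  df
}

# internal: invalid-argument condition used across the package
stop_invalid <- function(ok, msg) {
  if (!isTRUE(ok)) {
    stop(errorCondition(msg,
                        class = c("vhee_invalid_argument", "error", "condition")))
  }
  invisible(TRUE)
}
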