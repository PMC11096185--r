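# Beamline description: an ordered list of elements (quadrupoles, drifts,
# thin windows, phantom), each with a medium and an optional vacuum-pipe
# aperture, plus the beam block (energy, spread, entrance Twiss).

#' Construct a beamline element
#'
#' @param kind One of `"quad"`, `"drift"`, `"window"`, `"phantom"`.
#' @param length Element length in metres (>= 0).
#' @param medium Material name (see [material()]); the medium the beam
#'   traverses inside the element (inside a vacuum pipe this is `"vacuum"`).
#' @param K Normalised quadrupole strength in 1/m^2 (0 unless `kind="quad"`).
#' @param polarity +1 for a horizontally focusing quad (`K > 0` focuses x),
#'   -1 for vertically focusing; used by the optimizer's sign patterns.
#' @param pipe_radius Inner radius of the surrounding beampipe in metres, or
#'   `NA` if the element is not inside a pipe.
#' @param pipe_wall Pipe wall thickness in metres (metadata; particles
#'   reaching the inner wall are absorbed).
#' @param label Optional element name.
#' @param half_x,half_y Transverse half-apertures of a phantom in metres.
#' @return A list of class `beamline_element`.
#' @export
beamline_element <- function(kind, length, medium = "vacuum", K = 0,
                             polarity = 1, pipe_radius = NA_real_,
                             pipe_wall = NA_real_, label = kind,
                             half_x = NA_real_, half_y = NA_real_) {
  stop_invalid(kind %in% c("quad", "drift", "window", "phantom"),
               "unknown element kind")
  stop_invalid(is.finite(length) && length >= 0, "length must be >= 0")
  if (!is.na(pipe_radius)) {
    stop_invalid(pipe_radius > 0, "pipe_radius must be positive")
  }
  structure(list(kind = kind, length = length, medium = medium, K = K,
                 polarity = polarity, pipe_radius = pipe_radius,
                 pipe_wall = pipe_wall, label = label,
                 half_x = half_x, half_y = half_y),
            class = "beamline_element")
}

new_beamline <- function(elements, beam, name = "custom") {
  stop_invalid(length(elements) >= 1, "beamline needs at least one element")
  structure(list(elements = elements, beam = beam, name = name),
            class = "beamline")
}

#' @export
print.beamline <- function(x, ...) {
  cat(sprintf("<beamline '%s'>  %d elements, total length %.3f m\n",
              x$name, length(x$elements), beamline_length(x)))
  cat(sprintf("  beam: %.1f MeV (%.2f MeV rms spread)\n",
              x$beam$energy_MeV, x$beam$energy_spread_rms_MeV))
  for (el in x$elements) {
    cat(sprintf("  %-8s %-9s L=%7.4f m  medium=%-7s K=%8.3f  pipe_r=%s\n",
                el$kind, el$label, el$length, el$medium, el$K,
                ifelse(is.na(el$pipe_radius), "-",
                       sprintf("%.3f", el$pipe_radius))))
  }
  invisible(x)
}

#' Total beamline length in metres
#' @param bl A beamline.
#' @export
beamline_length <- function(bl) {
  sum(vapply(bl$elements, `[[`, numeric(1), "length"))
}

#' Indices of quadrupole elements
#' @param bl A beamline.
#' @export
quad_indices <- function(bl) {
  which(vapply(bl$elements, function(e) e$kind == "quad", logical(1)))
}

#' Set quadrupole strengths on a beamline
#'
#' @param bl A beamline.
#' @param K Numeric vector of strengths (1/m^2), one per quadrupole in beam
#'   order.
#' @return The updated beamline.
#' @export
set_quad_K <- function(bl, K) {
  qi <- quad_indices(bl)
  stop_invalid(length(K) == length(qi),
               "need one K per quadrupole in the beamline")
  for (j in seq_along(qi)) bl$elements[[qi[j]]]$K <- K[j]
  bl
}

#' Current quadrupole strengths
#' @param bl A beamline.
#' @export
get_quad_K <- function(bl) {
  vapply(bl$elements[quad_indices(bl)], `[[`, numeric(1), "K")
}

#' z position (m) of the phantom entrance, from the beamline start
#' @param bl A beamline.
#' @export
phantom_entrance_z <- function(bl) {
  lens <- vapply(bl$elements, `[[`, numeric(1), "length")
  ip <- which(vapply(bl$elements, function(e) e$kind == "phantom", logical(1)))
  stop_invalid(length(ip) == 1, "beamline must contain exactly one phantom")
  if (ip == 1) 0 else sum(lens[seq_len(ip - 1)])
}

#' Build a preset beamline
#'
#' Two presets are provided:
#'
#' * `"compact"`: a 2-m class focusing system — five 22.6 cm quadrupoles
#'   (QF1 QD1 QF2 QD2 QF3) separated by 25 cm drifts inside a stainless-steel
#'   vacuum pipe (3 mm wall, configurable inner radius), an 11 cm air gap,
#'   then a 30 x 30 x 30 cm water phantom. Default beam: 201 MeV, 2 MeV rms
#'   spread, round 0.5 mm sigma with small divergence.
#' * `"clear_like"`: the final six quadrupoles of a CLEAR-type user beamline —
#'   a triplet, a long drift, a doublet, the vacuum pipe ending at a 0.1 mm
#'   mylar exit window 139 cm after the last doublet quad, an in-air final
#'   quadrupole, 12 cm of air, a 0.1 mm Kapton entry window and a
#'   10 x 14 x 41 cm water tank. Pipe inner radius 1.9 cm. Default beam:
#'   201 MeV, 2 MeV rms spread, emittance artificially enlarged
#'   (screen-scattered), 1 mm entrance sigma.
#'
#' @param preset `"compact"` or `"clear_like"`.
#' @param pipe_radius_cm Inner beampipe radius in cm (compact default 1.9).
#' @param phantom_medium Medium filling the phantom: `"water"` (default),
#'   `"air"` or `"vacuum"` for medium-comparison studies.
#' @param beam Optional beam block overriding the preset default: a list with
#'   `energy_MeV`, `energy_spread_rms_MeV`, `twiss_x`, `twiss_y`.
#' @return A `beamline` object.
#' @export
build_beamline <- function(preset = c("compact", "clear_like"),
                           pipe_radius_cm = NULL,
                           phantom_medium = "water",
                           beam = NULL) {
  preset <- match.arg(preset)
  if (preset == "compact") {
    r <- (if (is.null(pipe_radius_cm)) 1.9 else pipe_radius_cm) / 100
    stop_invalid(r > 0, "pipe_radius_cm must be positive")
    qlen <- 0.226
    els <- list()
    labs <- c("QF1", "QD1", "QF2", "QD2", "QF3")
    pols <- c(1, -1, 1, -1, 1)
    for (i in 1:5) {
      els <- c(els, list(beamline_element("quad", qlen, "vacuum",
                                          polarity = pols[i], pipe_radius = r,
                                          pipe_wall = 0.003, label = labs[i])))
      if (i < 5) {
        els <- c(els, list(beamline_element("drift", 0.25, "vacuum",
                                            pipe_radius = r, pipe_wall = 0.003,
                                            label = paste0("D", i))))
      }
    }
    els <- c(els, list(
      beamline_element("drift", 0.11, "air", label = "airgap"),
      beamline_element("phantom", 0.30, phantom_medium, label = "phantom",
                       half_x = 0.15, half_y = 0.15)
    ))
    if (is.null(beam)) {
      beam <- list(energy_MeV = 201, energy_spread_rms_MeV = 2,
                   twiss_x = twiss(0, 20, 1.25e-8),
                   twiss_y = twiss(0, 20, 1.25e-8))
    }
    new_beamline(els, beam, name = sprintf("compact (pipe r=%.1f cm)", r * 100))
  } else {
    r <- (if (is.null(pipe_radius_cm)) 1.9 else pipe_radius_cm) / 100
    qlen <- 0.226
    pipe <- function(kind, len, label, polarity = 1) {
      beamline_element(kind, len, "vacuum", polarity = polarity,
                       pipe_radius = r, pipe_wall = 0.003, label = label)
    }
    els <- list(
      pipe("quad", qlen, "QT1", 1),
      pipe("drift", 0.35, "DT1"),
      pipe("quad", qlen, "QT2", -1),
      pipe("drift", 0.35, "DT2"),
      pipe("quad", qlen, "QT3", 1),
      pipe("drift", 9.0, "Dlong"),
      pipe("quad", qlen, "QDD870", -1),
      pipe("drift", 0.774, "DD1"),
      pipe("quad", qlen, "QF880", 1),
      pipe("drift", 1.39, "Dpipe_end"),
      beamline_element("window", 1e-4, "mylar", label = "exit_window"),
      beamline_element("drift", 2.384, "air", label = "air_transport"),
      beamline_element("quad", qlen, "air", polarity = -1, label = "QDD920"),
      beamline_element("drift", 0.12, "air", label = "air_to_tank"),
      beamline_element("window", 1e-4, "kapton", label = "tank_window"),
      beamline_element("phantom", 0.41, phantom_medium, label = "tank",
                       half_x = 0.05, half_y = 0.07)
    )
    if (is.null(beam)) {
      beam <- list(energy_MeV = 201, energy_spread_rms_MeV = 2,
                   twiss_x = twiss(0, 5, 2e-7),
                   twiss_y = twiss(0, 5, 2e-7))
    }
    new_beamline(els, beam, name = sprintf("clear_like (pipe r=%.1f cm)",
                                           r * 100))
  }
}

#' Read a beamline from a YAML/JSON configuration file
#'
#' The file has a `beam` block (`energy_MeV`, `energy_spread_rms_MeV` and per
#' plane `twiss_x: {alpha, beta, emittance}`, `twiss_y: ...`) and an
#' `elements` list; each element gives `kind`, `length_m`, optional `medium`,
#' `K` or `current_A`, `polarity`, `pipe_radius_m`, `pipe_wall_m`, `label`,
#' `half_x_m`, `half_y_m`. `current_A` is converted to K via Eq. of motion
#' constants ([current_to_K()]) using the beam energy.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `beamline` object.
#' @export
read_beamline <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  stop_invalid(!is.null(cfg$beam) && !is.null(cfg$elements),
               "config needs 'beam' and 'elements' blocks")
  b <- cfg$beam
  beam <- list(
    energy_MeV = as.numeric(b$energy_MeV),
    energy_spread_rms_MeV = as.numeric(b$energy_spread_rms_MeV %||% 0),
    twiss_x = twiss(b$twiss_x$alpha, b$twiss_x$beta, b$twiss_x$emittance),
    twiss_y = twiss(b$twiss_y$alpha, b$twiss_y$beta, b$twiss_y$emittance)
  )
  els <- lapply(cfg$elements, function(e) {
    K <- if (!is.null(e$K)) as.numeric(e$K)
         else if (!is.null(e$current_A)) {
           current_to_K(as.numeric(e$current_A), beam$energy_MeV)
         } else 0
    beamline_element(
      kind = e$kind, length = as.numeric(e$length_m),
      medium = e$medium %||% "vacuum", K = K,
      polarity = e$polarity %||% 1,
      pipe_radius = as.numeric(e$pipe_radius_m %||% NA_real_),
      pipe_wall = as.numeric(e$pipe_wall_m %||% NA_real_),
      label = e$label %||% e$kind,
      half_x = as.numeric(e$half_x_m %||% NA_real_),
      half_y = as.numeric(e$half_y_m %||% NA_real_)
    )
  })
  new_beamline(els, beam, name = cfg$name %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
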