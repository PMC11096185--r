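# End-to-end runs: configuration handling, canned studies and file outputs.
# Every run writes a manifest (config + seed + package version) sufficient
# to reproduce its outputs exactly.

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    cfg <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    attr(cfg, "dir") <- dirname(normalizePath(config))
    cfg
  } else if (is.list(config)) {
    config
  } else {
    stop_invalid(FALSE, "config must be a list or a file path")
  }
}

config_beamline <- function(cfg) {
  if (!is.null(cfg$lattice_file)) {
    base <- attr(cfg, "dir") %||% "."
    read_beamline(file.path(base, cfg$lattice_file))
  } else {
    bl <- build_beamline(cfg$preset %||% "compact",
                         pipe_radius_cm = cfg$pipe_radius_cm,
                         phantom_medium = cfg$phantom_medium %||% "water")
    if (!is.null(cfg$beam)) {
      b <- cfg$beam
      bl$beam <- list(
        energy_MeV = as.numeric(b$energy_MeV %||% bl$beam$energy_MeV),
        energy_spread_rms_MeV =
          as.numeric(b$energy_spread_rms_MeV %||%
                       bl$beam$energy_spread_rms_MeV),
        twiss_x = if (!is.null(b$twiss_x)) {
          twiss(b$twiss_x$alpha, b$twiss_x$beta, b$twiss_x$emittance)
        } else bl$beam$twiss_x,
        twiss_y = if (!is.null(b$twiss_y)) {
          twiss(b$twiss_y$alpha, b$twiss_y$beta, b$twiss_y$emittance)
        } else bl$beam$twiss_y)
    }
    if (!is.null(cfg$K)) bl <- set_quad_K(bl, as.numeric(unlist(cfg$K)))
    if (!is.null(cfg$currents_A)) {
      qi <- quad_indices(bl)
      pol <- vapply(bl$elements[qi], `[[`, numeric(1), "polarity")
      bl <- set_quad_K(bl, pol * abs(current_to_K(
        as.numeric(unlist(cfg$currents_A)), bl$beam$energy_MeV)))
    }
    bl
  }
}

config_settings <- function(cfg) {
  s <- cfg$mc %||% list()
  mc_settings(
    step_water_cm = as.numeric(s$step_water_cm %||% 0.1),
    step_air_cm = as.numeric(s$step_air_cm %||% 0.5),
    voxel_cm = as.numeric(s$voxel_cm %||% 0.1),
    lateral_half_cm = as.numeric(s$lateral_half_cm %||% 5),
    column_half_cm = as.numeric(s$column_half_cm %||% 0.15)
  )
}

write_manifest <- function(out_dir, cfg, seed, extra = list()) {
  man <- c(list(
    package = "vheefocus",
    version = as.character(utils::packageVersion("vheefocus")),
    seed = seed,
    config = cfg
  ), extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run one simulation: sample, transport, score, write curves
#'
#' Executes the full chain on the configured beamline and writes
#' `depth_dose.csv` (`z_cm, percent_dose`), `hwhm.csv`
#' (`depth_cm, hwhm_x_cm, hwhm_y_cm`) and `manifest.json` into `out_dir`.
#' The phantom medium may be `"water"`, `"air"` or `"vacuum"` for
#' medium-comparison studies (in vacuum a fluence proxy is scored, mimicking
#' films in a medium-free phantom).
#'
#' @param config A list or YAML/JSON path with fields `preset` or
#'   `lattice_file`, optional `pipe_radius_cm`, `phantom_medium`, `beam`,
#'   `K` or `currents_A`, `n`, `seed`, `mc` (step sizes), and for on-the-fly
#'   optimisation `optimize: {target_depth_cm, weight_x}`.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return Invisibly, a list with `curve`, `hwhm`, `peak_depth_cm`,
#'   `entrance_percent`, `n_alive`, `beamline`, `dose`.
#' @export
run_simulation <- function(config, out_dir = NULL) {
  cfg <- resolve_config(config)
  bl <- config_beamline(cfg)
  settings <- config_settings(cfg)
  n <- as.integer(cfg$n %||% 1e5)
  seed <- as.integer(cfg$seed %||% 1)
  if (!is.null(cfg$optimize)) {
    sol <- optimize_strengths(bl,
                              target_depth_cm =
                                as.numeric(cfg$optimize$target_depth_cm),
                              weight_x =
                                as.numeric(cfg$optimize$weight_x %||% 0.5))
    bl <- sol$beamline
  }
  r <- run_mc_once(bl, n, seed, settings)
  hw <- hwhm_vs_depth(r$dose, r$dose$z_centers[
    seq(1, length(r$dose$z_centers), by = 5)])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(z_cm = r$curve$depth_cm, percent_dose = r$curve$percent),
      file.path(out_dir, "depth_dose.csv"), row.names = FALSE)
    utils::write.csv(hw, file.path(out_dir, "hwhm.csv"), row.names = FALSE)
    write_manifest(out_dir, cfg, seed,
                   list(n = n, n_alive = r$n_alive,
                        peak_depth_cm = r$peak_depth_cm,
                        entrance_percent = r$entrance_percent,
                        quad_K = get_quad_K(bl)))
  }
  invisible(list(curve = r$curve, hwhm = hw,
                 peak_depth_cm = r$peak_depth_cm,
                 entrance_percent = r$entrance_percent,
                 n_alive = r$n_alive, beamline = bl, dose = r$dose))
}

#' Run a beampipe-radius study
#'
#' Optimises the preset once (unless `K` is supplied) and re-runs the Monte
#' Carlo per radius; writes `radius_study.csv`
#' (`radius_cm, peak_depth_cm, entrance_percent, surviving_fraction, seed`)
#' and a manifest.
#'
#' @param config List or file with `preset`, `radii_cm`, `n`, `seed`, and
#'   either `K` or `optimize: {target_depth_cm, pipe_radius_cm, weight_x}`.
#' @param out_dir Output directory or `NULL`.
#' @return Invisibly, the study data frame.
#' @export
run_radius_study <- function(config, out_dir = NULL) {
  cfg <- resolve_config(config)
  radii <- as.numeric(unlist(cfg$radii_cm))
  stop_invalid(length(radii) >= 1, "radii_cm must be non-empty")
  n <- as.integer(cfg$n %||% 1e5)
  seed <- as.integer(cfg$seed %||% 1)
  opt <- cfg$optimize %||% list(target_depth_cm = 15)
  bl0 <- build_beamline(cfg$preset %||% "compact",
                        pipe_radius_cm =
                          as.numeric(opt$pipe_radius_cm %||% 6))
  sol <- if (!is.null(cfg$K)) {
    bl <- set_quad_K(bl0, as.numeric(unlist(cfg$K)))
    structure(list(K = get_quad_K(bl), beamline = bl),
              class = "focus_solution")
  } else {
    optimize_strengths(bl0, as.numeric(opt$target_depth_cm),
                       weight_x = as.numeric(opt$weight_x %||% 0.5))
  }
  study <- if (length(radii) >= 2) {
    pipe_radius_study(sol, radii, preset = cfg$preset %||% "compact",
                      n = n, seed = seed, settings = config_settings(cfg))
  } else {
    bl <- build_beamline(cfg$preset %||% "compact", pipe_radius_cm = radii)
    bl <- set_quad_K(bl, sol$K)
    r <- run_mc_once(bl, n, seed, config_settings(cfg))
    data.frame(radius_cm = radii, peak_depth_cm = r$peak_depth_cm,
               entrance_percent = r$entrance_percent,
               surviving_fraction = r$n_alive / n, seed = seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(study, file.path(out_dir, "radius_study.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, cfg, seed, list(quad_K = sol$K))
  }
  invisible(study)
}

#' Analyse a stack of films
#'
#' Applies the film-dosimetry chain to each film: red-channel dose map,
#' maximum localisation on the smoothed map, on-axis dose and profile
#' HWHMs. The dose-versus-depth series is normalised to 100% at its
#' maximum. Films may be `film_image` objects or TIFF paths written by
#' [write_film()]; depths come from their `depth_mm` metadata (or the stack
#' spacing).
#'
#' @param films List of `film_image`s or character vector of TIFF paths.
#' @param curve A `calibration_curve` for the read-out channel.
#' @param spacing_mm Fallback film spacing when no depth metadata exists.
#' @param out_dir Output directory or `NULL`.
#' @param channel Read-out channel.
#' @param window Smoothing window in pixels (10 px at a 300 dpi scan
#'   corresponds to 0.85 mm; reduce it for coarser pixel pitches).
#' @return Invisibly, a data frame
#'   `depth_mm, on_axis_dose_Gy, percent_dose, hwhm_x_mm, hwhm_y_mm`.
#' @export
run_film_analysis <- function(films, curve, spacing_mm = 5, out_dir = NULL,
                              channel = "red", window = 10) {
  if (is.character(films)) films <- lapply(films, read_film)
  stop_invalid(length(films) >= 1, "need at least one film")
  rows <- lapply(seq_along(films), function(i) {
    f <- films[[i]]
    depth <- attr(f, "depth_mm") %||% ((i - 1) * spacing_mm)
    m <- film_dose_map(f, curve, channel)
    a <- tryCatch(analyze_film_map(m, window), error = function(e) {
      list(on_axis_dose_Gy = 0, hwhm_x_mm = NA_real_, hwhm_y_mm = NA_real_)
    })
    data.frame(depth_mm = depth, on_axis_dose_Gy = a$on_axis_dose_Gy,
               hwhm_x_mm = a$hwhm_x_mm, hwhm_y_mm = a$hwhm_y_mm)
  })
  out <- do.call(rbind, rows)
  mx <- max(out$on_axis_dose_Gy)
  out$percent_dose <- if (mx > 0) 100 * out$on_axis_dose_Gy / mx else 0
  out <- out[, c("depth_mm", "on_axis_dose_Gy", "percent_dose",
                 "hwhm_x_mm", "hwhm_y_mm")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "film_analysis.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, list(n_films = length(films),
                                 channel = channel,
                                 spacing_mm = spacing_mm), NA)
  }
  invisible(out)
}
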