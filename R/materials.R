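# Media traversed by the beam. Radiation lengths and collisional stopping
# powers are standard physical-data values near 200 MeV electron energy
# (PDG / ICRU tabulations); they are inputs to the condensed-history model,
# not fitted quantities.

#' Built-in materials table
#'
#' Columns: `name`, `density` (g/cm^3), `radiation_length_cm` (cm) and
#' `stopping_power_MeV_cm` (collisional, MeV/cm, near 200 MeV). Vacuum has an
#' infinite radiation length and zero stopping power.
#'
#' @param path Optional CSV with the same columns to use instead of the
#'   packaged table (`inst/extdata/materials.csv`).
#' @return Data frame of materials.
#' @export
material_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "materials.csv", package = "vheefocus")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$radiation_length_cm[df$name == "vacuum"] <- Inf
  df
}

#' Look up one material
#'
#' @param name Material name (case-insensitive), e.g. `"water"`, `"air"`,
#'   `"vacuum"`, `"pmma"`, `"kapton"`, `"mylar"`, `"steel"`.
#' @param table Materials data frame, defaults to [material_table()].
#' @return A list with `name`, `density`, `radiation_length_cm`,
#'   `stopping_power_MeV_cm`, class `material`.
#' @export
material <- function(name, table = material_table()) {
  i <- match(tolower(name), tolower(table$name))
  stop_invalid(!is.na(i), paste0("unknown material: ", name))
  structure(as.list(table[i, ]), class = "material")
}

is_vacuum <- function(mat) {
  tolower(mat$name) == "vacuum"
}
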