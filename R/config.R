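# Flat key-value configuration with [section] headers (INI dialect:
# `key = value`, `#`/`;` comments, "." decimal separator).  No installed
# package parses INI, so the ~30-line reader lives here; the schema check
# rejects unknown sections/keys so typos fail loudly before any
# computation.

reec_config_schema <- list(
  geometry   = c("r_inner_um", "r_outer_um", "height_um", "hole_diameter_um"),
  oxygen     = c("D_um2_s", "A_max_molecules_cell_s", "C_bulk_uM",
                 "half_saturation_uM"),
  glucose    = c("D_um2_s", "A_max_molecules_cell_s", "C_bulk_uM",
                 "half_saturation_uM"),
  consumers  = c("areal_density_cells_cm2"),
  column     = c("height_um", "C_top_uM"),
  simulation = c("t_end_s", "inspection_interval_s", "rms_tol", "spacing_um",
                 "output_interval_s"),
  profiling  = c("bin_width_um", "smooth_window", "front_fraction"),
  synth      = c("noise_sigma", "I_max", "background",
                 "density_cells_cm2", "image_scale_um_px", "psf_sigma_um",
                 "tile_amplitude", "tile_period_um")
)

#' Read a configuration file
#'
#' Reads the package's flat `[section] / key = value` configuration
#' format and validates every key against the known schema; unknown
#' sections or keys are rejected.  Values that parse as numbers become
#' numeric.
#'
#' @param path Path to the configuration file.
#' @return A named list of sections, each a named list of values, of
#'   class `reec_config`.
#' @seealso [default_config()] for the bundled reference parameter set.
#' @export
read_reec_config <- function(path) {
  if (!file.exists(path)) stop_reec("config file '", path, "' not found")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  cfg <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop_reec("config line ", i, " is not 'key = value': '", ln, "'")
    if (is.null(section))
      stop_reec("config line ", i, " appears before any [section]")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    cfg[[section]][[key]] <- if (!is.na(num)) num else val
  }
  validate_config(cfg)
  structure(cfg, class = "reec_config")
}

validate_config <- function(cfg) {
  for (sec in names(cfg)) {
    if (!sec %in% names(reec_config_schema))
      stop_reec("unknown config section '[", sec, "]'")
    bad <- setdiff(names(cfg[[sec]]), reec_config_schema[[sec]])
    if (length(bad))
      stop_reec("unknown key '", bad[1], "' in section '[", sec, "]'")
  }
  invisible(cfg)
}

#' Write a configuration file
#' @param cfg A `reec_config` list.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reec_config <- function(cfg, path) {
  validate_config(cfg)
  out <- character(0)
  for (sec in names(cfg)) {
    out <- c(out, paste0("[", sec, "]"))
    for (key in names(cfg[[sec]]))
      out <- c(out, paste0(key, " = ", format(cfg[[sec]][[key]],
                                              scientific = FALSE)))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Bundled reference configuration
#'
#' The default chamber geometry and transport parameter set (oxygen and
#' glucose diffusivities, measured per-cell consumption rates, boundary
#' concentrations, reference plating density) shipped with the package.
#'
#' @return A `reec_config` list.
#' @export
default_config <- function() {
  read_reec_config(system.file("extdata", "reec-defaults.ini",
                               package = "reec", mustWork = TRUE))
}

cfg_get <- function(cfg, section, key, default = NULL) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

#' Build model objects from a configuration
#'
#' Accessors turning a validated `reec_config` into the corresponding
#' model objects.
#'
#' @param cfg A `reec_config` from [read_reec_config()].
#' @param species `"oxygen"` or `"glucose"` for `cfg_species`.
#' @return `cfg_geometry`: a [chamber_geometry()]; `cfg_species`: a
#'   [transport_params()]; `cfg_consumers`: a [consumer_field()];
#'   `cfg_simulation`: a [simulation_config()]; `cfg_column`: a
#'   [column_spec()].
#' @export
cfg_geometry <- function(cfg) {
  chamber_geometry(
    r_inner = cfg_get(cfg, "geometry", "r_inner_um", 350),
    r_outer = cfg_get(cfg, "geometry", "r_outer_um", 6000),
    height = cfg_get(cfg, "geometry", "height_um", 100),
    hole_diameter = cfg_get(cfg, "geometry", "hole_diameter_um", 740.1))
}

#' @rdname cfg_geometry
#' @export
cfg_species <- function(cfg, species = "oxygen") {
  sec <- cfg[[species]]
  if (is.null(sec)) stop_reec("no [", species, "] section in config")
  Cb <- sec$C_bulk_uM
  transport_params(species, D = sec$D_um2_s,
                   A_max = sec$A_max_molecules_cell_s, C_bulk = Cb,
                   half_saturation = if (is.null(sec$half_saturation_uM))
                     Cb else sec$half_saturation_uM)
}

#' @rdname cfg_geometry
#' @export
cfg_consumers <- function(cfg) {
  consumer_field(
    areal_density = cfg_get(cfg, "consumers", "areal_density_cells_cm2", 2e5),
    height = cfg_get(cfg, "geometry", "height_um", 100))
}

#' @rdname cfg_geometry
#' @export
cfg_simulation <- function(cfg) {
  simulation_config(
    t_end = cfg_get(cfg, "simulation", "t_end_s", 172800),
    inspection_interval = cfg_get(cfg, "simulation", "inspection_interval_s",
                                  60),
    rms_tol = cfg_get(cfg, "simulation", "rms_tol", 0.001),
    spacing = cfg_get(cfg, "simulation", "spacing_um", 10))
}

#' @rdname cfg_geometry
#' @export
cfg_column <- function(cfg) {
  column_spec(column_height = cfg_get(cfg, "column", "height_um", 250),
              C_top = cfg_get(cfg, "column", "C_top_uM", 178),
              consumers = cfg_consumers(cfg),
              species = cfg_species(cfg, "oxygen"))
}
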