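#' Chamber geometry
#'
#' Geometry of a restricted exchange environment chamber (REEC).  The
#' simulation domain is the annulus between the aperture radius `r_inner`
#' and the chamber wall `r_outer`; `height` is the gap between the cell
#' monolayer and the chamber top.
#'
#' Defaults correspond to the reference chamber design: a ~0.74 mm aperture
#' drilled in a cover glass over a 12 mm inner-diameter O-ring, giving an
#' aperture radius of 350 um and an outer radius of 6000 um.  The nominal
#' spacer height is 100 um; the as-built mean height including the epoxy
#' layer is 138.4 um and is the value to use for interior-volume estimates.
#'
#' @param r_inner Aperture (opening) radius, um.
#' @param r_outer Chamber inner-wall radius, um.
#' @param height Chamber height, um.
#' @param hole_diameter Aperture diameter, um (bookkeeping only; the
#'   simulation uses `r_inner`).
#' @return An object of class `chamber_geometry`.
#' @examples
#' geom <- chamber_geometry()
#' chamber_volume(chamber_geometry(height = 138.4))  # ~15.65 uL
#' @export
chamber_geometry <- function(r_inner = 350, r_outer = 6000, height = 100,
                             hole_diameter = 740.1) {
  check_scalar(r_inner, "r_inner")
  check_scalar(r_outer, "r_outer")
  check_scalar(height, "height")
  check_scalar(hole_diameter, "hole_diameter")
  if (r_inner >= r_outer)
    stop_reec("'r_inner' (", r_inner, ") must be smaller than 'r_outer' (",
              r_outer, ")")
  structure(list(r_inner = r_inner, r_outer = r_outer, height = height,
                 hole_diameter = hole_diameter),
            class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat("REEC geometry: annulus", x$r_inner, "-", x$r_outer,
      "um, height", x$height, "um, aperture diameter", x$hole_diameter,
      "um\n")
  invisible(x)
}

#' Transport parameters for one molecular species
#'
#' Diffusivity, maximum per-cell consumption rate and boundary concentration
#' for a diffusing, cell-consumed species.  `half_saturation` is the
#' concentration at which the saturating uptake function reaches half its
#' maximum; the published rate law hard-wires it to `C_bulk`, which is kept
#' as the default but exposed as an explicit parameter.
#'
#' @param name Species label, e.g. `"oxygen"`.
#' @param D Diffusivity, um^2/s.
#' @param A_max Maximum per-cell consumption rate, molecules cell^-1 s^-1.
#' @param C_bulk Bulk (source) concentration, uM.
#' @param half_saturation Half-saturation concentration, uM; defaults to
#'   `C_bulk`.
#' @return An object of class `transport_params`.
#' @seealso [oxygen_params()], [glucose_params()] for the bundled defaults.
#' @export
transport_params <- function(name, D, A_max, C_bulk,
                             half_saturation = C_bulk) {
  if (!is.character(name) || length(name) != 1L)
    stop_reec("'name' must be a single string")
  check_scalar(D, "D")
  check_scalar(A_max, "A_max", allow_zero = TRUE)
  check_scalar(C_bulk, "C_bulk")
  check_scalar(half_saturation, "half_saturation")
  structure(list(name = name, D = D, A_max = A_max, C_bulk = C_bulk,
                 half_saturation = half_saturation),
            class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf("%s: D = %g um^2/s, A_max = %g molecules/cell/s, C_bulk = %g uM\n",
              x$name, x$D, x$A_max, x$C_bulk))
  invisible(x)
}

#' Reference oxygen transport parameters
#'
#' Oxygen in culture media at 37 C: D = 3370 um^2/s, A_max = 2.98e7
#' molecules cell^-1 s^-1 (mito-stress-test measurement on 4T1 mammary
#' carcinoma cells).  Air-saturated media at the top of the well holds
#' 178 uM dissolved oxygen; the concentration actually presented at the
#' chamber aperture is lower (171 uM by default, see [column_model()])
#' because the monolayer under the aperture consumes oxygen on its way in.
#'
#' @param C_bulk Aperture boundary concentration, uM (default 171).
#' @return A [transport_params()] object.
#' @export
oxygen_params <- function(C_bulk = 171) {
  transport_params("oxygen", D = 3370, A_max = 2.98e7, C_bulk = C_bulk)
}

#' Reference glucose transport parameters
#'
#' Glucose in culture media: D = 616 um^2/s, A_max = 6.47e7 molecules
#' cell^-1 s^-1, bulk concentration 25 mM (high-glucose DMEM).
#'
#' @param C_bulk Bulk concentration, uM (default 25000).
#' @return A [transport_params()] object.
#' @export
glucose_params <- function(C_bulk = 25000) {
  transport_params("glucose", D = 616, A_max = 6.47e7, C_bulk = C_bulk)
}

#' Consumer (cell) density field
#'
#' Converts an areal plating density to the volumetric consumer density
#' seen by the transport model, `n = areal density / chamber height`.
#' The default areal density, 2e5 cells/cm^2, is a confluent monolayer;
#' with a 100 um chamber this gives n = 2e-5 cells/um^3.
#'
#' @param areal_density Cells per cm^2.
#' @param height Chamber height over the monolayer, um.
#' @return An object of class `consumer_field` with fields
#'   `areal_density` (cells/cm^2), `height` (um) and the derived
#'   `volumetric_density` (cells/um^3).
#' @export
consumer_field <- function(areal_density = 2e5, height = 100) {
  check_scalar(areal_density, "areal_density", allow_zero = TRUE)
  check_scalar(height, "height")
  structure(list(
    areal_density = areal_density,
    height = height,
    volumetric_density = per_cm2_to_per_um2(areal_density) / height
  ), class = "consumer_field")
}

#' @export
print.consumer_field <- function(x, ...) {
  cat(sprintf("consumers: %g cells/cm^2 over %g um -> n = %g cells/um^3\n",
              x$areal_density, x$height, x$volumetric_density))
  invisible(x)
}

#' Media-column specification for the aperture boundary model
#'
#' Describes the column of media between the oxygen source (fully
#' oxygenated media above the chamber cover glass) and the cell monolayer
#' beneath the aperture, used by [column_model()].  The default 250 um
#' column is the 100 um chamber height plus a 150 um cover glass.
#'
#' @param column_height Column height L, um.
#' @param C_top Concentration at the top of the column, uM.
#' @param consumers A [consumer_field()].
#' @param species A [transport_params()].
#' @return An object of class `column_spec`.
#' @export
column_spec <- function(column_height = 250, C_top = 178,
                        consumers = consumer_field(),
                        species = oxygen_params()) {
  check_scalar(column_height, "column_height")
  check_scalar(C_top, "C_top")
  stopifnot(inherits(consumers, "consumer_field"),
            inherits(species, "transport_params"))
  structure(list(column_height = column_height, C_top = C_top,
                 consumers = consumers, species = species),
            class = "column_spec")
}

#' Per-cell consumption rate constant
#'
#' The rate constant k relating saturating uptake to the bulk
#' concentration, `A_max = k * C_bulk`, expressed as a clearance:
#' k = A_max / (N_A * C_bulk) in um^3 cell^-1 s^-1.  k is linear in
#' `A_max` and inversely proportional to `C_bulk`.
#'
#' @param species A [transport_params()] object.
#' @return k in um^3 cell^-1 s^-1.
#' @examples
#' per_cell_rate(oxygen_params())  # ~289 um^3/cell/s
#' @export
per_cell_rate <- function(species) {
  stopifnot(inherits(species, "transport_params"))
  if (species$C_bulk <= 0)
    stop_reec("'C_bulk' must be > 0 to calibrate the per-cell rate")
  molecules_to_mol(species$A_max) / uM_to_mol_um3(species$C_bulk)
}

#' Characteristic diffusion-consumption length
#'
#' The length scale lambda = sqrt(D / (n k)) over which a consumed species
#' decays away from its source at steady state.  Larger diffusivity or
#' sparser/slower consumers push lambda out; for reference oxygen
#' parameters at confluent density lambda is ~763 um.
#'
#' @param species A [transport_params()] object.
#' @param consumers A [consumer_field()] object.
#' @return lambda in um.  If the volumetric consumption rate `n * k` is
#'   zero the species is never consumed; `Inf` is returned with a warning.
#' @export
characteristic_length <- function(species, consumers = consumer_field()) {
  stopifnot(inherits(species, "transport_params"),
            inherits(consumers, "consumer_field"))
  nk <- consumers$volumetric_density * per_cell_rate(species)
  if (nk == 0) {
    warning("zero consumption: characteristic length is infinite")
    return(Inf)
  }
  sqrt(species$D / nk)
}

# Saturating uptake response f(C) = C_bulk * C / (C + Km), uM.
# Continuous at C = 0 with value 0; f(Km) = C_bulk / 2; f -> C_bulk as
# C -> Inf.  With the default Km = C_bulk, f(C) ~ C in the dilute limit.
saturating_response <- function(C, C_bulk, Km) {
  ifelse(C <= 0, 0, C_bulk * C / (C + Km))
}

#' Volumetric consumption rate at a given concentration
#'
#' The sink term of the transport model, `n * k * f(C)` with the
#' saturating response `f(C) = C_bulk * C / (C + Km)`, returned in uM/s.
#' It is monotone non-decreasing in C, zero at C = 0, and bounded above by
#' the saturation rate `n * k * C_bulk` (the volumetric equivalent of
#' `n * A_max`).
#'
#' @param C Concentration(s), uM.  Must be non-negative.
#' @param species A [transport_params()] object.
#' @param consumers A [consumer_field()] object.
#' @return Consumption rate(s), uM/s.
#' @export
consumption_term <- function(C, species, consumers = consumer_field()) {
  stopifnot(inherits(species, "transport_params"),
            inherits(consumers, "consumer_field"))
  if (any(!is.finite(C)) || any(C < 0))
    stop_reec("concentrations must be finite and >= 0")
  nk <- consumers$volumetric_density * per_cell_rate(species)
  nk * saturating_response(C, species$C_bulk, species$half_saturation)
}

#' Oxygen concentration at the cell layer beneath the aperture
#'
#' One-dimensional steady flux balance for the media column above the
#' monolayer under the chamber aperture, with consumption confined to the
#' bottom boundary (the cells).  At steady state the diffusive flux down
#' the column equals the areal consumption `J = sigma * A_max`, giving a
#' linear profile with cell-layer concentration `C_cell = C_top - J L / D`.
#' This is how the dynamic model's aperture boundary value (171 uM for
#' oxygen) is derived from the fully oxygenated value at the top of the
#' well (178 uM).
#'
#' @param spec A [column_spec()].
#' @return The cell-layer concentration in uM, with attributes `drop_uM`
#'   (the concentration drop down the column) and `clamped` (`TRUE` if the
#'   naive value was negative and was clamped to zero, meaning the cells
#'   would consume faster than the column can supply).
#' @examples
#' column_model(column_spec())  # ~170.7 uM, drop ~7.3 uM
#' @export
column_model <- function(spec = column_spec()) {
  stopifnot(inherits(spec, "column_spec"))
  sp <- spec$species
  if (sp$D <= 0) stop_reec("'D' must be > 0")
  sigma_um2 <- per_cm2_to_per_um2(spec$consumers$areal_density)
  J <- sigma_um2 * molecules_to_mol(sp$A_max)        # mol um^-2 s^-1
  drop <- mol_um3_to_uM(J * spec$column_height / sp$D)
  C_cell <- spec$C_top - drop
  clamped <- FALSE
  if (C_cell < 0) {
    warning("column model saturated: consumption exceeds diffusive supply; ",
            "cell-layer concentration clamped to 0")
    C_cell <- 0
    clamped <- TRUE
  }
  structure(C_cell, drop_uM = drop, clamped = clamped)
}

#' Chamber interior volume
#'
#' Volume of the cylindrical chamber interior, `pi * r_outer^2 * height`,
#' in uL.  With the as-built mean height of 138.4 um over a 12 mm
#' O-ring this is ~15.65 uL.
#'
#' @param geom A [chamber_geometry()].
#' @param height Optional height override in um (e.g. the as-built height
#'   when `geom` carries the nominal simulation height); may be zero.
#' @return Volume in uL.
#' @export
chamber_volume <- function(geom = chamber_geometry(), height = NULL) {
  stopifnot(inherits(geom, "chamber_geometry"))
  h <- if (is.null(height)) geom$height else
    check_scalar(height, "height", allow_zero = TRUE)
  um3_to_uL(pi * geom$r_outer^2 * h)
}
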