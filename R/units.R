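# Internal unit system: micrometres (length), seconds (time), micromolar
# (concentration), cells (amount of consumers).  Every quantity crossing the
# package boundary in another unit is converted here and nowhere else, because
# the published parameter set mixes unit systems (molecules per cell per
# second, cells per cm^2, mM, uM) and silent mixing is the main correctness
# risk in this kind of calculation.

#' Physical and unit-conversion constants
#'
#' Conversion factors used throughout the package.  The internal unit system
#' is \{um, s, uM, cells\}.
#'
#' * `avogadro`: molecules per mole, 6.02214076e23 (exact, 2019 SI).
#' * `um3_per_L`: 1e15 (1 L = 1e-3 m^3, 1 m^3 = 1e18 um^3).
#' * `um3_per_uL`: 1e9.
#' * `um2_per_cm2`: 1e8.
#'
#' A concentration of `c` uM equals `c * 1e-21` mol/um^3.
#'
#' @format A named list of numeric constants.
#' @export
reec_constants <- list(
  avogadro    = 6.02214076e23,
  um3_per_L   = 1e15,
  um3_per_uL  = 1e9,
  um2_per_cm2 = 1e8
)

# uM -> mol/um^3  (c * 1e-6 mol/L / 1e15 um^3/L)
uM_to_mol_um3 <- function(c_uM) c_uM * 1e-6 / reec_constants$um3_per_L

# mol/um^3 -> uM
mol_um3_to_uM <- function(c) c * reec_constants$um3_per_L / 1e-6

# molecules -> mol
molecules_to_mol <- function(n) n / reec_constants$avogadro

# cells/cm^2 -> cells/um^2
per_cm2_to_per_um2 <- function(s) s / reec_constants$um2_per_cm2

# um^3 -> uL
um3_to_uL <- function(v) v / reec_constants$um3_per_uL

stop_reec <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = TRUE, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_reec("'", name, "' must be a single finite number")
  if (positive && !allow_zero && x <= 0)
    stop_reec("'", name, "' must be > 0 (got ", format(x), ")")
  if (positive && allow_zero && x < 0)
    stop_reec("'", name, "' must be >= 0 (got ", format(x), ")")
  x
}
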