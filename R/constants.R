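# Physical constants (CODATA 2018). The gas constant is carried in two unit
# systems: J·mol^-1·K^-1 for thermal (Eyring/Arrhenius) terms and
# cm^3·bar·mol^-1·K^-1 for pressure terms, so that activation volumes in
# cm^3·mol^-1 and pressures in bar combine without conversion factors.
.const <- list(
  kB      = 1.380649e-23,    # Boltzmann constant, J K^-1
  h       = 6.62607015e-34,  # Planck constant, J s
  hbar    = 1.054571817e-34, # reduced Planck constant, J s
  R_J     = 8.31446,         # gas constant, J mol^-1 K^-1
  R_bar   = 83.1446          # gas constant, cm^3 bar mol^-1 K^-1
)

#' Physical constants used throughout the package
#'
#' Returns the CODATA-based constants used by the forward models and fitting
#' routines. The gas constant is provided both in SI thermal units
#' (`R_J`, J·mol⁻¹·K⁻¹) and in pressure-volume units
#' (`R_bar`, cm³·bar·mol⁻¹·K⁻¹ = 83.1446), the latter matching the units in
#' which activation volumes (cm³·mol⁻¹) and activation compressibilities
#' (cm³·mol⁻¹·kbar⁻¹) are conventionally reported.
#'
#' @return A named list with elements `kB`, `h`, `hbar` (J-based CODATA
#'   values), `R_J` and `R_bar`.
#' @examples
#' physical_constants()$R_bar
#' @export
physical_constants <- function() .const

# default experimental temperature: 25 degrees C
.default_T <- 298.15
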