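#' Unit system used throughout the 0D model
#'
#' All lumped-parameter element equations are evaluated in clinical units:
#' volumes in mL, flows in mL/s, pressures in mmHg, areas in cm2, time in s,
#' blood density in g/cm3. The valve/stenosis pressure-gradient formulas are
#' native to CGS (dyn/cm2) and are converted with [dyn_cm2_to_mmhg()].
#'
#' @format A named list with elements
#' \describe{
#'   \item{rho_blood}{blood density, 1.05 g/cm3 (= 1050 kg/m3)}
#'   \item{mu_blood}{dynamic viscosity of blood, 0.0035 Pa.s}
#'   \item{dyn_per_mmhg}{1 mmHg = 1333.22 dyn/cm2}
#'   \item{pa_per_mmhg}{1 mmHg = 133.322 Pa}
#' }
#' @export
blood_constants <- list(
  rho_blood    = 1.05,     # g/cm3
  mu_blood     = 0.0035,   # Pa.s
  dyn_per_mmhg = 1333.22,  # dyn/cm2 per mmHg
  pa_per_mmhg  = 133.322   # Pa per mmHg
)

#' Convert a stress/pressure from dyn/cm2 to mmHg
#' @param x pressure in dyn/cm2
#' @return pressure in mmHg
#' @export
dyn_cm2_to_mmhg <- function(x) x / blood_constants$dyn_per_mmhg

#' Convert a stress/pressure from mmHg to Pa
#' @param x pressure in mmHg
#' @return pressure in Pa
#' @export
mmhg_to_pa <- function(x) x * blood_constants$pa_per_mmhg

#' Convert an SI hydraulic resistance (Pa.s/m3) to clinical units (mmHg.s/mL)
#' @param r_si resistance in Pa.s/m3
#' @return resistance in mmHg.s/mL
#' @export
resistance_si_to_clinical <- function(r_si) {
  # Pa -> mmHg: /133.322 ; m3 -> mL: /1e6
  r_si / blood_constants$pa_per_mmhg / 1e6
}
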