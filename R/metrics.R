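# Clinical hemodynamic indices: simplified-Bernoulli Doppler gradients,
# systemic arterial compliance, and per-beat flow bookkeeping.

#' Peak Doppler pressure gradient (simplified Bernoulli)
#'
#' `dP = 4 Vmax^2`, the clinical estimate of the peak trans-stenotic
#' pressure gradient from the maximum velocity downstream of the
#' coarctation during systole.
#'
#' @param v_max peak velocity, m/s
#' @return gradient, mmHg
#' @export
doppler_peak_gradient <- function(v_max) {
  if (any(v_max < 0)) stop("v_max must be >= 0", call. = FALSE)
  4 * v_max^2
}

#' Peak velocity implied by a simplified-Bernoulli gradient
#'
#' Inverse of [doppler_peak_gradient()]: `Vmax = sqrt(dP / 4)`.
#'
#' @param dp gradient, mmHg
#' @return velocity, m/s
#' @export
peak_velocity_from_gradient <- function(dp) {
  if (any(dp < 0)) stop("gradient must be >= 0", call. = FALSE)
  sqrt(dp / 4)
}

#' Systemic arterial compliance
#'
#' `SAC = SV / (SBP - DBP)`: total stroke volume over pulse pressure.
#' Pulse pressure is systolic minus diastolic; a negative compliance is
#' non-physical.
#'
#' @param sv total stroke volume, mL
#' @param sbp,dbp systolic/diastolic brachial pressure, mmHg
#' @return compliance, mL/mmHg
#' @export
systemic_arterial_compliance <- function(sv, sbp, dbp) {
  if (any(sbp == dbp)) stop("pulse pressure is zero", call. = FALSE)
  sv / (sbp - dbp)
}

#' Mean relative error between simulated and measured values
#'
#' `mean(|sim - ref| / ref)`.
#'
#' @param sim,ref equal-length numeric vectors; `ref` values must be > 0
#' @return mean relative error (fraction)
#' @export
mean_relative_error <- function(sim, ref) {
  if (length(sim) != length(ref)) stop("length mismatch", call. = FALSE)
  if (any(ref <= 0)) stop("reference values must be > 0", call. = FALSE)
  mean(abs(sim - ref) / ref)
}

#' Per-beat stroke volumes from simulated waveforms
#'
#' Trapezoidal per-beat integrals of the aortic-valve, upper-body branch,
#' trans-coarctation and graft flows over the final (steady) cycle.
#'
#' @param waves a `cycle_waveforms` object from [simulate_circuit()]
#' @return named vector (total, branch, coa, graft), mL, with attribute
#'   `steady` (FALSE raises a warning, not an error)
#' @export
stroke_volumes <- function(waves) {
  stopifnot(inherits(waves, "cycle_waveforms"))
  if (!waves$converged)
    warning("waveforms are not at steady state; stroke volumes are approximate")
  w <- waves$waves
  out <- c(total = .trapz(w$time, w$q_av),
           branch = .trapz(w$time, w$q_ub),
           coa = .trapz(w$time, w$q_coa),
           graft = .trapz(w$time, w$q_graft))
  attr(out, "steady") <- waves$converged
  out
}

#' Hemodynamic summary of a steady simulation
#'
#' @param waves a `cycle_waveforms` object
#' @return a `hemodynamic_summary` list: sbp, dbp (mmHg), sac (mL/mmHg),
#'   total/branch/coa/graft stroke volumes (mL), peak trans-coarctation
#'   gradient (mmHg) taken as the cycle maximum of the coarctation element's
#'   net pressure drop
#' @export
hemodynamic_summary <- function(waves) {
  stopifnot(inherits(waves, "cycle_waveforms"))
  s <- waves$cycle_summary[waves$cycles_run, ]
  sv <- stroke_volumes(waves)
  w <- waves$waves
  # net drop across the coarctation branch, excluding the proximal resistance
  p <- waves$params
  dp_coa <- (w$p_apost - w$p_sa) - p$r_pda * w$q_coa
  out <- list(sbp = s$sbp, dbp = s$dbp,
              sac = systemic_arterial_compliance(sv[["total"]], s$sbp, s$dbp),
              total_sv = sv[["total"]], branch_sv = sv[["branch"]],
              coa_sv = sv[["coa"]], graft_sv = sv[["graft"]],
              peak_coa_gradient = max(dp_coa))
  class(out) <- "hemodynamic_summary"
  out
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat(sprintf("<hemodynamic_summary> SBP/DBP %.1f/%.1f mmHg, SAC %.2f mL/mmHg\n",
              x$sbp, x$dbp, x$sac))
  cat(sprintf("  SV total %.1f = branch %.1f + coa %.1f + graft %.1f mL\n",
              x$total_sv, x$branch_sv, x$coa_sv, x$graft_sv))
  cat(sprintf("  peak trans-COA gradient %.2f mmHg\n", x$peak_coa_gradient))
  invisible(x)
}

#' Published bypass-graft cohort table
#'
#' The printed hemodynamic table of the three-patient bypass-graft cohort
#' this package models: brachial pressures, peak Doppler gradients, systemic
#' arterial compliances, per-branch stroke volumes, peak downstream
#' velocities, and graft geometry, for each patient in pre- and
#' post-intervention state.
#'
#' @return a data.frame, one row per patient-state
#' @export
bypass_cohort <- function() {
  utils::read.csv(system.file("extdata", "bypass_cohort.csv",
                              package = "coaflow"),
                  stringsAsFactors = FALSE)
}

#' Arithmetic self-consistency audit of the cohort table
#'
#' Recomputes every derived cell of [bypass_cohort()] from its printed
#' inputs: the peak Doppler gradient from the printed peak velocity
#' (`4 Vmax^2`) and the systemic arterial compliance from the printed stroke
#' volume and pressures (`SV / (SBP - DBP)`), plus the per-branch flow
#' bookkeeping (total SV vs. sum of branch flows). A derived cell is
#' `consistent` when the recomputed value agrees with the printed one within
#' half a unit of the printed cell's last digit; discrepant cells are
#' flagged, never forced to match.
#'
#' @param tol_last_digit agreement tolerance in units of the printed cell's
#'   last decimal (default 0.5, i.e. standard rounding)
#' @return a data.frame with one row per derived cell: patient, status,
#'   quantity, printed, recomputed, tol, consistent
#' @export
audit_cohort_consistency <- function(tol_last_digit = 0.5) {
  tb <- bypass_cohort()
  rows <- list()
  for (i in seq_len(nrow(tb))) {
    r <- tb[i, ]
    # Bernoulli gradient from printed velocity
    g <- doppler_peak_gradient(r$vmax_ms)
    tolg <- tol_last_digit * 10^(-r$peak_gradient_digits)
    rows[[length(rows) + 1]] <- data.frame(
      patient = r$patient, status = r$status, quantity = "peak_gradient_mmhg",
      printed = r$peak_gradient_mmhg, recomputed = g, tol = tolg,
      consistent = abs(g - r$peak_gradient_mmhg) <= tolg)
    # SAC from printed SV and pressures
    sac <- systemic_arterial_compliance(r$total_sv_ml, r$sbp_mmhg, r$dbp_mmhg)
    tols <- tol_last_digit * 10^(-r$sac_digits)
    rows[[length(rows) + 1]] <- data.frame(
      patient = r$patient, status = r$status, quantity = "sac_ml_mmhg",
      printed = r$sac_ml_mmhg, recomputed = sac, tol = tols,
      consistent = abs(sac - r$sac_ml_mmhg) <= tols)
    # flow bookkeeping: total vs sum of branches (1 percent tolerance)
    ssum <- sum(c(r$branch_sv_ml, r$coa_sv_ml, r$graft_sv_ml), na.rm = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      patient = r$patient, status = r$status, quantity = "total_sv_ml",
      printed = r$total_sv_ml, recomputed = ssum,
      tol = 0.01 * r$total_sv_ml,
      consistent = abs(ssum - r$total_sv_ml) <= 0.01 * r$total_sv_ml)
  }
  do.call(rbind, rows)
}
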