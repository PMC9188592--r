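#' Double-Hill elastance parameter set
#'
#' Time-varying elastance of a heart chamber in double-Hill form: a rising
#' Hill factor with exponent `m1` and time scale `tau1` multiplied by a
#' decaying factor with exponent `m2` and time scale `tau2`, scaled by
#' `N = (e_max - e_min)/2` and offset by `e_min`. The scaling is implemented
#' literally (no renormalization forcing the curve maximum to `e_max`), so the
#' realized peak elastance is `N * max(H1*H2) + e_min`.
#'
#' @param e_max,e_min maximum / minimum elastance, mmHg/mL
#' @param m1,m2 ascending / descending Hill gradients (dimensionless)
#' @param tau1_frac,tau2_frac ascending / descending time translations as
#'   fractions of the cycle duration `T`
#' @param T cardiac cycle duration, s
#' @return an object of class `elastance_params`
#' @export
elastance_params <- function(e_max, e_min, m1, m2, tau1_frac, tau2_frac, T) {
  if (!(e_max > e_min && e_min > 0)) stop("need e_max > e_min > 0", call. = FALSE)
  if (!(m1 > 0 && m2 > 0)) stop("need m1, m2 > 0", call. = FALSE)
  if (!(tau1_frac > 0 && tau2_frac > tau1_frac && tau2_frac * T < T))
    stop("need 0 < tau1 < tau2 < T", call. = FALSE)
  structure(list(e_max = e_max, e_min = e_min, m1 = m1, m2 = m2,
                 tau1 = tau1_frac * T, tau2 = tau2_frac * T, T = T),
            class = "elastance_params")
}

#' Left-ventricular elastance constants (double-Hill)
#'
#' Standard LV values: e_max 2.1, e_min 0.06 mmHg/mL, m1 1.32, m2 27.4,
#' tau1 0.269 T, tau2 0.452 T.
#' @param T cycle duration, s
#' @return an `elastance_params` object
#' @export
lv_elastance_defaults <- function(T) {
  elastance_params(2.1, 0.06, 1.32, 27.4, 0.269, 0.452, T)
}

#' Left-atrial elastance constants (double-Hill)
#'
#' Standard LA values: e_max 0.17, e_min 0.06 mmHg/mL, m1 1.32, m2 13.1,
#' tau1 0.110 T, tau2 0.18 T.
#' @param T cycle duration, s
#' @return an `elastance_params` object
#' @export
la_elastance_defaults <- function(T) {
  elastance_params(0.17, 0.06, 1.32, 13.1, 0.110, 0.18, T)
}

#' Normalized time-varying elastance (double-Hill)
#'
#' `E(t) = N * [(t/tau1)^m1 / (1 + (t/tau1)^m1)] * [1 / (1 + (t/tau2)^m2)]
#'  + e_min`, with `N = (e_max - e_min)/2`. Time is wrapped modulo the cycle
#' duration, so the curve is periodic.
#'
#' @param t time, s (vectorized)
#' @param p an [elastance_params()] object
#' @return elastance, mmHg/mL
#' @export
normalized_elastance <- function(t, p) {
  t <- t %% p$T
  N <- (p$e_max - p$e_min) / 2
  h1 <- (t / p$tau1)^p$m1
  N * (h1 / (1 + h1)) / (1 + (t / p$tau2)^p$m2) + p$e_min
}

#' Chamber pressure from elastance and volume
#'
#' `P = E(t) * (V - V0)`; may transiently be negative during filling.
#'
#' @param e_t elastance, mmHg/mL
#' @param v chamber volume, mL
#' @param v0 unloaded volume, mL
#' @return pressure, mmHg
#' @export
chamber_pressure <- function(e_t, v, v0) e_t * (v - v0)

#' Energy loss coefficient of an orifice
#'
#' `E_L Co = EOA * A / (A - EOA)`: the effective downstream-recovery-corrected
#' area of a valve or stenosis with effective orifice area `EOA` opening into
#' a reference area `A`.
#'
#' @param eoa effective orifice area, cm2
#' @param a_ref downstream/reference cross-sectional area, cm2
#' @return energy loss coefficient, cm2
#' @export
energy_loss_coefficient <- function(eoa, a_ref) {
  if (any(eoa <= 0) || any(eoa >= a_ref))
    stop("degenerate orifice: need 0 < eoa < a_ref", call. = FALSE)
  eoa * a_ref / (a_ref - eoa)
}

#' Net transvalvular pressure gradient (energy-loss formulation)
#'
#' `PG_net = 2 pi rho / sqrt(E_L Co) * dQ/dt + rho / (2 E_L Co^2) * Q^2`,
#' evaluated in CGS and converted to mmHg. The convective term is applied as
#' `Q |Q|` so the gradient is odd in the flow direction.
#'
#' @param q flow, mL/s
#' @param dq_dt flow derivative, mL/s2
#' @param el_co energy loss coefficient, cm2
#' @param rho blood density, g/cm3
#' @return net pressure gradient, mmHg
#' @export
valve_net_pg <- function(q, dq_dt, el_co, rho = blood_constants$rho_blood) {
  if (any(el_co <= 0)) stop("el_co must be > 0", call. = FALSE)
  dyn_cm2_to_mmhg(2 * pi * rho / sqrt(el_co) * dq_dt +
                    rho / (2 * el_co^2) * q * abs(q))
}

#' Net mitral pressure gradient (inertance formulation)
#'
#' `PG_net = M_MV / EOA * dQ/dt + rho / (2 EOA^2) * Q^2` (CGS, converted to
#' mmHg). `m_mv` is the mitral inertance constant (default 0.53 g/cm2).
#'
#' @param q flow, mL/s
#' @param dq_dt flow derivative, mL/s2
#' @param eoa effective orifice area, cm2
#' @param m_mv inertance, g/cm2
#' @param rho blood density, g/cm3
#' @return net pressure gradient, mmHg
#' @export
mitral_net_pg <- function(q, dq_dt, eoa, m_mv = 0.53,
                          rho = blood_constants$rho_blood) {
  if (any(eoa <= 0)) stop("eoa must be > 0", call. = FALSE)
  if (any(m_mv < 0)) stop("m_mv must be >= 0", call. = FALSE)
  dyn_cm2_to_mmhg(m_mv / eoa * dq_dt + rho / (2 * eoa^2) * q * abs(q))
}

#' Trans-coarctation net pressure gradient
#'
#' The valve energy-loss formulation evaluated with the coarctation energy
#' loss coefficient `EOA_coa * A / (A - EOA_coa)`, `A` the aortic area
#' downstream of the stenosis.
#'
#' @param q trans-coarctation flow, mL/s
#' @param dq_dt flow derivative, mL/s2
#' @param eoa_coa coarctation effective orifice area, cm2
#' @param a_downstream aortic area downstream of the coarctation, cm2
#' @param rho blood density, g/cm3
#' @return net pressure gradient, mmHg
#' @export
coa_net_pg <- function(q, dq_dt, eoa_coa, a_downstream,
                       rho = blood_constants$rho_blood) {
  valve_net_pg(q, dq_dt, energy_loss_coefficient(eoa_coa, a_downstream), rho)
}

#' Pulmonary-valve inflow waveform
#'
#' Rectified sine: `Q(t) = q_mpv * sin(pi t / t_ee)` for `t <= t_ee`, zero for
#' the rest of the cycle; periodic in `T`. Its per-cycle integral is
#' `2 q_mpv t_ee / pi`.
#'
#' @param t time, s (vectorized)
#' @param q_mpv peak flow amplitude, mL/s
#' @param t_ee end-ejection time, s
#' @param T cycle duration, s
#' @return inflow, mL/s
#' @export
pulmonary_inflow <- function(t, q_mpv, t_ee, T) {
  if (!(t_ee > 0 && t_ee <= T)) stop("need 0 < t_ee <= T", call. = FALSE)
  t <- t %% T
  ifelse(t <= t_ee, q_mpv * sin(pi * t / t_ee), 0)
}
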