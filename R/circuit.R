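# 0D circulation model: left heart + systemic circuit with coarctation and
# optional bypass-graft branch.
#
# Topology: pulmonary inflow (rectified sine) -> LA (elastance) -> mitral
# valve -> LV (elastance) -> aortic valve -> aortic node (C_ao to ground,
# R_ao in series) -> bifurcation feeding (i) upper-body resistance R_ub,
# (ii) proximal-descending resistance R_pda in series with the coarctation
# element, (iii) the graft resistance (post state only); the three branches
# reconverge at the systemic node (C_SAC), then R_SA -> R_SV -> constant
# central venous pressure P_CV0. Regurgitant conduits (AR, MR) run antiparallel
# to their valves when their effective orifice areas are nonzero.
#
# State vector: v_lv, v_la [mL]; p_ao, p_sa [mmHg]; q_av, q_mv, q_coa, q_ar,
# q_mr [mL/s]. Valve conduits are ideal diodes: each inertial flow ODE is
# integrated while its flow is positive or its opening gradient favorable;
# a zero crossing from above is localized by step bisection and the conduit
# is clamped shut until the gradient is favorable again.

.elco_cap <- 2000  # cm2; an effectively absent stenosis (gradient well under 1 mmHg)

#' Assemble lumped-parameter circuit parameters from a patient record
#'
#' Converts the clinical measurements into the resistances, compliances,
#' elastance chambers and valve/stenosis elements of the 0D model, with the
#' standard initial values for the parameters that are later calibrated
#' (C_ao 0.5 mL/mmHg, C_SAC 2 mL/mmHg, R_SA 0.8 mmHg.s/mL) and constants
#' R_ao = R_SV = R_pda = 0.05 mmHg.s/mL, P_CV0 = 4 mmHg, mitral inertance
#' 0.53 g/cm2. The pulmonary-valve amplitude `q_mpv` starts at the value
#' whose rectified-sine integral equals the measured forward LVOT stroke
#' volume; calibration refines it. The pulmonary ladder constants are carried
#' as inert documented constants (`$pulmonary_ladder`): a sensitivity analysis
#' in the source model family found them to have negligible effect, so they
#' are not dynamically simulated.
#'
#' @param record a [patient_record()]
#' @param v0_lv,v0_la unloaded chamber volumes, mL
#' @param atrial_kick_frac LA-before-LV activation offset as a fraction of T
#' @param graft_inertance unused switch kept for completeness; the graft is a
#'   pure Poiseuille resistance by default
#' @return an object of class `circuit_params`
#' @export
circuit_params_from_record <- function(record, v0_lv = 10, v0_la = 5,
                                       atrial_kick_frac = 0.12,
                                       graft_inertance = FALSE) {
  stopifnot(inherits(record, "patient_record"))
  d <- record$doppler
  T <- d$cycle_duration_T
  rho <- blood_constants$rho_blood
  k_dyn <- blood_constants$dyn_per_mmhg

  elco_av <- energy_loss_coefficient(d$eoa_av, d$a_ao)
  elco_coa <- if (d$eoa_coa >= 0.999 * d$a_downstream_coa) .elco_cap else
    min(.elco_cap, energy_loss_coefficient(d$eoa_coa, d$a_downstream_coa))
  elco_ar <- if (d$eoa_ar > 0) energy_loss_coefficient(d$eoa_ar, d$a_lvot) else NA_real_

  valve_coef <- function(elco) {
    list(k1 = 2 * pi * rho / sqrt(elco) / k_dyn,   # mmHg per (mL/s2)
         k2 = rho / (2 * elco^2) / k_dyn)          # mmHg per (mL/s)^2
  }
  mitral_coef <- function(eoa, m_mv = 0.53) {
    list(k1 = m_mv / eoa / k_dyn, k2 = rho / (2 * eoa^2) / k_dyn)
  }

  p <- list(
    state = record$state,
    T = T, t_ee = d$ejection_time,
    q_mpv = pi * d$forward_lvot_sv / (2 * d$ejection_time),
    r_ao = 0.05, r_sv = 0.05, r_sa = 0.8, r_pda = 0.05,
    r_ub = 1.0,
    r_graft = if (record$state == "post") graft_resistance(record$graft) else NA_real_,
    graft_present = record$state == "post",
    c_ao = 0.5, c_sac = 2.0,
    p_cv0 = 4.0,
    lv = list(el = lv_elastance_defaults(T), v0 = v0_lv),
    la = list(el = la_elastance_defaults(T), v0 = v0_la),
    atrial_kick = atrial_kick_frac * T,
    av = valve_coef(elco_av),
    coa = valve_coef(elco_coa),
    ar = if (d$eoa_ar > 0) valve_coef(elco_ar) else NULL,
    mv = mitral_coef(d$eoa_mv),
    mr = if (d$eoa_mr > 0) mitral_coef(d$eoa_mr) else NULL,
    eoa_coa = d$eoa_coa, a_downstream_coa = d$a_downstream_coa,
    pulmonary_ladder = c(l_pv = 5e-4, r_pv = 0.002, r_pvc = 0.001, c_pvc = 40,
                         l_pc = 3e-4, r_pc = 0.21, r_pa = 0.01, c_pa = 4),
    record = record
  )
  class(p) <- "circuit_params"
  p
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params> state:", x$state, "\n")
  cat(sprintf("  T %.3f s, q_mpv %.1f mL/s, R_sa %.3f, C_sac %.2f, C_ao %.2f, R_ub %.3f\n",
              x$T, x$q_mpv, x$r_sa, x$c_sac, x$c_ao, x$r_ub))
  if (x$graft_present)
    cat(sprintf("  graft resistance %.4g mmHg.s/mL\n", x$r_graft))
  invisible(x)
}

# indices into the state vector
.iy <- c(v_lv = 1L, v_la = 2L, p_ao = 3L, p_sa = 4L,
         q_av = 5L, q_mv = 6L, q_coa = 7L, q_ar = 8L, q_mr = 9L)

#' Time derivatives of the circuit state
#'
#' Evaluates the right-hand side of the 0D model at time `t` for state `y`
#' (named as in `coaflow:::.iy`) under valve activity flags `act` (named
#' logical: av, mv, ar, mr). Inactive conduits contribute zero flow and zero
#' derivative. Returns the derivative vector with the auxiliary signals
#' (p_lv, p_la, p_apost, q_ub, q_graft, q_pv) as an attribute.
#'
#' @param state numeric state vector (v_lv, v_la, p_ao, p_sa, q_av, q_mv,
#'   q_coa, q_ar, q_mr)
#' @param t time, s
#' @param params a [circuit_params_from_record()] object
#' @param act named logical vector of valve activity flags
#' @return derivative vector `d(state)/dt` with attribute `aux`
#' @export
assemble_derivatives <- function(state, t, params, act = c(av = TRUE, mv = TRUE,
                                                           ar = FALSE, mr = FALSE)) {
  p <- params
  y <- state
  if (any(!is.finite(y)))
    stop("integration failure: non-finite state in ",
         paste(names(.iy)[!is.finite(y)], collapse = ","), call. = FALSE)
  v_lv <- y[1L]; v_la <- y[2L]; p_ao <- y[3L]; p_sa <- y[4L]
  q_av <- y[5L]; q_mv <- y[6L]; q_coa <- y[7L]; q_ar <- y[8L]; q_mr <- y[9L]

  e_lv <- normalized_elastance(t, p$lv$el)
  e_la <- normalized_elastance(t + p$atrial_kick, p$la$el)
  p_lv <- e_lv * (v_lv - p$lv$v0)
  p_la <- e_la * (v_la - p$la$v0)

  g_par <- 1 / p$r_ub + if (p$graft_present) 1 / p$r_graft else 0
  p_apost <- (p_ao / p$r_ao + p_sa * g_par - q_coa) / (1 / p$r_ao + g_par)
  q_ub <- (p_apost - p_sa) / p$r_ub
  q_graft <- if (p$graft_present) (p_apost - p_sa) / p$r_graft else 0
  q_pv <- pulmonary_inflow(t, p$q_mpv, p$t_ee, p$T)
  q_sys_out <- (p_sa - p$p_cv0) / (p$r_sa + p$r_sv)

  dq_av <- if (act[["av"]])
    (p_lv - p_ao - p$av$k2 * q_av * abs(q_av)) / p$av$k1 else 0
  dq_mv <- if (act[["mv"]])
    (p_la - p_lv - p$mv$k2 * q_mv * abs(q_mv)) / p$mv$k1 else 0
  dq_ar <- if (!is.null(p$ar) && act[["ar"]])
    (p_ao - p_lv - p$ar$k2 * q_ar * abs(q_ar)) / p$ar$k1 else 0
  dq_mr <- if (!is.null(p$mr) && act[["mr"]])
    (p_lv - p_la - p$mr$k2 * q_mr * abs(q_mr)) / p$mr$k1 else 0
  dq_coa <- (p_apost - p_sa - p$r_pda * q_coa - p$coa$k2 * q_coa * abs(q_coa)) / p$coa$k1

  dy <- c(
    q_mv - q_av - q_mr + q_ar,                       # v_lv
    q_pv - q_mv + q_mr,                              # v_la
    (q_av - q_ar - (p_ao - p_apost) / p$r_ao) / p$c_ao,  # p_ao
    (q_ub + q_coa + q_graft - q_sys_out) / p$c_sac,  # p_sa
    dq_av, dq_mv, dq_coa, dq_ar, dq_mr)
  attr(dy, "aux") <- c(p_lv = p_lv, p_la = p_la, p_apost = p_apost,
                       q_ub = q_ub, q_graft = q_graft, q_pv = q_pv)
  dy
}

# bare RHS used inside the integrator (no checks, no aux)
.rhs <- function(y, t, p, act) {
  v_lv <- y[1L]; v_la <- y[2L]; p_ao <- y[3L]; p_sa <- y[4L]
  q_av <- y[5L]; q_mv <- y[6L]; q_coa <- y[7L]; q_ar <- y[8L]; q_mr <- y[9L]

  p_lv <- normalized_elastance(t, p$lv$el) * (v_lv - p$lv$v0)
  p_la <- normalized_elastance(t + p$atrial_kick, p$la$el) * (v_la - p$la$v0)

  p_apost <- (p_ao / p$r_ao + p_sa * p$g_par - q_coa) * p$inv_gtot
  q_ub <- (p_apost - p_sa) / p$r_ub
  q_graft <- if (p$graft_present) (p_apost - p_sa) / p$r_graft else 0
  tt <- t %% p$T
  q_pv <- if (tt <= p$t_ee) p$q_mpv * sin(pi * tt / p$t_ee) else 0

  dq_av <- if (act[1L]) (p_lv - p_ao - p$av$k2 * q_av * abs(q_av)) / p$av$k1 else 0
  dq_mv <- if (act[2L]) (p_la - p_lv - p$mv$k2 * q_mv * abs(q_mv)) / p$mv$k1 else 0
  dq_ar <- if (act[3L]) (p_ao - p_lv - p$ar$k2 * q_ar * abs(q_ar)) / p$ar$k1 else 0
  dq_mr <- if (act[4L]) (p_lv - p_la - p$mr$k2 * q_mr * abs(q_mr)) / p$mr$k1 else 0
  dq_coa <- (p_apost - p_sa - p$r_pda * q_coa - p$coa$k2 * q_coa * abs(q_coa)) / p$coa$k1

  c(q_mv - q_av - q_mr + q_ar,
    q_pv - q_mv + q_mr,
    (q_av - q_ar - (p_ao - p_apost) / p$r_ao) / p$c_ao,
    (q_ub + q_coa + q_graft - (p_sa - p$p_cv0) / p$r_sasv) / p$c_sac,
    dq_av, dq_mv, dq_coa, dq_ar, dq_mr)
}

.aux_signals <- function(y, t, p) {
  p_lv <- normalized_elastance(t, p$lv$el) * (y[1L] - p$lv$v0)
  p_la <- normalized_elastance(t + p$atrial_kick, p$la$el) * (y[2L] - p$la$v0)
  p_apost <- (y[3L] / p$r_ao + y[4L] * p$g_par - y[7L]) * p$inv_gtot
  q_ub <- (p_apost - y[4L]) / p$r_ub
  q_graft <- if (p$graft_present) (p_apost - y[4L]) / p$r_graft else 0
  tt <- t %% p$T
  q_pv <- if (tt <= p$t_ee) p$q_mpv * sin(pi * tt / p$t_ee) else 0
  c(p_lv, p_la, p_apost, q_ub, q_graft, q_pv)
}

# one implicit trapezoidal step with (frozen-Jacobian) Newton iteration;
# returns list(y, ok, res)
.trap_step <- function(y0, t0, dt, f0, p, act, J_lu, tol, maxit = 8L) {
  y <- y0 + dt * f0  # explicit Euler predictor
  for (it in seq_len(maxit)) {
    f <- .rhs(y, t0 + dt, p, act)
    r <- y - y0 - dt / 2 * (f0 + f)
    res <- max(abs(r))
    if (!is.finite(res)) return(list(y = y, ok = FALSE, res = Inf))
    if (res < tol) return(list(y = y, ok = TRUE, res = res))
    dyn <- tryCatch(solve(J_lu, r), error = function(e) NULL)
    if (is.null(dyn)) return(list(y = y, ok = FALSE, res = res))
    y <- y - dyn
  }
  list(y = y, ok = FALSE, res = res)
}

.newton_jacobian <- function(y, t, dt, p, act) {
  n <- length(y)
  J <- diag(n)
  f0 <- .rhs(y, t, p, act)
  h <- pmax(1e-6, 1e-6 * abs(y))
  for (j in seq_len(n)) {
    yj <- y; yj[j] <- yj[j] + h[j]
    J[, j] <- J[, j] - dt / 2 * (.rhs(yj, t, p, act) - f0) / h[j]
  }
  J
}

.param_vector <- function(p) {
  el <- function(e) c(e$e_max, e$e_min, e$m1, e$m2, e$tau1, e$tau2)
  c(p$T, p$t_ee, p$q_mpv,
    p$r_ao, p$r_sv, p$r_sa, p$r_pda, p$r_ub,
    if (p$graft_present) p$r_graft else 1.0,
    p$c_ao, p$c_sac, p$p_cv0,
    el(p$lv$el), p$lv$v0, el(p$la$el), p$la$v0, p$atrial_kick,
    p$av$k1, p$av$k2, p$mv$k1, p$mv$k2, p$coa$k1, p$coa$k2,
    if (is.null(p$ar)) c(1, 0) else c(p$ar$k1, p$ar$k2),
    if (is.null(p$mr)) c(1, 0) else c(p$mr$k1, p$mr$k2),
    as.numeric(p$graft_present), as.numeric(!is.null(p$ar)),
    as.numeric(!is.null(p$mr)))
}

#' Integrate the 0D circulation to (quasi-)steady state
#'
#' Implicit trapezoidal variable-step integration with Newton iteration
#' (residual tolerance `tol`, default 1e-6), initial step `dt_init`
#' (default 0.1 ms), step growth on success and halving on Newton failure.
#' Valve opening is checked at every accepted step; a forward-flow zero
#' crossing is localized by bisecting the step down to 1e-6 s before the
#' conduit is clamped shut. Cycles are integrated one at a time; the run
#' stops early once the cycle-to-cycle relative change of systolic pressure,
#' diastolic pressure and forward stroke volume all fall below `steady_tol`
#' (default 0.1 percent).
#'
#' The default engine is the compiled stepper; `engine = "r"` runs the same
#' scheme implemented in pure R (slow; used to cross-validate the compiled
#' path on short runs).
#'
#' @param params a [circuit_params_from_record()] object
#' @param n_cycles maximum number of cardiac cycles (default 150)
#' @param dt_init initial time step, s
#' @param dt_max maximum time step, s
#' @param tol Newton residual tolerance
#' @param steady_tol relative cycle-to-cycle drift declaring steady state
#' @param init optional initial state (named as `coaflow:::.iy`) to warm-start
#' @param init_volumes initial chamber volumes c(v_lv, v_la), mL
#' @param init_pressure initial arterial pressures, mmHg
#' @param engine `"cpp"` (default) or `"r"`
#' @return a `cycle_waveforms` object: list with `waves` (data.frame of the
#'   final cycle: time, cycle and the named signals), `cycle_summary`
#'   (per-cycle SBP/DBP/SV history), `converged`, `cycles_run`, `final_state`.
#'   Non-convergence within `n_cycles` sets `converged = FALSE` (with a
#'   warning flag, not an error).
#' @export
simulate_circuit <- function(params, n_cycles = 150L, dt_init = 1e-4,
                             dt_max = 1e-3, tol = 1e-6, steady_tol = 1e-3,
                             init = NULL, init_volumes = c(120, 60),
                             init_pressure = 70, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  sig_names <- c("v_lv", "v_la", "p_ao", "p_sa", "q_av", "q_mv", "q_coa",
                 "q_ar", "q_mr", "p_lv", "p_la", "p_apost", "q_ub", "q_graft", "q_pv")
  y0 <- if (!is.null(init)) unname(init) else
    c(init_volumes[1], init_volumes[2], init_pressure, init_pressure, 0, 0, 0, 0, 0)
  if (engine == "r")
    return(.simulate_circuit_r(params, n_cycles, dt_init, dt_max, tol,
                               steady_tol, y0))
  res <- .lpm_run_cpp(.param_vector(params), y0, as.integer(n_cycles),
                      dt_init, dt_max, tol, steady_tol, 1L)
  waves <- as.data.frame(res$waves)
  names(waves) <- c("time", sig_names)
  waves <- cbind(time = waves$time, cycle = res$cycles_run,
                 waves[sig_names])
  summ <- as.data.frame(res$summary)
  names(summ) <- c("sbp", "dbp", "sv")
  out <- list(waves = waves, cycle_summary = summ,
              converged = res$converged, cycles_run = res$cycles_run,
              final_state = stats::setNames(res$final_state, names(.iy)),
              params = params)
  class(out) <- "cycle_waveforms"
  if (!res$converged)
    attr(out, "warning") <- "steady state not reached within n_cycles"
  out
}

.simulate_circuit_r <- function(params, n_cycles = 150L, dt_init = 1e-4,
                                dt_max = 1e-3, tol = 1e-6, steady_tol = 1e-3,
                                y0 = c(120, 60, 70, 70, 0, 0, 0, 0, 0)) {
  p <- params
  # cached aggregates for the bifurcation node
  p$g_par <- 1 / p$r_ub + if (p$graft_present) 1 / p$r_graft else 0
  p$inv_gtot <- 1 / (1 / p$r_ao + p$g_par)
  p$r_sasv <- p$r_sa + p$r_sv
  if (is.null(p$ar)) p$ar <- list(k1 = 1, k2 = 0)
  if (is.null(p$mr)) p$mr <- list(k1 = 1, k2 = 0)
  has_ar <- !is.null(params$ar); has_mr <- !is.null(params$mr)

  y <- y0
  act <- c(FALSE, FALSE, FALSE, FALSE)  # av, mv, ar, mr
  dt_min <- 1e-6
  T <- p$T

  sig_names <- c("v_lv", "v_la", "p_ao", "p_sa", "q_av", "q_mv", "q_coa",
                 "q_ar", "q_mr", "p_lv", "p_la", "p_apost", "q_ub", "q_graft", "q_pv")
  summ <- matrix(NA_real_, n_cycles, 3,
                 dimnames = list(NULL, c("sbp", "dbp", "sv")))
  converged <- FALSE
  waves <- NULL
  cycles_run <- 0L

  for (cyc in seq_len(n_cycles)) {
    t <- (cyc - 1L) * T
    t_end <- cyc * T
    dt <- dt_init
    cap <- 4096L
    rec_t <- numeric(cap); rec_y <- matrix(0, cap, 15L); nrec <- 0L
    push <- function(tt, yy) {
      nrec <<- nrec + 1L
      if (nrec > cap) {
        cap <<- cap * 2L
        rec_t <<- c(rec_t, numeric(cap / 2L))
        rec_y <<- rbind(rec_y, matrix(0, cap / 2L, 15L))
      }
      rec_t[nrec] <<- tt
      rec_y[nrec, ] <<- c(yy, .aux_signals(yy, tt, p))
    }
    push(t, y)
    J <- .newton_jacobian(y, t, dt, p, act)
    steps_since_jac <- 0L

    while (t < t_end - 1e-12) {
      dt_eff <- min(dt, t_end - t)
      # open valves whose gradient is favorable
      aux <- .aux_signals(y, t, p)
      p_lv <- aux[1L]; p_la <- aux[2L]
      new_act <- act
      if (!act[1L] && p_lv > y[3L]) new_act[1L] <- TRUE
      if (!act[2L] && p_la > p_lv)  new_act[2L] <- TRUE
      if (has_ar && !act[3L] && y[3L] > p_lv) new_act[3L] <- TRUE
      if (has_mr && !act[4L] && p_lv > p_la)  new_act[4L] <- TRUE
      if (!identical(new_act, act)) {
        act <- new_act
        J <- .newton_jacobian(y, t, dt_eff, p, act)
        steps_since_jac <- 0L
      }

      f0 <- .rhs(y, t, p, act)
      st <- .trap_step(y, t, dt_eff, f0, p, act, J, tol)
      if (!st$ok) {
        if (steps_since_jac > 0L) {
          J <- .newton_jacobian(y, t, dt_eff, p, act)
          steps_since_jac <- 0L
          st <- .trap_step(y, t, dt_eff, f0, p, act, J, tol)
        }
        if (!st$ok) {
          dt <- dt_eff / 2
          if (dt < dt_min)
            stop("integration failure: step size underflow at t = ",
                 signif(t, 6), call. = FALSE)
          next
        }
      }
      yn <- st$y
      # valve closure: forward flow crossed zero from above -> bisect
      closing <- c(act[1L] && yn[5L] < 0, act[2L] && yn[6L] < 0,
                   act[3L] && yn[8L] < 0, act[4L] && yn[9L] < 0)
      if (any(closing)) {
        if (dt_eff > dt_min * 2) { dt <- dt_eff / 2; next }
        iq <- c(5L, 6L, 8L, 9L)[closing]
        yn[iq] <- 0
        act[closing] <- FALSE
        J <- .newton_jacobian(yn, t + dt_eff, dt, p, act)
        steps_since_jac <- 0L
      }
      if (yn[1L] <= 0 || yn[2L] <= 0)
        stop("integration failure: non-positive chamber volume (",
             c("v_lv", "v_la")[which(yn[1:2] <= 0)[1]], ") at t = ",
             signif(t + dt_eff, 6), call. = FALSE)
      t <- t + dt_eff
      y <- yn
      push(t, y)
      steps_since_jac <- steps_since_jac + 1L
      if (st$res < tol / 10 && dt < dt_max) {
        dt <- min(dt * 1.3, dt_max)
        J <- .newton_jacobian(y, t, dt, p, act)
        steps_since_jac <- 0L
      }
    }

    cycles_run <- cyc
    tt <- rec_t[seq_len(nrec)]
    yy <- rec_y[seq_len(nrec), , drop = FALSE]
    sbp <- max(yy[, 3L]); dbp <- min(yy[, 3L])
    sv <- .trapz(tt, yy[, 5L])
    summ[cyc, ] <- c(sbp, dbp, sv)
    if (cyc > 1L) {
      prev <- summ[cyc - 1L, ]
      drift <- abs(summ[cyc, ] - prev) / pmax(abs(prev), 1e-9)
      if (all(drift < steady_tol)) converged <- TRUE
    }
    if (converged || cyc == n_cycles) {
      waves <- data.frame(time = tt, cycle = cyc, yy)
      names(waves) <- c("time", "cycle", sig_names)
      break
    }
  }

  out <- list(waves = waves,
              cycle_summary = as.data.frame(summ[seq_len(cycles_run), , drop = FALSE]),
              converged = converged, cycles_run = cycles_run,
              final_state = stats::setNames(y, names(.iy)),
              params = params)
  class(out) <- "cycle_waveforms"
  if (!converged)
    attr(out, "warning") <- "steady state not reached within n_cycles"
  out
}

#' @export
print.cycle_waveforms <- function(x, ...) {
  s <- x$cycle_summary[nrow(x$cycle_summary), ]
  cat("<cycle_waveforms> ", x$cycles_run, " cycles, ",
      if (x$converged) "steady" else "NOT steady", "\n", sep = "")
  cat(sprintf("  final cycle: SBP %.1f, DBP %.1f mmHg, forward SV %.1f mL\n",
              s$sbp, s$dbp, s$sv))
  invisible(x)
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Export waveforms as tidy long-format data
#'
#' @param waves a `cycle_waveforms` object
#' @return data.frame with columns time, cycle, signal, value
#' @export
waveforms_long <- function(waves) {
  w <- waves$waves
  sig <- setdiff(names(w), c("time", "cycle"))
  data.frame(time = rep(w$time, length(sig)),
             cycle = rep(w$cycle, length(sig)),
             signal = rep(sig, each = nrow(w)),
             value = unlist(w[sig], use.names = FALSE))
}
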