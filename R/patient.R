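#' Doppler echocardiography measurement set
#'
#' Bundles the Doppler-derived scalars that define one patient in one state.
#' Areas are cm2, volumes mL, velocity-time integrals (VTI) cm, times s.
#'
#' @param heart_rate heart rate, 1/min
#' @param ejection_time systolic ejection time, s
#' @param a_lvot left-ventricular outflow tract area, cm2
#' @param vti_lvot LVOT velocity-time integral, cm
#' @param a_ao ascending aorta cross-sectional area, cm2
#' @param a_dao descending aorta cross-sectional area, cm2
#' @param vti_dao descending aorta velocity-time integral, cm
#' @param eoa_av aortic-valve effective orifice area, cm2
#' @param eoa_mv mitral-valve effective orifice area, cm2
#' @param eoa_coa effective orifice area of the coarctation, cm2
#' @param a_downstream_coa aortic area downstream of the coarctation, cm2
#' @param eoa_ar aortic-regurgitation effective orifice area, cm2 (0 if none)
#' @param eoa_mr mitral-regurgitation effective orifice area, cm2 (0 if none)
#' @param edv,esv end-diastolic / end-systolic LV volume, mL
#' @param cycle_duration_T cardiac cycle duration, s; defaults to 60/heart_rate
#' @return an object of class `doppler_measurements`
#' @export
doppler_measurements <- function(heart_rate, ejection_time, a_lvot, vti_lvot,
                                 a_ao, a_dao, vti_dao, eoa_av, eoa_mv,
                                 eoa_coa, a_downstream_coa,
                                 eoa_ar = 0, eoa_mr = 0,
                                 edv = 150, esv = 70,
                                 cycle_duration_T = 60 / heart_rate) {
  d <- list(heart_rate = heart_rate, cycle_duration_T = cycle_duration_T,
            ejection_time = ejection_time,
            a_lvot = a_lvot, vti_lvot = vti_lvot,
            forward_lvot_sv = a_lvot * vti_lvot,
            a_ao = a_ao, a_dao = a_dao, vti_dao = vti_dao,
            eoa_av = eoa_av, eoa_mv = eoa_mv,
            eoa_coa = eoa_coa, a_downstream_coa = a_downstream_coa,
            eoa_ar = eoa_ar, eoa_mr = eoa_mr, edv = edv, esv = esv)
  class(d) <- "doppler_measurements"
  validate_doppler(d)
  d
}

#' Validate a Doppler measurement set
#'
#' Checks the physical/physiological invariants: positive areas, regurgitant
#' orifices >= 0, orifice areas smaller than their reference areas, cycle
#' duration consistent with heart rate within 1 percent, positive forward
#' stroke volume.
#'
#' @param d a `doppler_measurements` object
#' @return `d`, invisibly; errors if an invariant fails
#' @export
validate_doppler <- function(d) {
  pos <- c("a_lvot", "a_ao", "a_dao", "eoa_av", "eoa_mv", "eoa_coa",
           "a_downstream_coa")
  for (f in pos)
    if (!is.finite(d[[f]]) || d[[f]] <= 0)
      stop("invalid measurement: ", f, " must be > 0", call. = FALSE)
  if (d$eoa_ar < 0 || d$eoa_mr < 0)
    stop("invalid measurement: regurgitant EOAs must be >= 0", call. = FALSE)
  if (d$eoa_av >= d$a_ao)
    stop("invalid measurement: eoa_av must be < a_ao", call. = FALSE)
  if (d$eoa_coa > d$a_downstream_coa)
    stop("invalid measurement: eoa_coa must be <= a_downstream_coa", call. = FALSE)
  if (abs(d$cycle_duration_T - 60 / d$heart_rate) > 0.01 * d$cycle_duration_T)
    stop("invalid measurement: cycle_duration_T inconsistent with heart_rate",
         call. = FALSE)
  if (d$forward_lvot_sv <= 0)
    stop("invalid measurement: forward_lvot_sv must be > 0", call. = FALSE)
  if (d$ejection_time <= 0 || d$ejection_time >= d$cycle_duration_T)
    stop("invalid measurement: ejection_time must lie in (0, T)", call. = FALSE)
  invisible(d)
}

#' Brachial cuff pressures
#' @param sbp systolic brachial pressure, mmHg
#' @param dbp diastolic brachial pressure, mmHg
#' @return an object of class `pressure_measurements`
#' @export
pressure_measurements <- function(sbp, dbp) {
  if (!(sbp > dbp && dbp > 0))
    stop("invalid pressures: need sbp > dbp > 0", call. = FALSE)
  structure(list(sbp = sbp, dbp = dbp), class = "pressure_measurements")
}

#' Bypass-graft geometry
#'
#' Extra-anatomical conduit left in place after grafting; the proximal
#' anastomosis is either the left subclavian artery or the aortic arch.
#'
#' @param length graft length, cm
#' @param diameter inner diameter, cm
#' @param origin `"left_subclavian"` or `"aortic_arch"`
#' @return an object of class `graft_geometry`
#' @export
graft_geometry <- function(length, diameter,
                           origin = c("left_subclavian", "aortic_arch")) {
  origin <- match.arg(origin)
  if (length <= 0 || diameter <= 0)
    stop("graft length and diameter must be > 0", call. = FALSE)
  structure(list(length = length, diameter = diameter, origin = origin),
            class = "graft_geometry")
}

#' Patient record: one patient in one (pre/post intervention) state
#'
#' @param doppler a [doppler_measurements()] object
#' @param pressures a [pressure_measurements()] object
#' @param state `"pre"` or `"post"` intervention
#' @param graft a [graft_geometry()]; required iff `state = "post"`
#' @param id optional label
#' @return an object of class `patient_record`
#' @export
patient_record <- function(doppler, pressures, state = c("pre", "post"),
                           graft = NULL, id = "synthetic") {
  state <- match.arg(state)
  stopifnot(inherits(doppler, "doppler_measurements"),
            inherits(pressures, "pressure_measurements"))
  if (state == "post" && is.null(graft))
    stop("post-intervention record requires a graft geometry", call. = FALSE)
  if (state == "pre" && !is.null(graft))
    stop("pre-intervention record must not carry a graft", call. = FALSE)
  structure(list(id = id, doppler = doppler, pressures = pressures,
                 state = state, graft = graft),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  d <- x$doppler
  cat("<patient_record> ", x$id, " [", x$state, " intervention]\n", sep = "")
  cat(sprintf("  HR %.0f /min, T %.3f s, forward LVOT-SV %.1f mL\n",
              d$heart_rate, d$cycle_duration_T, d$forward_lvot_sv))
  cat(sprintf("  SBP/DBP %.0f/%.0f mmHg, EOA(coa) %.2f of %.2f cm2 downstream\n",
              x$pressures$sbp, x$pressures$dbp, d$eoa_coa, d$a_downstream_coa))
  if (!is.null(x$graft))
    cat(sprintf("  graft: %s, L %.1f cm, D %.2f cm\n",
                x$graft$origin, x$graft$length, x$graft$diameter))
  invisible(x)
}

#' Forward LVOT stroke volume from Doppler
#'
#' Doppler product form: the volume crossing the LVOT per beat is the LVOT
#' cross-sectional area times the LVOT velocity-time integral.
#'
#' @param a_lvot LVOT area, cm2
#' @param vti_lvot LVOT velocity-time integral, cm
#' @return stroke volume, mL
#' @export
forward_lvot_sv_from_doppler <- function(a_lvot, vti_lvot) {
  if (any(a_lvot <= 0)) stop("invalid measurement: a_lvot must be > 0", call. = FALSE)
  if (any(vti_lvot < 0)) stop("invalid measurement: vti_lvot must be >= 0", call. = FALSE)
  a_lvot * vti_lvot
}

#' Descending-aorta stroke volume from Doppler
#'
#' Per-beat volume through the descending aorta (flow through the coarctation
#' plus, post-intervention, the bypass graft): `a_dao * vti_dao`.
#'
#' @param a_dao descending aorta area, cm2
#' @param vti_dao descending aorta velocity-time integral, cm
#' @return stroke volume, mL
#' @export
descending_sv_from_doppler <- function(a_dao, vti_dao) {
  if (any(a_dao <= 0)) stop("invalid measurement: a_dao must be > 0", call. = FALSE)
  if (any(vti_dao < 0)) stop("invalid measurement: vti_dao must be >= 0", call. = FALSE)
  a_dao * vti_dao
}

#' Poiseuille resistance of a bypass graft
#'
#' Hagen-Poiseuille resistance 128 mu L / (pi D^4) of the conduit, converted
#' to clinical units. Real graft junctions add losses this laminar estimate
#' ignores; in the 0D model the flow split is ultimately set by calibration.
#'
#' @param geom a [graft_geometry()]
#' @param viscosity dynamic viscosity, Pa.s
#' @return resistance in mmHg.s/mL
#' @export
graft_resistance <- function(geom, viscosity = blood_constants$mu_blood) {
  stopifnot(inherits(geom, "graft_geometry"))
  if (viscosity <= 0) stop("viscosity must be > 0", call. = FALSE)
  L <- geom$length / 100   # m
  D <- geom$diameter / 100 # m
  if (D == 0) stop("graft diameter must be > 0", call. = FALSE)
  r_si <- 128 * viscosity * L / (pi * D^4)  # Pa.s/m3
  resistance_si_to_clinical(r_si)
}

# severity -> coarctation area ratio eoa_coa / a_downstream_coa
.severity_ratio <- c(none = 1.0, mild = 0.6, moderate = 0.4, severe = 0.25)

#' Generate a synthetic coarctation patient
#'
#' Draws a physiologically plausible patient record emulating the value
#' envelope of the bypass-graft cohort this package models: forward LVOT
#' stroke volumes 55-90 mL, systolic/diastolic brachial pressures within
#' 120-160 / 50-80 mmHg, coarctation severity expressed as the ratio of the
#' stenosis effective orifice area to the downstream aortic area
#' (none/mild/moderate/severe = 1.0/0.6/0.4/0.25). The descending-aorta
#' stroke volume is drawn as 55-70 percent of the forward stroke volume so
#' the upper-body/descending split is always realizable. Deterministic for a
#' fixed seed.
#'
#' @param seed integer RNG seed
#' @param severity coarctation severity class
#' @param state `"pre"` or `"post"` intervention
#' @return a [patient_record()]
#' @export
generate_synthetic_patient <- function(seed = 1L,
                                       severity = c("moderate", "none", "mild", "severe"),
                                       state = c("pre", "post")) {
  severity <- match.arg(severity)
  state <- match.arg(state)
  runif_old <- .Random.seed_exists()
  on.exit(.restore_seed(runif_old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  hr  <- runif(1, 60, 85)
  Tc  <- 60 / hr
  tej <- runif(1, 0.30, 0.36) * sqrt(Tc / 0.85)  # scales weakly with cycle length
  sv  <- runif(1, 55, 90)
  a_lvot <- runif(1, 3.0, 4.5)
  a_ao   <- runif(1, 6.0, 9.0)
  a_dao  <- runif(1, 3.0, 5.0)
  desc_frac <- runif(1, 0.55, 0.70)
  desc_sv <- desc_frac * sv
  a_down <- runif(1, 2.2, 3.8)
  eoa_coa <- .severity_ratio[[severity]] * a_down
  eoa_av <- runif(1, 0.30, 0.55) * a_ao
  eoa_mv <- runif(1, 3.0, 5.0)
  sbp <- runif(1, 120, 160)
  dbp <- runif(1, 50, 80)
  edv <- runif(1, 120, 180)
  esv <- edv - sv * runif(1, 1.0, 1.15)  # total SV >= forward SV (no regurg here)

  dop <- doppler_measurements(
    heart_rate = hr, ejection_time = tej,
    a_lvot = a_lvot, vti_lvot = sv / a_lvot,
    a_ao = a_ao, a_dao = a_dao, vti_dao = desc_sv / a_dao,
    eoa_av = eoa_av, eoa_mv = eoa_mv,
    eoa_coa = eoa_coa, a_downstream_coa = a_down,
    edv = edv, esv = esv)
  prs <- pressure_measurements(sbp, dbp)
  graft <- NULL
  if (state == "post")
    graft <- graft_geometry(length = runif(1, 6.9, 8.3),
                            diameter = runif(1, 1.5, 1.7),
                            origin = sample(c("left_subclavian", "aortic_arch"), 1))
  patient_record(dop, prs, state = state, graft = graft,
                 id = sprintf("synth-%d-%s-%s", as.integer(seed), severity, state))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a patient record as a flat YAML document
#'
#' The on-disk schema is flat `key: value` scalars in the fixed clinical
#' units (mL, s, mmHg, cm2, cm); graft keys are present only for post states.
#'
#' @param record a [patient_record()]
#' @param path file path
#' @return `write_patient_yaml` returns `path` invisibly; `read_patient_yaml`
#'   returns a [patient_record()].
#' @export
write_patient_yaml <- function(record, path) {
  stopifnot(inherits(record, "patient_record"))
  d <- record$doppler
  x <- list(id = record$id, state = record$state,
            heart_rate = d$heart_rate, cycle_duration_T = d$cycle_duration_T,
            ejection_time = d$ejection_time,
            a_lvot = d$a_lvot, vti_lvot = d$vti_lvot,
            a_ao = d$a_ao, a_dao = d$a_dao, vti_dao = d$vti_dao,
            eoa_av = d$eoa_av, eoa_mv = d$eoa_mv,
            eoa_coa = d$eoa_coa, a_downstream_coa = d$a_downstream_coa,
            eoa_ar = d$eoa_ar, eoa_mr = d$eoa_mr,
            edv = d$edv, esv = d$esv,
            sbp = record$pressures$sbp, dbp = record$pressures$dbp)
  if (!is.null(record$graft))
    x <- c(x, list(graft_length = record$graft$length,
                   graft_diameter = record$graft$diameter,
                   graft_origin = record$graft$origin))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_patient_yaml
#' @export
read_patient_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("state", "heart_rate", "ejection_time", "a_lvot", "vti_lvot",
            "a_ao", "a_dao", "vti_dao", "eoa_av", "eoa_mv", "eoa_coa",
            "a_downstream_coa", "sbp", "dbp")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("patient file missing keys: ", paste(miss, collapse = ", "), call. = FALSE)
  dop <- doppler_measurements(
    heart_rate = x$heart_rate,
    cycle_duration_T = if (!is.null(x$cycle_duration_T)) x$cycle_duration_T else 60 / x$heart_rate,
    ejection_time = x$ejection_time,
    a_lvot = x$a_lvot, vti_lvot = x$vti_lvot,
    a_ao = x$a_ao, a_dao = x$a_dao, vti_dao = x$vti_dao,
    eoa_av = x$eoa_av, eoa_mv = x$eoa_mv,
    eoa_coa = x$eoa_coa, a_downstream_coa = x$a_downstream_coa,
    eoa_ar = if (is.null(x$eoa_ar)) 0 else x$eoa_ar,
    eoa_mr = if (is.null(x$eoa_mr)) 0 else x$eoa_mr,
    edv = if (is.null(x$edv)) 150 else x$edv,
    esv = if (is.null(x$esv)) 70 else x$esv)
  graft <- NULL
  if (identical(x$state, "post"))
    graft <- graft_geometry(x$graft_length, x$graft_diameter, x$graft_origin)
  patient_record(dop, pressure_measurements(x$sbp, x$dbp),
                 state = x$state, graft = graft,
                 id = if (is.null(x$id)) "file" else x$id)
}
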