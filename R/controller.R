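#' Speed-controller parameters
#'
#' The belt-speed command is issued once per accepted footstep:
#' `v_tgt = vtm_bar + G_v * vbar_kf + G_p * (pbar_kf - p0)`, clamped to
#' `[v_min, v_max]`, and the acceleration command brings the belt to the
#' target over `dt_tgt` seconds (about one step duration), clamped to
#' `[-a_max, a_max]`. Despite the plus signs this is negative feedback:
#' belt speed and walker lab-frame speed are oppositely directed, so a
#' walker drifting forward speeds the belt up and is carried back toward
#' the baseline position `p0`.
#'
#' Default gains are the published values `G_v = 0.25` (dimensionless) and
#' `G_p = 0.1` (1/s); `dt_tgt = 0.5` s; the belt starts at
#' `v_start = 0.8` m/s in self-paced trials.
#'
#' @param G_v speed-error gain (dimensionless, >= 0).
#' @param G_p position-error gain (1/s, >= 0).
#' @param dt_tgt time allotted to reach the target speed (s).
#' @param p0 baseline position on the deck (m).
#' @param v_min,v_max belt speed clamp (m/s); the belt never reverses.
#' @param a_max belt acceleration clamp (m/s^2).
#' @param v_start initial belt speed for self-paced trials (m/s).
#' @return List of class `"sp_controller_params"`.
#' @export
controller_params <- function(G_v = 0.25, G_p = 0.1, dt_tgt = 0.5, p0 = 0,
                              v_min = 0, v_max = 2.5, a_max = 2.0,
                              v_start = 0.8) {
  stopifnot(G_v >= 0, G_p >= 0, dt_tgt > 0, a_max > 0,
            v_min <= v_start, v_start <= v_max)
  structure(list(G_v = G_v, G_p = G_p, dt_tgt = dt_tgt, p0 = p0,
                 v_min = v_min, v_max = v_max, a_max = a_max,
                 v_start = v_start),
            class = "sp_controller_params")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Target belt speed for the coming step
#'
#' @param vtm_bar mean belt speed over the completed step (m/s).
#' @param vbar_kf estimated mean lab-frame walker speed over the step (m/s).
#' @param pbar_kf estimated mean walker position over the step (m).
#' @param params a [controller_params()] object.
#' @return Clamped target belt speed (m/s).
#' @export
target_speed <- function(vtm_bar, vbar_kf, pbar_kf, params) {
  stopifnot(is.finite(vtm_bar), is.finite(vbar_kf), is.finite(pbar_kf))
  clamp(vtm_bar + params$G_v * vbar_kf + params$G_p * (pbar_kf - params$p0),
        params$v_min, params$v_max)
}

#' Target belt acceleration
#'
#' @param v_tgt target belt speed (m/s).
#' @param vtm_bar mean belt speed over the completed step (m/s).
#' @param params a [controller_params()] object.
#' @return Clamped target acceleration (m/s^2).
#' @export
target_accel <- function(v_tgt, vtm_bar, params) {
  clamp((v_tgt - vtm_bar) / params$dt_tgt, -params$a_max, params$a_max)
}

#' Baseline position from a fixed-speed calibration window
#'
#' The baseline `p0` is the mean estimated walker position over a
#' fixed-speed familiarization window.
#'
#' @param position_log numeric vector of estimated positions (m).
#' @return Mean position `p0` (m).
#' @export
calibrate_p0 <- function(position_log) {
  position_log <- position_log[is.finite(position_log)]
  if (length(position_log) == 0) stop("empty calibration window")
  mean(position_log)
}

#' Command generation at a processed contact
#'
#' Emits a treadmill command for an accepted step; rejected steps (e.g.
#' crossovers) produce no command and the belt continues executing its
#' previous one, because the step-mean state is unreliable there.
#'
#' @param step one-row step result from the estimator (fields `t1`,
#'   `vtm_bar`, `vbar_kf`, `pbar_kf`, `applied`).
#' @param params a [controller_params()] object.
#' @return One-row `data.frame` with `t_issue`, `vtm_tgt`, `atm_tgt`, or
#'   `NULL` when the step was rejected.
#' @export
update_on_contact <- function(step, params) {
  if (!isTRUE(as.logical(step$applied))) return(NULL)
  v_tgt <- target_speed(step$vtm_bar, step$vbar_kf, step$pbar_kf, params)
  data.frame(t_issue = step$t1, vtm_tgt = v_tgt,
             atm_tgt = target_accel(v_tgt, step$vtm_bar, params))
}
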