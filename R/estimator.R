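#' Kalman filter parameters for walking-state estimation
#'
#' The filter tracks the walker's fore-aft lab-frame position and speed,
#' `x = (p, v)`, with a constant-acceleration kinematic model driven by the
#' measured fore-aft acceleration: `x <- A x + B a_mes` at every tick of
#' length `dt`. Process noise enters through the acceleration channel, so
#' the additive covariance term is `sigma_a2 * B %*% t(B)`. Step
#' measurements `(pbar_mes, vbar_mes)` correct the state once per accepted
#' footstep with measurement covariance `R`; the observation matrix is the
#' identity.
#'
#' Defaults are the published constants of the method: `dt = 0.001` s,
#' `sigma_a2 = 2.9` (m/s^2)^2, `R = 1e-3 * diag(c(0.6, 7.2))`
#' (units m^2 and (m/s)^2), `P0 = 1e-3 * [[3.5, 1.5], [1.5, 1.6]]`.
#'
#' @param dt tick length in seconds.
#' @param sigma_a2 acceleration noise variance ((m/s^2)^2).
#' @param R 2x2 step-measurement noise covariance (position then speed).
#' @param P0 2x2 initial error covariance.
#' @param max_step maximum accepted step duration (s).
#' @param min_step minimum accepted step duration (s).
#' @return List of class `"sp_filter_params"` with `A`, `B`, `Q_add` and the
#'   arguments above.
#' @export
filter_params <- function(dt = 0.001, sigma_a2 = 2.9,
                          R = 1e-3 * diag(c(0.6, 7.2)),
                          P0 = 1e-3 * matrix(c(3.5, 1.5, 1.5, 1.6), 2, 2),
                          max_step = 1.2, min_step = 0.2) {
  stopifnot(dt > 0, sigma_a2 >= 0, all(dim(R) == c(2, 2)),
            all(dim(P0) == c(2, 2)))
  if (max(abs(R - t(R))) > 0 || max(abs(P0 - t(P0))) > 0) {
    stop("R and P0 must be symmetric")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("R must be positive definite")
  }
  A <- matrix(c(1, 0, dt, 1), 2, 2)
  B <- c(dt^2 / 2, dt)
  structure(list(dt = dt, sigma_a2 = sigma_a2, A = A, B = B,
                 Q_add = sigma_a2 * (B %*% t(B)), R = R, P0 = P0,
                 max_step = max_step, min_step = min_step),
            class = "sp_filter_params")
}

#' Initialize the filter state
#'
#' Starts at `p = 0`, `v = 0`, `P = P0`, with empty per-step accumulators
#' and no prior contact reference.
#'
#' @param params a [filter_params()] object.
#' @return List of class `"sp_filter_state"`.
#' @export
kf_init <- function(params = filter_params()) {
  structure(list(x = c(0, 0), P = params$P0,
                 acc_p = 0, acc_v = 0, acc_n = 0L,
                 t_prev = NA_real_, cop_prev = NA_real_,
                 sample_prev = NA_integer_),
            class = "sp_filter_state")
}

#' Per-tick time update (predict)
#'
#' Advances the state with the measured acceleration, propagates the error
#' covariance, and extends the per-step running means with the new state.
#'
#' @param state an `"sp_filter_state"`.
#' @param a_mes measured fore-aft acceleration (m/s^2), finite scalar.
#' @param params a [filter_params()] object.
#' @return The updated state.
#' @export
kf_time_update <- function(state, a_mes, params) {
  if (length(a_mes) != 1 || !is.finite(a_mes)) {
    stop("a_mes must be a finite scalar")
  }
  state$x <- as.numeric(params$A %*% state$x + params$B * a_mes)
  state$P <- params$A %*% state$P %*% t(params$A) + params$Q_add
  state$acc_p <- state$acc_p + state$x[1]
  state$acc_v <- state$acc_v + state$x[2]
  state$acc_n <- state$acc_n + 1L
  state
}

#' Per-footstep measurement update (correct)
#'
#' Corrects the instantaneous state with an accepted step measurement. The
#' innovation compares the measured step means `(pbar_mes, vbar_mes)` with
#' the per-step running means of the estimated state, while the Kalman gain
#' `K = P (P + R)^-1` and covariance update `P <- (I - K) P` operate on the
#' instantaneous covariance. The covariance is re-symmetrized and the step
#' accumulators reset.
#'
#' @param state an `"sp_filter_state"` with non-empty accumulators.
#' @param meas an accepted one-row step measurement (see
#'   [step_measurement()]), needing fields `pmes` and `vmes`.
#' @param params a [filter_params()] object.
#' @return The updated state.
#' @export
kf_measurement_update <- function(state, meas, params) {
  if (!isTRUE(as.logical(meas$accepted))) {
    stop("measurement update requires an accepted step")
  }
  if (state$acc_n < 1L) stop("no ticks accumulated since the last contact")
  S <- state$P + params$R
  K <- state$P %*% solve(S)
  innov <- c(meas$pmes, meas$vmes) -
    c(state$acc_p, state$acc_v) / state$acc_n
  state$x <- as.numeric(state$x + K %*% innov)
  P <- (diag(2) - K) %*% state$P
  state$P <- (P + t(P)) / 2
  state$acc_p <- 0
  state$acc_v <- 0
  state$acc_n <- 0L
  state
}

#' Handle a detected foot contact
#'
#' Every detected contact ends the current step: the per-step means of the
#' estimated state are read out and the accumulators reset, and the contact
#' becomes the reference for the next step. The measurement update is
#' applied only when the step measurement is accepted; rejected steps
#' (e.g. implausibly long intervals caused by belt crossovers) skip the
#' correction, leaving the state continuous. The first contact of a trial
#' has no step measurement and only sets the reference.
#'
#' @param state an `"sp_filter_state"`.
#' @param meas a one-row step measurement, or `NULL` for a first contact.
#' @param params a [filter_params()] object.
#' @param contact optional contact row (fields `t`, `cop`, `sample`) stored
#'   as the new step reference.
#' @return List with `state`, `applied` (was the correction applied),
#'   and the pre-correction step means `pbar_kf`, `vbar_kf` (`NA` when no
#'   ticks had accumulated).
#' @export
kf_handle_contact <- function(state, meas = NULL, params, contact = NULL) {
  if (state$acc_n > 0L) {
    pbar <- state$acc_p / state$acc_n
    vbar <- state$acc_v / state$acc_n
  } else {
    pbar <- NA_real_
    vbar <- NA_real_
  }
  applied <- FALSE
  if (!is.null(meas) && isTRUE(as.logical(meas$accepted)) &&
      state$acc_n > 0L) {
    state <- kf_measurement_update(state, meas, params)
    applied <- TRUE
  } else {
    state$acc_p <- 0
    state$acc_v <- 0
    state$acc_n <- 0L
  }
  if (!is.null(contact)) {
    state$t_prev <- contact$t
    state$cop_prev <- contact$cop
    state$sample_prev <- contact$sample
  }
  list(state = state, applied = applied, pbar_kf = pbar, vbar_kf = vbar)
}

#' Offline replay of the estimator over a recorded series
#'
#' Runs the full per-tick loop on a force-plate series exactly as an online
#' estimator would: causal low-pass filtering, threshold contact detection,
#' per-tick time updates from the measured acceleration, and per-accepted-
#' footstep measurement updates from the step measurements.
#'
#' @param series a [force_plate_series()] with body mass/weight set.
#' @param params a [filter_params()] object.
#' @param order,fc low-pass filter order and cutoff (Hz).
#' @param threshold,rearm contact detection levels (fractions of body
#'   weight).
#' @param measurement_updates set `FALSE` to disable the per-footstep
#'   corrections (pure force integration; diverges, which is the point of
#'   the comparison).
#' @return List of class `"sp_estimate"`: `est` (per-tick `t`, `p_kf`,
#'   `v_kf`, `P00`, `P01`, `P11`), `steps` (per-contact step table with
#'   measurements, pre-correction estimate means and `applied`),
#'   `contacts`, and `params`.
#' @export
run_offline <- function(series, params = filter_params(), order = 3,
                        fc = 25, threshold = 0.2, rearm = 0.1,
                        measurement_updates = TRUE) {
  filt <- lowpass(series, order = order, fc = fc)
  contacts <- detect_contacts(filt, threshold = threshold, rearm = rearm)
  a <- accel_measurement(filt)
  n <- nrow(series)
  tt <- series$t
  dt <- params$dt
  if (abs(dt - (tt[2] - tt[1])) > 1e-9 * dt) {
    stop("filter dt must equal the series sampling interval")
  }
  ctv <- pracma::cumtrapz(tt, series$vtm)[, 1]

  # scalar-state inner loop (identical recursion to kf_time_update /
  # kf_measurement_update, unrolled for speed)
  h2 <- dt^2 / 2
  q00 <- params$Q_add[1, 1]; q01 <- params$Q_add[1, 2]
  q11 <- params$Q_add[2, 2]
  r00 <- params$R[1, 1]; r01 <- params$R[1, 2]; r11 <- params$R[2, 2]
  p <- 0; v <- 0
  P00 <- params$P0[1, 1]; P01 <- params$P0[1, 2]; P11 <- params$P0[2, 2]
  accp <- 0; accv <- 0; nacc <- 0L
  t_prev <- NA_real_; cop_prev <- NA_real_
  i_prev <- NA_integer_; ctv_prev <- NA_real_

  cvec <- integer(n)
  cvec[contacts$sample] <- seq_len(nrow(contacts))

  ep <- numeric(n); ev <- numeric(n)
  eP00 <- numeric(n); eP01 <- numeric(n); eP11 <- numeric(n)
  srows <- vector("list", nrow(contacts))

  for (k in seq_len(n)) {
    ak <- a[k]
    # time update
    p <- p + dt * v + h2 * ak
    v <- v + dt * ak
    t00 <- P00 + dt * (P01 + P01) + dt * dt * P11 + q00
    t01 <- P01 + dt * P11 + q01
    P11 <- P11 + q11
    P00 <- t00
    P01 <- t01
    accp <- accp + p
    accv <- accv + v
    nacc <- nacc + 1L

    j <- cvec[k]
    if (j > 0L) {
      cop_now <- contacts$cop[j]
      if (!is.na(t_prev)) {
        dur <- tt[k] - t_prev
        travel <- ctv[k] - ctv_prev
        yf1 <- cop_now
        yf0 <- cop_prev - travel
        vtm_bar <- travel / dur
        vmes <- (yf1 - yf0) / dur - vtm_bar
        pmes <- (yf1 + yf0) / 2
        accepted <- dur <= params$max_step && dur >= params$min_step
        pbar <- accp / nacc
        vbar <- accv / nacc
        applied <- FALSE
        if (accepted && measurement_updates) {
          # K = P (P + R)^-1 via the 2x2 cofactor inverse
          s00 <- P00 + r00; s01 <- P01 + r01; s11 <- P11 + r11
          det <- s00 * s11 - s01 * s01
          k00 <- (P00 * s11 - P01 * s01) / det
          k01 <- (-P00 * s01 + P01 * s00) / det
          k10 <- (P01 * s11 - P11 * s01) / det
          k11 <- (-P01 * s01 + P11 * s00) / det
          ip <- pmes - pbar
          iv <- vmes - vbar
          p <- p + k00 * ip + k01 * iv
          v <- v + k10 * ip + k11 * iv
          n00 <- (1 - k00) * P00 - k01 * P01
          n01 <- (1 - k00) * P01 - k01 * P11
          n10 <- -k10 * P00 + (1 - k11) * P01
          n11 <- -k10 * P01 + (1 - k11) * P11
          P00 <- n00
          P01 <- (n01 + n10) / 2
          P11 <- n11
          applied <- TRUE
        }
        srows[[j]] <- data.frame(
          t0 = t_prev, t1 = tt[k], belt = contacts$belt[j],
          y_f0 = yf0, y_f1 = yf1, vtm_bar = vtm_bar, vmes = vmes,
          pmes = pmes, accepted = accepted, pbar_kf = pbar,
          vbar_kf = vbar, applied = applied)
        accp <- 0; accv <- 0; nacc <- 0L
      } else {
        # first contact: reference only
        accp <- 0; accv <- 0; nacc <- 0L
      }
      t_prev <- tt[k]
      cop_prev <- cop_now
      i_prev <- k
      ctv_prev <- ctv[k]
    }

    ep[k] <- p; ev[k] <- v
    eP00[k] <- P00; eP01[k] <- P01; eP11[k] <- P11
  }

  steps <- if (length(srows) && any(!vapply(srows, is.null, TRUE))) {
    do.call(rbind, srows[!vapply(srows, is.null, TRUE)])
  } else {
    data.frame(t0 = numeric(0), t1 = numeric(0), belt = character(0),
               y_f0 = numeric(0), y_f1 = numeric(0), vtm_bar = numeric(0),
               vmes = numeric(0), pmes = numeric(0), accepted = logical(0),
               pbar_kf = numeric(0), vbar_kf = numeric(0),
               applied = logical(0))
  }
  structure(list(est = data.frame(t = tt, p_kf = ep, v_kf = ev,
                                  P00 = eP00, P01 = eP01, P11 = eP11),
                 steps = steps, contacts = contacts, params = params),
            class = "sp_estimate")
}
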