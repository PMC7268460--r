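#' Two-belt force-plate time series
#'
#' Container for uniformly sampled per-belt treadmill force-plate signals:
#' vertical force `fz`, fore-aft force `fy` (positive in the walker's forward
#' direction, `+y`), fore-aft centre of pressure `copy` in the lab frame, and
#' the belt-speed magnitude `vtm` (the belt surface moves in `-y`).
#'
#' @param t sample times in seconds on a strictly uniform grid, or `NULL` to
#'   build the grid from `fs`.
#' @param fz_l,fy_l,copy_l left-belt vertical force (N), fore-aft force (N)
#'   and fore-aft COP (m). `copy_l` may be `NA` where the belt is unloaded.
#' @param fz_r,fy_r,copy_r right-belt channels, as above.
#' @param vtm belt-speed magnitude series (m/s, non-negative).
#' @param fs sampling rate in Hz, used when `t` is `NULL`.
#' @param body_mass subject mass in kg (optional; required for acceleration
#'   measurement).
#' @param body_weight subject weight in N (optional; defaults to
#'   `body_mass * 9.81` when the mass is given). Required for contact
#'   detection.
#'
#' @return A `data.frame` of class `"fp_series"` with columns
#'   `t, fz_l, fy_l, copy_l, fz_r, fy_r, copy_r, vtm` and attributes
#'   `fs`, `body_mass`, `body_weight`.
#' @export
force_plate_series <- function(t = NULL, fz_l, fy_l, copy_l, fz_r, fy_r,
                               copy_r, vtm, fs = 1000,
                               body_mass = NULL, body_weight = NULL) {
  n <- length(fz_l)
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  lens <- c(length(t), length(fy_l), length(copy_l), length(fz_r),
            length(fy_r), length(copy_r), length(vtm))
  if (any(lens != n)) stop("all channels must have the same length")
  if (n < 2) stop("a force-plate series needs at least two samples")
  dt <- diff(t)
  if (any(!is.finite(t)) || max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("sampling must be strictly uniform")
  }
  fs <- 1 / dt[1]
  for (ch in list(fz_l, fy_l, fz_r, fy_r, vtm)) {
    if (any(!is.finite(ch))) stop("force and belt-speed samples must be finite")
  }
  if (any(vtm < 0)) stop("belt speed magnitude vtm must be non-negative")
  if (is.null(body_weight) && !is.null(body_mass)) {
    body_weight <- body_mass * 9.81
  }
  out <- data.frame(t = t, fz_l = fz_l, fy_l = fy_l, copy_l = copy_l,
                    fz_r = fz_r, fy_r = fy_r, copy_r = copy_r, vtm = vtm)
  structure(out, fs = fs, body_mass = body_mass, body_weight = body_weight,
            class = c("fp_series", "data.frame"))
}

fp_fs <- function(series) attr(series, "fs")

fp_body_weight <- function(series) {
  bw <- attr(series, "body_weight")
  if (is.null(bw)) {
    stop("body_weight is not set; configure it or run calibrate_body_weight()")
  }
  bw
}

fp_body_mass <- function(series) {
  m <- attr(series, "body_mass")
  if (is.null(m) || m <= 0) {
    stop("body_mass must be set and positive; configure it or run ",
         "calibrate_body_weight()")
  }
  m
}

#' Fore-aft centre of pressure from vertical force and frontal moment
#'
#' The fore-aft COP is the ratio of the frontal-plane moment arm to the
#' vertical force, shifted by the plate origin offset into the lab frame.
#' Samples whose vertical force is below the validity floor are marked
#' invalid (`NA`), never silently zeroed.
#'
#' @param fz vertical force (N).
#' @param moment fore-aft moment-arm numerator (N m), i.e. the frontal
#'   moment component divided out so that `moment / fz` is a position.
#' @param origin plate origin offset in the lab frame (m).
#' @param floor validity floor for `fz` (N); COP is `NA` at or below it.
#' @return COP series (m) with `NA` at invalid samples.
#' @export
compute_cop <- function(fz, moment, origin = 0, floor = 50) {
  if (length(moment) != length(fz)) stop("fz and moment lengths differ")
  cop <- moment / fz + origin
  cop[!(fz > floor)] <- NA_real_
  cop
}

# validity floor for COP: 5% of body weight when known, else 50 N
cop_floor <- function(series) {
  bw <- attr(series, "body_weight")
  if (is.null(bw)) 50 else 0.05 * bw
}

#' Causal low-pass filtering of force-plate channels
#'
#' Applies a causal (online-capable) Butterworth low-pass filter to every
#' force channel. The COP is not filtered directly: the ratio is ill-behaved
#' near an unloaded plate, so the fore-aft moment (`copy * fz`, zero where
#' the COP is invalid) and the vertical force are filtered separately and
#' the COP re-formed from the filtered pair, masked below the validity
#' floor.
#'
#' @param series a [force_plate_series()].
#' @param order filter order (default third order).
#' @param fc cutoff frequency in Hz (default 25 Hz); must be below Nyquist.
#' @return A filtered `fp_series` with the same grid and attributes.
#' @export
lowpass <- function(series, order = 3, fc = 25) {
  fs <- fp_fs(series)
  if (fc >= fs / 2) stop("cutoff fc must be below the Nyquist frequency")
  if (order < 1) stop("filter order must be at least 1")
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  fl <- function(x) as.numeric(signal::filter(bf, x))

  mom_l <- ifelse(is.na(series$copy_l), 0, series$copy_l * series$fz_l)
  mom_r <- ifelse(is.na(series$copy_r), 0, series$copy_r * series$fz_r)

  fz_l <- fl(series$fz_l)
  fz_r <- fl(series$fz_r)
  floor_n <- cop_floor(series)
  out <- series
  out$fz_l <- fz_l
  out$fz_r <- fz_r
  out$fy_l <- fl(series$fy_l)
  out$fy_r <- fl(series$fy_r)
  out$copy_l <- compute_cop(fz_l, fl(mom_l), floor = floor_n)
  out$copy_r <- compute_cop(fz_r, fl(mom_r), floor = floor_n)
  out
}

#' Detect foot contacts from vertical force threshold crossings
#'
#' A contact is the rising edge at which a belt's vertical force first
#' exceeds `threshold` (default 20%) of body weight. Each belt re-arms only
#' after its force has dropped below the hysteresis level (`rearm`, default
#' 10% of body weight), which suppresses chatter around the threshold. If
#' both belts cross within the same sample, the belt with the larger
#' vertical force wins and the other is suppressed until it re-arms.
#'
#' @param series an `fp_series` (normally already [lowpass()]-filtered).
#' @param threshold contact threshold as a fraction of body weight.
#' @param rearm re-arm (hysteresis) level as a fraction of body weight.
#' @return A `data.frame` with one row per contact: `sample`, `t`, `belt`
#'   (`"left"`/`"right"`) and `cop` (that belt's COP at the crossing sample).
#' @export
detect_contacts <- function(series, threshold = 0.2, rearm = 0.1) {
  bw <- fp_body_weight(series)
  thr <- threshold * bw
  low <- rearm * bw
  fz <- cbind(series$fz_l, series$fz_r)
  cop <- cbind(series$copy_l, series$copy_r)
  n <- nrow(fz)
  belts <- c("left", "right")

  # below-rearm cumulative counts let the armed state be resolved at the
  # candidate crossings only, instead of walking every sample
  cl <- apply(fz < low, 2, cumsum)
  init_armed <- fz[1, ] < thr
  up <- lapply(1:2, function(b) {
    which(fz[-1, b] > thr & fz[-n, b] <= thr) + 1L
  })
  cand <- sort(unique(c(up[[1]], up[[2]])))
  last_evt <- c(0L, 0L) # sample at which each belt last disarmed
  samp <- integer(0)
  side <- integer(0)
  for (k in cand) {
    hit <- c(FALSE, FALSE)
    for (b in 1:2) {
      if (!(k %in% up[[b]])) next
      e <- last_evt[b]
      hit[b] <- if (e == 0L) {
        init_armed[b] || cl[k - 1, b] > cl[1, b]
      } else {
        k - 1L > e && cl[k - 1, b] > cl[e, b]
      }
    }
    if (!any(hit)) next
    if (hit[1] && hit[2]) {
      # simultaneous dual-belt crossing: larger force wins, the other is
      # suppressed until it re-arms
      win <- which.max(fz[k, ])
      last_evt[] <- k
    } else {
      win <- which(hit)
      last_evt[win] <- k
    }
    samp <- c(samp, k)
    side <- c(side, win)
  }
  data.frame(sample = samp, t = series$t[samp], belt = belts[side],
             cop = cop[cbind(samp, side)])
}

#' Lab-frame foot positions of two consecutive contacts
#'
#' The leading foot position `y_f1` is the COP at the current contact. The
#' trailing foot position `y_f0` is the COP at the previous contact carried
#' along with the belt's material motion over the step: with `+y` the
#' walker's forward direction and the belt surface moving in `-y`, a
#' stationary foot translates backwards by the integral of the belt speed,
#' so `y_f0 = cop_prev - integral(vtm)`. `y_f1 - y_f0` is then the forward
#' step length in the lab frame.
#'
#' @param prev,curr single contact rows as returned by [detect_contacts()].
#' @param series the `fp_series` supplying the belt-speed history.
#' @return Named numeric vector `c(y_f0, y_f1)`.
#' @export
foot_positions <- function(prev, curr, series) {
  if (!(prev$t < curr$t)) stop("contacts must be in increasing time order")
  idx <- prev$sample:curr$sample
  v <- series$vtm[idx]
  if (any(is.na(v))) stop("belt-speed samples missing in the step interval")
  travel <- pracma::trapz(series$t[idx], v)
  c(y_f0 = prev$cop - travel, y_f1 = curr$cop)
}

#' Per-step speed and position measurement
#'
#' Implements the step measurements used by the estimator: the subject's
#' mean lab-frame speed over a step is the walking speed (step length over
#' step time) minus the mean belt speed, and the mean position is the middle
#' of the leading and trailing foot placements. A step is accepted when its
#' duration lies within `[min_step, max_step]`; longer intervals typically
#' indicate a missed (crossover) contact and are rejected.
#'
#' @inheritParams foot_positions
#' @param max_step maximum plausible step duration (s), default 1.2 s.
#' @param min_step minimum step duration (s), a re-trigger guard,
#'   default 0.2 s.
#' @return One-row `data.frame`: `t0, t1, belt, y_f0, y_f1, vtm_bar,
#'   vmes, pmes, accepted`. `vtm_bar` is the time-average belt speed over
#'   the step, so `vmes = (y_f1 - y_f0)/(t1 - t0) - vtm_bar` exactly.
#' @export
step_measurement <- function(prev, curr, series, max_step = 1.2,
                             min_step = 0.2) {
  yf <- foot_positions(prev, curr, series)
  dur <- curr$t - prev$t
  idx <- prev$sample:curr$sample
  travel <- pracma::trapz(series$t[idx], series$vtm[idx])
  vtm_bar <- travel / dur
  vmes <- (yf[["y_f1"]] - yf[["y_f0"]]) / dur - vtm_bar
  data.frame(t0 = prev$t, t1 = curr$t, belt = curr$belt,
             y_f0 = yf[["y_f0"]], y_f1 = yf[["y_f1"]],
             vtm_bar = vtm_bar, vmes = vmes,
             pmes = (yf[["y_f1"]] + yf[["y_f0"]]) / 2,
             accepted = dur <= max_step && dur >= min_step)
}

#' Fore-aft acceleration measurement
#'
#' Newton's second law applied to the total fore-aft ground reaction force:
#' `a_mes = (fy_l + fy_r) / m`, positive in the walker-forward direction.
#'
#' @param series an `fp_series` with `body_mass` set.
#' @return Acceleration series (m/s^2) on the series' grid.
#' @export
accel_measurement <- function(series) {
  m <- fp_body_mass(series)
  (series$fy_l + series$fy_r) / m
}

#' Calibrate body weight from a quiet-standing window
#'
#' Averages the total vertical force over a standing window and converts to
#' mass with g = 9.81 m/s^2.
#'
#' @param series an `fp_series`.
#' @param window `c(t_start, t_end)` in seconds, or `NULL` for the whole
#'   series.
#' @param min_window minimum window length in seconds (default 1 s).
#' @return List with `body_weight` (N) and `body_mass` (kg).
#' @export
calibrate_body_weight <- function(series, window = NULL, min_window = 1) {
  g <- 9.81
  if (is.null(window)) window <- range(series$t)
  keep <- series$t >= window[1] & series$t <= window[2]
  if (diff(window) < min_window || !any(keep)) {
    stop("calibration window shorter than the configured minimum")
  }
  bw <- mean(series$fz_l[keep] + series$fz_r[keep])
  list(body_weight = bw, body_mass = bw / g)
}

#' Attach subject mass/weight to a series
#'
#' @param series an `fp_series`.
#' @param body_mass subject mass (kg); weight defaults to `9.81 * body_mass`.
#' @param body_weight subject weight (N), optional override.
#' @return The series with updated attributes.
#' @export
set_body_mass <- function(series, body_mass, body_weight = NULL) {
  attr(series, "body_mass") <- body_mass
  attr(series, "body_weight") <-
    if (is.null(body_weight)) body_mass * 9.81 else body_weight
  series
}
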