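#' Per-step RMS estimator errors
#'
#' Root-mean-square differences between estimated and reference per-step
#' mean speeds and positions. The position error is offset-corrected per
#' trial (the trial-mean position difference is removed first), because the
#' estimator tracks position relative to the average centre of pressure at
#' consecutive foot strikes, not an absolute body landmark.
#'
#' @param est `data.frame` with per-step `vbar` and `pbar` estimates.
#' @param truth `data.frame` with per-step reference `vbar` and `pbar`,
#'   aligned step-for-step with `est`.
#' @return List with `rms_v` (m/s) and `rms_p` (m, offset-corrected).
#' @export
rms_step_errors <- function(est, truth) {
  if (nrow(est) != nrow(truth)) stop("step tables are not aligned")
  dv <- est$vbar - truth$vbar
  dp <- est$pbar - truth$pbar
  dp <- dp - mean(dp)
  list(rms_v = sqrt(mean(dv^2)), rms_p = sqrt(mean(dp^2)))
}

# mean +/- max(sd, eps) band of a tail segment
tail_band <- function(x, eps) {
  m <- mean(x)
  s <- max(stats::sd(x), eps)
  c(m - s, m + s)
}

#' Convergence time of a walking-speed series
#'
#' The convergence band is the mean plus or minus one standard deviation of
#' the speeds over the last `tail_frac` (default 20%) of the trial; the
#' convergence time is the first time the speed enters that band. A
#' degenerate band (zero tail SD) is widened by `eps` so band entry is
#' well-defined.
#'
#' @param t sample times (s).
#' @param v walking-speed series (m/s) on `t`.
#' @param duration trial duration (s); defaults to `max(t)`.
#' @param tail_frac trailing fraction that defines the band.
#' @param eps minimum half-width of the band (m/s).
#' @return Convergence time `t_cnvg` (s).
#' @export
convergence_time <- function(t, v, duration = max(t), tail_frac = 0.2,
                             eps = 1e-3) {
  if (duration <= 0) stop("duration must be positive")
  tail <- v[t >= duration * (1 - tail_frac)]
  if (length(tail) < 2) stop("tail segment is empty")
  band <- tail_band(tail, eps)
  inside <- which(v >= band[1] & v <= band[2])
  if (length(inside) == 0) stop("speed never enters the convergence band")
  t[inside[1]]
}

#' Convergence distance of a walking-speed series
#'
#' As [convergence_time()], but the band is built from the speeds over the
#' final `tail_dist` metres (default 30 m) of cumulative distance, and the
#' result is the cumulative distance walked at first band entry.
#'
#' @inheritParams convergence_time
#' @param tail_dist trailing distance that defines the band (m).
#' @return Convergence distance `d_cnvg` (m).
#' @export
convergence_distance <- function(t, v, tail_dist = 30, eps = 1e-3) {
  d <- pracma::cumtrapz(t, v)[, 1]
  total <- d[length(d)]
  if (total < tail_dist) stop("trial covers less than the tail distance")
  tail <- v[d >= total - tail_dist]
  band <- tail_band(tail, eps)
  inside <- which(v >= band[1] & v <= band[2])
  if (length(inside) == 0) stop("speed never enters the convergence band")
  d[inside[1]]
}

#' Mean walking speed over fixed-length distance sections
#'
#' Splits the walked distance into `n_sections` sections of
#' `section_length` metres at the given start offsets (by default evenly
#' spread over a `track_length`-metre course, each section centred in its
#' share of the track) and returns the mean speed, distance over time, for
#' each section. Section boundary times are linearly interpolated on the
#' cumulative-distance curve.
#'
#' @inheritParams convergence_time
#' @param section_length section length (m).
#' @param n_sections number of sections.
#' @param offsets optional explicit section start distances (m).
#' @param track_length nominal course length used to place default
#'   offsets (m).
#' @return Numeric vector of section mean speeds (m/s).
#' @export
section_speeds <- function(t, v, section_length = 10, n_sections = 6,
                           offsets = NULL, track_length = 150) {
  d <- pracma::cumtrapz(t, v)[, 1]
  if (is.null(offsets)) {
    spacing <- track_length / n_sections
    offsets <- (seq_len(n_sections) - 1) * spacing +
      (spacing - section_length) / 2
  }
  if (max(offsets) + section_length > d[length(d)] + 1e-9) {
    stop("trial does not cover the requested sections")
  }
  t_at <- function(dist) stats::approx(d, t, xout = dist, ties = "ordered")$y
  vapply(offsets, function(o) {
    section_length / (t_at(o + section_length) - t_at(o))
  }, numeric(1))
}

#' Least-squares linear fit and Pearson correlation
#'
#' Fits `y ~ b1 * x + b0` by least squares and reports Pearson's
#' correlation coefficient with its two-sided p-value.
#'
#' @param x,y paired speed measurements of equal length (>= 3).
#' @return List with `b1`, `b0`, `R`, `p`.
#' @export
linear_fit_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must be equal-length vectors with at least 3 elements")
  }
  if (stats::sd(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  list(b1 = unname(stats::coef(fit)[2]), b0 = unname(stats::coef(fit)[1]),
       R = unname(ct$estimate), p = ct$p.value)
}

#' Intra-subject variability of repeated speed measurements
#'
#' Sample standard deviation (n-1 denominator) of each subject's repeated
#' measurements, and the mean across subjects.
#'
#' @param speeds numeric vector of measurements.
#' @param subject grouping factor aligned with `speeds`.
#' @return List with `sd_intra` (named per-subject SDs) and `mean_sd`.
#' @export
intra_subject_sd <- function(speeds, subject) {
  groups <- split(speeds, subject)
  if (any(lengths(groups) < 2)) {
    stop("every subject needs at least two measurements")
  }
  sds <- vapply(groups, stats::sd, numeric(1))
  list(sd_intra = sds, mean_sd = mean(sds))
}

#' Per-footstep walking-speed series
#'
#' The walking speed attributed to each step is the mean belt speed plus
#' the estimated mean lab-frame speed over that step, sampled at the step's
#' closing contact and held constant between contacts (zero-order hold; the
#' value of the first step extends back to the trial start).
#'
#' @param steps step table with `t1`, `vtm_bar`, `vbar_kf`.
#' @param t time grid to sample onto (s).
#' @return `data.frame` with `t` and walking speed `v` (m/s).
#' @export
walking_speed_series <- function(steps, t) {
  if (nrow(steps) == 0) stop("no steps to build a speed series from")
  w <- steps$vtm_bar + steps$vbar_kf
  v <- stats::approx(steps$t1, w, xout = t, method = "constant",
                     f = 0, rule = 2, ties = "ordered")$y
  data.frame(t = t, v = v)
}

#' Ground-truth per-step means aligned to an estimated step table
#'
#' Averages the simulator's true lab-frame COM velocity and position over
#' each step interval `[t0, t1]` of an estimated step table, producing the
#' reference table for [rms_step_errors()].
#'
#' @param trial an `"sp_trial"` with a `truth` component.
#' @param steps step table with `t0` and `t1`.
#' @return `data.frame` with per-step `vbar` and `pbar` ground truth.
#' @export
step_truth <- function(trial, steps) {
  tt <- trial$truth$t
  out <- lapply(seq_len(nrow(steps)), function(i) {
    keep <- tt >= steps$t0[i] & tt <= steps$t1[i]
    c(vbar = mean(trial$truth$v_lab[keep]),
      pbar = mean(trial$truth$com[keep]))
  })
  as.data.frame(do.call(rbind, out))
}
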