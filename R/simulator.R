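#' Virtual walker parameters
#'
#' A deliberately minimal gait model whose forces are Newton-consistent by
#' construction: within each step the walker holds a constant belt-relative
#' speed plus a zero-mean sinusoidal oscillation, so the total fore-aft
#' force is exactly mass times the lab-frame acceleration of the centre of
#' mass (COM). Step duration follows the linear cadence law
#' `T_step = c0 - c1 * v` (floored), step length is speed times duration,
#' feet land alternately on the two belts symmetrically about the COM, and
#' vertical load transfers between feet over a raised-cosine double-support
#' window. The walker steers its belt-relative speed toward a command
#' (its preferred speed, or the belt speed in scripted trials) plus a weak
#' station-keeping correction toward its station point, which stands in for
#' human position control on the deck.
#'
#' Noise is injected at the sensor level so the estimator's measurement
#' covariance keeps its meaning: white noise on the fore-aft force channels
#' (expressed as an acceleration sigma), on the per-belt COP, and jitter on
#' step timing.
#'
#' @param mass body mass (kg).
#' @param v_pref preferred walking speed (m/s).
#' @param c0,c1 cadence law intercept (s) and slope (s^2/m).
#' @param t_step_min,t_step_max step-duration clamp (s).
#' @param ds_frac double-support fraction of step duration, in (0, 1).
#' @param osc_amp within-step speed oscillation amplitude (m/s).
#' @param k_station station-keeping gain (1/s).
#' @param station station point on the deck (m, lab frame).
#' @param sigma_acc accel-channel sensor noise sigma (m/s^2).
#' @param sigma_cop COP sensor noise sigma (m).
#' @param sigma_tstep step-time jitter sigma (s).
#' @param crossover_prob per-step probability of a belt crossover.
#' @return List of class `"sp_walker"`.
#' @export
walker_params <- function(mass = 70, v_pref = 1.3, c0 = 0.8, c1 = 0.2,
                          t_step_min = 0.3, t_step_max = 1.5,
                          ds_frac = 0.2, osc_amp = 0.15, k_station = 0.1,
                          station = 0, sigma_acc = 0.1, sigma_cop = 0.024,
                          sigma_tstep = 0.01, crossover_prob = 0) {
  stopifnot(mass > 0, v_pref > 0, ds_frac > 0, ds_frac < 1,
            t_step_min > 0, t_step_max > t_step_min,
            sigma_acc >= 0, sigma_cop >= 0, sigma_tstep >= 0,
            crossover_prob >= 0, crossover_prob <= 1)
  structure(list(mass = mass, v_pref = v_pref, c0 = c0, c1 = c1,
                 t_step_min = t_step_min, t_step_max = t_step_max,
                 ds_frac = ds_frac, osc_amp = osc_amp,
                 k_station = k_station, station = station,
                 sigma_acc = sigma_acc, sigma_cop = sigma_cop,
                 sigma_tstep = sigma_tstep, crossover_prob = crossover_prob),
            class = "sp_walker")
}

#' COP sensor noise that yields a target step-measurement scatter
#'
#' Step measurements read the causally filtered COP at single contact
#' samples, so white per-sample COP noise reaches them attenuated by the
#' low-pass filter's white-noise gain `g = sqrt(sum(h^2))` (`h` the filter
#' impulse response). The step position measurement averages two foot
#' positions, so a per-step position scatter of `sigma_p` requires a
#' per-sample sensor sigma of `sqrt(2) * sigma_p / g`. The corresponding
#' step-speed scatter is `2 * sigma_p / T_step`, consistent with the
#' published measurement covariance at a normal cadence.
#'
#' @param sigma_p target per-step position measurement scatter (m).
#' @param fs sampling rate (Hz).
#' @param order,fc low-pass filter order and cutoff (Hz).
#' @return Per-sample COP noise sigma (m) for [walker_params()].
#' @export
calibrate_cop_noise <- function(sigma_p = sqrt(0.6e-3), fs = 1000,
                                order = 3, fc = 25) {
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  h <- as.numeric(signal::filter(bf, c(1, rep(0, 4999))))
  sqrt(2) * sigma_p / sqrt(sum(h^2))
}

walker_is_stochastic <- function(walker) {
  walker$sigma_acc > 0 || walker$sigma_cop > 0 || walker$sigma_tstep > 0 ||
    walker$crossover_prob > 0
}

#' Scripted belt-speed profiles
#'
#' The five 60-s schedules used to exercise the estimator with a manually
#' controlled belt: constant 0.8, 1.3 and 1.8 m/s, a staircase rising from
#' 0.8 to 1.8 m/s in 0.2 m/s plateaus of 10 s each, and the same staircase
#' in reverse order.
#'
#' @param name one of `"const_0.8"`, `"const_1.3"`, `"const_1.8"`,
#'   `"staircase_up"`, `"staircase_down"`.
#' @return List of class `"sp_profile"` with the `name`, the schedule
#'   function `fn(t)` (m/s) and the nominal `duration` (s).
#' @export
scripted_profiles <- function(name) {
  stair <- c(0.8, 1.0, 1.2, 1.4, 1.6, 1.8)
  fn <- switch(name,
    const_0.8 = function(t) rep(0.8, length(t)),
    const_1.3 = function(t) rep(1.3, length(t)),
    const_1.8 = function(t) rep(1.8, length(t)),
    staircase_up = function(t) stair[pmin(floor(t / 10) + 1, 6)],
    staircase_down = function(t) rev(stair)[pmin(floor(t / 10) + 1, 6)],
    stop("unknown profile name: ", name)
  )
  structure(list(name = name, fn = fn, duration = 60),
            class = "sp_profile")
}

# belt executes a target schedule with a slew-rate limit (speed continuous)
rate_limit_speed <- function(target, dt, a_max, v0 = target[1]) {
  n <- length(target)
  v <- numeric(n)
  v[1] <- v0
  dv_max <- a_max * dt
  for (k in 2:n) {
    dv <- target[k] - v[k - 1]
    v[k] <- v[k - 1] + clamp(dv, -dv_max, dv_max)
  }
  pmax(v, 0)
}

# sequential step generation + per-tick COM kinematics for a known belt
# speed series
synth_walk <- function(walker, vtm, t, duration, follow_belt, jitters,
                       cross_draws, crossover_steps, com0 = 0) {
  n <- length(t)
  dt <- t[2] - t[1]
  v_lab <- numeric(n)
  com_cur <- com0
  t_c <- 0
  k <- 0
  belts <- c("left", "right")
  side_prev <- 2L # first step lands left
  rows <- list()
  while (t_c < duration - 1e-9) {
    k <- k + 1
    i_c <- round(t_c / dt) + 1
    v_cmd <- if (follow_belt) vtm[i_c] else walker$v_pref
    v_walk <- v_cmd + walker$k_station * (walker$station - com_cur)
    if (v_walk <= 0) stop("infeasible walker state: non-positive step speed")
    T_raw <- walker$c0 - walker$c1 * v_walk
    if (T_raw <= 0) stop("infeasible walker parameters: negative step time")
    T_k <- clamp(T_raw + jitters[k], walker$t_step_min, walker$t_step_max)
    L_k <- v_walk * T_k
    cross <- (k %in% crossover_steps) ||
      (k > 1 && cross_draws[k] < walker$crossover_prob)
    side <- if (k == 1) 1L else if (cross) side_prev else 3L - side_prev
    i_end <- min(round((t_c + T_k) / dt) + 1, n)
    if (i_end > i_c) {
      seg <- i_c:(i_end - 1)
      v_lab[seg] <- v_walk +
        walker$osc_amp * sin(2 * pi * (t[seg] - t_c) / T_k) - vtm[seg]
      com_cur <- com_cur + sum(v_lab[seg]) * dt
    }
    rows[[k]] <- data.frame(step = k, t_contact = t_c, belt = belts[side],
                            v_walk = v_walk, T_step = T_k, L_step = L_k,
                            y_place = NA_real_)
    side_prev <- side
    t_c <- t_c + T_k
  }
  v_lab[n] <- v_lab[n - 1]
  com <- com0 + dt * c(0, cumsum(v_lab[-n]))
  steps <- do.call(rbind, rows)
  # feet land symmetrically about the COM at contact
  ic <- round(steps$t_contact / dt) + 1
  steps$y_place <- com[ic] + steps$L_step / 2
  list(steps = steps, v_lab = v_lab, com = com)
}

#' Synthesize two-belt force-plate signals from a COM trajectory
#'
#' The total fore-aft force is mass times the discrete COM acceleration at
#' every sample (Newton-consistent before noise injection). Vertical load
#' is body weight, transferred between consecutive feet over a
#' raised-cosine double-support window so the belt forces always sum to
#' body weight once the first foot is loaded. Each belt's COP is the
#' force-weighted position of the feet on it, each foot riding the belt
#' from its placement point. Sensor noise (fore-aft force, COP) is added
#' last when `noise = TRUE`.
#'
#' @param traj `data.frame` with per-tick `t`, `com`, `v_lab`, `vtm`.
#' @param footsteps step table as produced by [synth_trial()] (`t_contact`,
#'   `belt`, `T_step`, `y_place`, ...).
#' @param walker a [walker_params()] object.
#' @param noise inject the walker's sensor noise (default `TRUE`).
#' @return A [force_plate_series()].
#' @export
synth_forces <- function(traj, footsteps, walker, noise = TRUE) {
  g <- 9.81
  n <- nrow(traj)
  t <- traj$t
  dt <- t[2] - t[1]
  mass <- walker$mass
  W <- mass * g
  K <- nrow(footsteps)
  ic <- round(footsteps$t_contact / dt) + 1
  ds <- walker$ds_frac * footsteps$T_step
  if (K > 1 && any(ic[-1] <= ic[-K])) {
    stop("footstep contacts must be strictly increasing")
  }
  if (K > 2) {
    tc <- footsteps$t_contact
    # a stance ends when the next foot's transfer completes; a further
    # contact inside that window would overlap stances on a belt
    if (any(tc[2:(K - 1)] + ds[2:(K - 1)] > tc[3:K] + 1e-12)) {
      stop("overlapping stances: a contact occurs before the previous ",
           "load transfer completes")
    }
  }

  ctv <- pracma::cumtrapz(t, traj$vtm)[, 1]
  a <- c(0, diff(traj$v_lab)) / dt

  fz <- matrix(0, n, 2)
  mom <- matrix(0, n, 2)
  colnames(fz) <- c("left", "right")
  ramp <- function(idx, i0, dsk) {
    # raised-cosine 0 -> 1 over the double-support window
    x <- (t[idx] - t[i0]) / dsk
    ifelse(x >= 1, 1, 0.5 * (1 - cos(pi * pmax(x, 0))))
  }
  for (k in seq_len(K)) {
    i0 <- ic[k]
    i_stop <- if (k < K) min(round((footsteps$t_contact[k + 1] +
                                      ds[k + 1]) / dt) + 1, n) else n
    idx <- i0:i_stop
    share <- ramp(idx, i0, ds[k])
    if (k < K) {
      i1 <- ic[k + 1]
      over <- idx >= i1
      share[over] <- share[over] - ramp(idx[over], i1, ds[k + 1])
    }
    fz_k <- W * share
    pos_k <- footsteps$y_place[k] - (ctv[idx] - ctv[i0])
    b <- if (footsteps$belt[k] == "left") 1L else 2L
    fz[idx, b] <- fz[idx, b] + fz_k
    mom[idx, b] <- mom[idx, b] + fz_k * pos_k
  }

  fz_tot <- fz[, 1] + fz[, 2]
  sh_l <- ifelse(fz_tot > 0, fz[, 1] / fz_tot, 0.5)
  fy_tot <- mass * a
  fy_l <- fy_tot * sh_l
  fy_r <- fy_tot * (1 - sh_l)
  floor_n <- 0.05 * W
  cop_l <- ifelse(fz[, 1] > floor_n, mom[, 1] / fz[, 1], NA_real_)
  cop_r <- ifelse(fz[, 2] > floor_n, mom[, 2] / fz[, 2], NA_real_)

  if (noise) {
    if (walker$sigma_acc > 0) {
      s <- mass * walker$sigma_acc / sqrt(2)
      fy_l <- fy_l + stats::rnorm(n, 0, s)
      fy_r <- fy_r + stats::rnorm(n, 0, s)
    }
    if (walker$sigma_cop > 0) {
      cop_l <- cop_l + stats::rnorm(n, 0, walker$sigma_cop)
      cop_r <- cop_r + stats::rnorm(n, 0, walker$sigma_cop)
    }
  }

  force_plate_series(t = t, fz_l = fz[, 1], fy_l = fy_l, copy_l = cop_l,
                     fz_r = fz[, 2], fy_r = fy_r, copy_r = cop_r,
                     vtm = traj$vtm, body_mass = mass, body_weight = W)
}

#' Simulate an open-loop (scripted belt) walking trial
#'
#' Generates a ground-truth COM trajectory and footstep schedule for a
#' virtual walker on a belt following a scripted speed profile, then
#' synthesizes the force-plate signals. The belt executes the schedule
#' with a slew-rate limit so its speed is continuous. By default the
#' walker follows the imposed belt speed (as a human does on a manually
#' controlled treadmill); set `follow_belt = FALSE` to keep it at its
#' preferred speed instead.
#'
#' @param walker a [walker_params()] object.
#' @param profile profile name (see [scripted_profiles()]), an
#'   `sp_profile`, a function of time, or a per-tick numeric series.
#' @param duration trial length (s).
#' @param seed RNG seed; mandatory when any walker noise is active.
#' @param fs sampling rate (Hz).
#' @param a_max belt slew-rate limit (m/s^2).
#' @param com0 initial COM position (m).
#' @param crossover_steps indices of steps forced onto the previous step's
#'   belt (crossovers).
#' @param follow_belt walker matches the belt speed (`TRUE`, scripted
#'   trials) or walks at `v_pref` (`FALSE`).
#' @return List of class `"sp_trial"`: `series` (the [force_plate_series()]),
#'   `truth` (per-tick `t`, `com`, `v_lab`, `vtm`), `footsteps`, `walker`,
#'   `profile`, `seed`, `fs`, `duration`.
#' @export
synth_trial <- function(walker, profile = "const_1.3", duration = 60,
                        seed = NULL, fs = 1000, a_max = 2, com0 = 0,
                        crossover_steps = integer(), follow_belt = TRUE) {
  nominal_T <- walker$c0 - walker$c1 * walker$v_pref
  if (duration <= 2 * nominal_T) stop("duration must exceed two steps")
  stochastic <- walker_is_stochastic(walker)
  if (stochastic) {
    if (is.null(seed)) stop("stochastic simulation requires an explicit seed")
    set.seed(seed)
  }
  n <- round(duration * fs) + 1
  t <- (seq_len(n) - 1) / fs
  prof_name <- NA_character_
  if (is.character(profile)) profile <- scripted_profiles(profile)
  if (inherits(profile, "sp_profile")) {
    prof_name <- profile$name
    target <- profile$fn(t)
  } else if (is.function(profile)) {
    target <- profile(t)
  } else {
    target <- rep_len(as.numeric(profile), n)
  }
  vtm <- rate_limit_speed(target, 1 / fs, a_max)

  max_steps <- ceiling(duration / walker$t_step_min) + 5
  jitters <- if (walker$sigma_tstep > 0) {
    stats::rnorm(max_steps, 0, walker$sigma_tstep)
  } else {
    numeric(max_steps)
  }
  cross_draws <- if (walker$crossover_prob > 0) {
    stats::runif(max_steps)
  } else {
    rep(1, max_steps)
  }
  walk <- synth_walk(walker, vtm, t, duration, follow_belt, jitters,
                     cross_draws, crossover_steps, com0 = com0)
  truth <- data.frame(t = t, com = walk$com, v_lab = walk$v_lab, vtm = vtm)
  series <- synth_forces(truth, walk$steps, walker,
                         noise = stochastic)
  structure(list(series = series, truth = truth, footsteps = walk$steps,
                 walker = walker, profile = prof_name, seed = seed,
                 fs = fs, duration = duration),
            class = "sp_trial")
}

#' Force a belt crossover at a given step of a simulated trial
#'
#' Reassigns the designated footstep to its predecessor's belt and
#' re-synthesizes the force signals (the COM trajectory is unchanged). The
#' loaded belt then never unloads across that contact, so no threshold
#' crossing occurs and the estimator sees one long inter-contact interval.
#' When the trial is stochastic the sensor noise is re-drawn from the
#' trial's recorded seed.
#'
#' @param trial an `"sp_trial"` from [synth_trial()].
#' @param step_index index (>= 2) of the footstep to merge.
#' @return The modified trial.
#' @export
inject_crossover <- function(trial, step_index) {
  fs_tab <- trial$footsteps
  if (step_index < 2 || step_index > nrow(fs_tab)) {
    stop("step_index must address an existing step after the first")
  }
  fs_tab$belt[step_index] <- fs_tab$belt[step_index - 1]
  # gait re-alternates from the crossover foot, so later steps flip belts
  K <- nrow(fs_tab)
  if (step_index < K) {
    for (k in (step_index + 1):K) {
      fs_tab$belt[k] <- setdiff(c("left", "right"), fs_tab$belt[k - 1])
    }
  }
  stochastic <- walker_is_stochastic(trial$walker)
  if (stochastic) set.seed(trial$seed)
  trial$series <- synth_forces(trial$truth, fs_tab, trial$walker,
                               noise = stochastic)
  trial$footsteps <- fs_tab
  trial
}
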