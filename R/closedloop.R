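#' Closed-loop self-paced treadmill simulation
#'
#' Runs the full loop with no hardware: per tick, the virtual walker
#' advances and its force-plate signals are synthesized, causally filtered
#' and fed to the Kalman estimator; at each detected foot contact the
#' estimator performs its per-footstep correction and, for accepted steps,
#' the speed controller issues a belt command which the belt model executes
#' as a rate-limited ramp. The belt starts at `cparams$v_start`
#' (0.8 m/s by default).
#'
#' @param walker a [walker_params()] object (the walker walks at its
#'   preferred speed with station keeping).
#' @param fparams a [filter_params()] object; its `dt` must match `1/fs`.
#' @param cparams a [controller_params()] object.
#' @param duration trial length (s).
#' @param seed RNG seed; mandatory when any walker noise is active.
#' @param fs sampling rate (Hz).
#' @param com0 initial COM position (m).
#' @param crossover_steps walker step indices forced onto the previous
#'   step's belt.
#' @param order,fc causal low-pass order and cutoff (Hz).
#' @param threshold,rearm contact detection levels (fractions of body
#'   weight).
#' @return List of class `"sp_trial"` with the synthesized `series`, the
#'   ground `truth` (`t`, `com`, `v_lab`, `vtm`), `footsteps`, and the
#'   in-loop `est` (per-tick estimates), `steps` (per-contact table) and
#'   `commands` (one row per accepted step).
#' @export
closed_loop <- function(walker, fparams = filter_params(),
                        cparams = controller_params(), duration = 60,
                        seed = NULL, fs = 1000, com0 = 0,
                        crossover_steps = integer(), order = 3, fc = 25,
                        threshold = 0.2, rearm = 0.1) {
  stochastic <- walker_is_stochastic(walker)
  if (stochastic) {
    if (is.null(seed)) stop("stochastic simulation requires an explicit seed")
    set.seed(seed)
  }
  dt <- 1 / fs
  if (abs(fparams$dt - dt) > 1e-9 * dt) {
    stop("filter dt must equal the simulation sampling interval")
  }
  n <- round(duration * fs) + 1
  t <- (seq_len(n) - 1) * dt
  g <- 9.81
  mass <- walker$mass
  W <- mass * g
  thr <- threshold * W
  low <- rearm * W
  floor_n <- 0.05 * W

  # pre-drawn sensor noise and step jitter (deterministic given seed)
  zn <- numeric(n)
  fyn_l <- if (walker$sigma_acc > 0) {
    stats::rnorm(n, 0, mass * walker$sigma_acc / sqrt(2))
  } else zn
  fyn_r <- if (walker$sigma_acc > 0) {
    stats::rnorm(n, 0, mass * walker$sigma_acc / sqrt(2))
  } else zn
  copn_l <- if (walker$sigma_cop > 0) stats::rnorm(n, 0, walker$sigma_cop)
            else zn
  copn_r <- if (walker$sigma_cop > 0) stats::rnorm(n, 0, walker$sigma_cop)
            else zn
  max_steps <- ceiling(duration / walker$t_step_min) + 5
  jitters <- if (walker$sigma_tstep > 0) {
    stats::rnorm(max_steps, 0, walker$sigma_tstep)
  } else numeric(max_steps)
  cross_draws <- if (walker$crossover_prob > 0) stats::runif(max_steps)
                 else rep(1, max_steps)

  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  bq <- bf$b
  aq <- bf$a
  m_ord <- length(aq) - 1
  Z <- matrix(0, m_ord + 1, 5) # DF2T states; extra zero row

  # Kalman scalars (same recursion as run_offline)
  h2 <- dt^2 / 2
  q00 <- fparams$Q_add[1, 1]; q01 <- fparams$Q_add[1, 2]
  q11 <- fparams$Q_add[2, 2]
  r00 <- fparams$R[1, 1]; r01 <- fparams$R[1, 2]; r11 <- fparams$R[2, 2]
  p <- 0; v <- 0
  P00 <- fparams$P0[1, 1]; P01 <- fparams$P0[1, 2]; P11 <- fparams$P0[2, 2]
  accp <- 0; accv <- 0; nacc <- 0L
  t_prev <- NA_real_; cop_prev <- NA_real_; ctv_prev <- NA_real_

  # controller / belt
  v_belt <- cparams$v_start
  cmd_v <- v_belt
  cmd_a <- cparams$a_max

  # walker
  com <- com0
  v_lab_prev <- 0
  next_contact <- 0
  step_k <- 0L
  side_prev <- 2L
  belts <- c("left", "right")
  v_walk_cur <- walker$v_pref
  t_step_start <- 0
  T_cur <- walker$c0 - walker$c1 * walker$v_pref
  fin_pos <- 0; fin_belt <- 1L; fin_tc <- 0; fin_ds <- 0.1
  fout_pos <- 0; fout_belt <- 1L; fout_active <- FALSE

  armed1 <- TRUE; armed2 <- TRUE
  fzlf_prev <- 0; fzrf_prev <- 0
  ctv <- 0; vb_prev <- v_belt

  # logs
  l_fzl <- numeric(n); l_fzr <- numeric(n)
  l_fyl <- numeric(n); l_fyr <- numeric(n)
  l_cpl <- numeric(n); l_cpr <- numeric(n)
  l_vtm <- numeric(n); l_com <- numeric(n); l_vlab <- numeric(n)
  ep <- numeric(n); ev <- numeric(n)
  eP00 <- numeric(n); eP01 <- numeric(n); eP11 <- numeric(n)
  srows <- list(); n_steps <- 0L
  crows <- list(); n_cmd <- 0L
  frows <- list()

  b1 <- bq[1]
  for (k in seq_len(n)) {
    tk <- t[k]
    if (k > 1) ctv <- ctv + dt * (vb_prev + v_belt) / 2
    vb_prev <- v_belt

    # walker initiates a new step
    if (tk >= next_contact - 1e-9) {
      step_k <- step_k + 1L
      v_walk_cur <- walker$v_pref +
        walker$k_station * (walker$station - com)
      if (v_walk_cur <= 0) {
        stop("infeasible walker state: non-positive step speed")
      }
      T_raw <- walker$c0 - walker$c1 * v_walk_cur
      if (T_raw <= 0) stop("infeasible walker parameters: negative step time")
      T_cur <- clamp(T_raw + jitters[step_k], walker$t_step_min,
                     walker$t_step_max)
      L_cur <- v_walk_cur * T_cur
      cross <- (step_k %in% crossover_steps) ||
        (step_k > 1L && cross_draws[step_k] < walker$crossover_prob)
      side <- if (step_k == 1L) 1L else if (cross) side_prev
              else 3L - side_prev
      if (fout_active && step_k > 1L) {
        # previous transfer finished long ago (ds < T); overwrite is safe
        fout_active <- FALSE
      }
      if (step_k > 1L) {
        fout_pos <- fin_pos
        fout_belt <- fin_belt
        fout_active <- TRUE
      }
      fin_pos <- com + L_cur / 2
      fin_belt <- side
      fin_tc <- tk
      fin_ds <- walker$ds_frac * T_cur
      frows[[step_k]] <- data.frame(step = step_k, t_contact = tk,
                                    belt = belts[side],
                                    v_walk = v_walk_cur, T_step = T_cur,
                                    L_step = L_cur, y_place = fin_pos)
      side_prev <- side
      t_step_start <- tk
      next_contact <- tk + T_cur
    }

    # COM kinematics
    v_lab <- v_walk_cur +
      walker$osc_amp * sin(2 * pi * (tk - t_step_start) / T_cur) - v_belt
    a_true <- if (k == 1) 0 else (v_lab - v_lab_prev) / dt
    v_lab_prev <- v_lab

    # vertical load shares and per-belt signals
    share_in <- if (tk < fin_tc + fin_ds) {
      0.5 * (1 - cos(pi * (tk - fin_tc) / fin_ds))
    } else {
      fout_active <- FALSE
      1
    }
    fzl <- 0; fzr <- 0; moml <- 0; momr <- 0
    fz_in <- W * share_in
    if (fin_belt == 1L) {
      fzl <- fzl + fz_in; moml <- moml + fz_in * fin_pos
    } else {
      fzr <- fzr + fz_in; momr <- momr + fz_in * fin_pos
    }
    if (fout_active) {
      fz_out <- W * (1 - share_in)
      if (fout_belt == 1L) {
        fzl <- fzl + fz_out; moml <- moml + fz_out * fout_pos
      } else {
        fzr <- fzr + fz_out; momr <- momr + fz_out * fout_pos
      }
    }
    fzt <- fzl + fzr
    shl <- if (fzt > 0) fzl / fzt else 0.5
    fy_tot <- mass * a_true
    fyl <- fy_tot * shl + fyn_l[k]
    fyr <- fy_tot * (1 - shl) + fyn_r[k]
    copl <- if (fzl > floor_n) moml / fzl + copn_l[k] else NA_real_
    copr <- if (fzr > floor_n) momr / fzr + copn_r[k] else NA_real_
    moml_meas <- if (fzl > floor_n) copl * fzl else 0
    momr_meas <- if (fzr > floor_n) copr * fzr else 0

    # causal low-pass (direct form II transposed), 5 channels
    xs <- c(fzl, fzr, fyl + fyr, moml_meas, momr_meas)
    ys <- b1 * xs + Z[1, ]
    for (j in seq_len(m_ord)) {
      Z[j, ] <- bq[j + 1] * xs - aq[j + 1] * ys + Z[j + 1, ]
    }
    fzlf <- ys[1]; fzrf <- ys[2]; fyf <- ys[3]
    momlf <- ys[4]; momrf <- ys[5]

    # Kalman time update
    ak <- fyf / mass
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

    # contact detection with hysteresis
    hit1 <- armed1 && k > 1 && fzlf > thr && fzlf_prev <= thr
    hit2 <- armed2 && k > 1 && fzrf > thr && fzrf_prev <= thr
    ev_belt <- 0L
    if (hit1 && hit2) {
      ev_belt <- if (fzlf >= fzrf) 1L else 2L
      armed1 <- FALSE; armed2 <- FALSE
    } else if (hit1) {
      ev_belt <- 1L; armed1 <- FALSE
    } else if (hit2) {
      ev_belt <- 2L; armed2 <- FALSE
    }
    if (ev_belt > 0L) {
      cop_now <- if (ev_belt == 1L) momlf / fzlf else momrf / fzrf
      if (!is.na(t_prev)) {
        dur <- tk - t_prev
        travel <- ctv - ctv_prev
        yf1 <- cop_now
        yf0 <- cop_prev - travel
        vtm_bar <- travel / dur
        vmes <- (yf1 - yf0) / dur - vtm_bar
        pmes <- (yf1 + yf0) / 2
        accepted <- dur <= fparams$max_step && dur >= fparams$min_step
        pbar <- accp / nacc
        vbar <- accv / nacc
        applied <- FALSE
        if (accepted && nacc > 0L) {
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
          # one belt command per accepted step
          v_tgt <- clamp(vtm_bar + cparams$G_v * vbar +
                           cparams$G_p * (pbar - cparams$p0),
                         cparams$v_min, cparams$v_max)
          a_tgt <- clamp((v_tgt - vtm_bar) / cparams$dt_tgt,
                         -cparams$a_max, cparams$a_max)
          cmd_v <- v_tgt
          cmd_a <- a_tgt
          n_cmd <- n_cmd + 1L
          crows[[n_cmd]] <- data.frame(t_issue = tk, vtm_tgt = v_tgt,
                                       atm_tgt = a_tgt)
        }
        n_steps <- n_steps + 1L
        srows[[n_steps]] <- data.frame(
          t0 = t_prev, t1 = tk, belt = belts[ev_belt], y_f0 = yf0,
          y_f1 = yf1, vtm_bar = vtm_bar, vmes = vmes, pmes = pmes,
          accepted = accepted, pbar_kf = pbar, vbar_kf = vbar,
          applied = applied)
      }
      accp <- 0; accv <- 0; nacc <- 0L
      t_prev <- tk
      cop_prev <- cop_now
      ctv_prev <- ctv
    }
    armed1 <- armed1 || fzlf < low
    armed2 <- armed2 || fzrf < low
    fzlf_prev <- fzlf
    fzrf_prev <- fzrf

    # logs
    l_fzl[k] <- fzl; l_fzr[k] <- fzr
    l_fyl[k] <- fyl; l_fyr[k] <- fyr
    l_cpl[k] <- copl; l_cpr[k] <- copr
    l_vtm[k] <- v_belt; l_com[k] <- com; l_vlab[k] <- v_lab
    ep[k] <- p; ev[k] <- v
    eP00[k] <- P00; eP01[k] <- P01; eP11[k] <- P11

    # belt ramps toward its command (takes effect next tick); feet ride it
    dv <- cmd_v - v_belt
    mv <- abs(cmd_a) * dt
    v_belt <- if (abs(dv) <= mv) cmd_v else v_belt + sign(dv) * mv
    v_belt <- max(v_belt, 0)
    fin_pos <- fin_pos - vb_prev * dt
    if (fout_active) fout_pos <- fout_pos - vb_prev * dt
    com <- com + v_lab * dt
  }

  series <- force_plate_series(t = t, fz_l = l_fzl, fy_l = l_fyl,
                               copy_l = l_cpl, fz_r = l_fzr, fy_r = l_fyr,
                               copy_r = l_cpr, vtm = l_vtm,
                               body_mass = mass, body_weight = W)
  empty_steps <- data.frame(t0 = numeric(0), t1 = numeric(0),
                            belt = character(0), y_f0 = numeric(0),
                            y_f1 = numeric(0), vtm_bar = numeric(0),
                            vmes = numeric(0), pmes = numeric(0),
                            accepted = logical(0), pbar_kf = numeric(0),
                            vbar_kf = numeric(0), applied = logical(0))
  structure(list(
    series = series,
    truth = data.frame(t = t, com = l_com, v_lab = l_vlab, vtm = l_vtm),
    footsteps = do.call(rbind, frows),
    est = data.frame(t = t, p_kf = ep, v_kf = ev, P00 = eP00,
                     P01 = eP01, P11 = eP11),
    steps = if (n_steps > 0L) do.call(rbind, srows) else empty_steps,
    commands = if (n_cmd > 0L) do.call(rbind, crows) else
      data.frame(t_issue = numeric(0), vtm_tgt = numeric(0),
                 atm_tgt = numeric(0)),
    walker = walker, fparams = fparams, cparams = cparams,
    profile = "closed_loop", seed = seed, fs = fs, duration = duration),
    class = "sp_trial")
}
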