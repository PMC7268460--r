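# walker with all sensor noise off (deterministic trials)
quiet_walker <- function(...) {
  walker_params(sigma_acc = 0, sigma_cop = 0, sigma_tstep = 0, ...)
}

# Independent batch joint-Gaussian conditional-mean solver.
# Model: x_0 ~ N(0, P0); x_k = A x_{k-1} + B a_k + B eps_k,
# eps_k ~ N(0, sigma_a2); z_k = x_k + v_k, v_k ~ N(0, R) after every tick.
# Returns E[x_N | z_1..z_N] computed by one dense joint-Gaussian solve over
# the latent (x_0, eps_1..eps_N), never by the sequential recursion.
batch_posterior_mean <- function(a, z, params) {
  N <- length(a)
  A <- params$A
  B <- params$B
  Apow <- vector("list", N + 1)
  Apow[[1]] <- diag(2)
  for (k in 1:N) Apow[[k + 1]] <- A %*% Apow[[k]]
  xs <- matrix(0, 2, N)
  x <- c(0, 0)
  for (k in 1:N) {
    x <- as.numeric(A %*% x + B * a[k])
    xs[, k] <- x
  }
  M <- matrix(0, 2 * N, 2 + N)
  for (k in 1:N) {
    rows <- (2 * k - 1):(2 * k)
    M[rows, 1:2] <- Apow[[k + 1]]
    for (j in 1:k) M[rows, 2 + j] <- Apow[[k - j + 1]] %*% B
  }
  C <- diag(c(0, 0, rep(params$sigma_a2, N)))
  C[1:2, 1:2] <- params$P0
  Rblk <- kronecker(diag(N), params$R)
  resid <- as.numeric(t(z)) - as.numeric(xs)
  S <- M %*% C %*% t(M) + Rblk
  theta <- C %*% t(M) %*% solve(S, resid)
  as.numeric(xs[, N] + M[(2 * N - 1):(2 * N), ] %*% theta)
}

# the package's recursion on the same instance (one time update per
# measurement update, so the step means equal the instantaneous state)
kf_run_instance <- function(a, z, params) {
  st <- kf_init(params)
  for (k in seq_along(a)) {
    st <- kf_time_update(st, a[k], params)
    meas <- data.frame(pmes = z[k, 1], vmes = z[k, 2], accepted = TRUE)
    st <- kf_measurement_update(st, meas, params)
  }
  st$x
}

# Independently coded online estimator loop: matrix algebra with solve(),
# its own trapezoidal belt-travel bookkeeping, fed tick by tick.
online_loop_oracle <- function(series, params) {
  filt <- lowpass(series)
  contacts <- detect_contacts(filt)
  a <- accel_measurement(filt)
  n <- nrow(series)
  A <- params$A
  B <- params$B
  x <- c(0, 0)
  P <- params$P0
  acc <- c(0, 0)
  nacc <- 0
  ref <- NULL
  ctv <- pracma::cumtrapz(series$t, series$vtm)[, 1]
  cmap <- integer(n)
  cmap[contacts$sample] <- seq_len(nrow(contacts))
  p_out <- numeric(n)
  v_out <- numeric(n)
  for (k in seq_len(n)) {
    x <- as.numeric(A %*% x + B * a[k])
    P <- A %*% P %*% t(A) + params$Q_add
    acc <- acc + x
    nacc <- nacc + 1
    j <- cmap[k]
    if (j > 0) {
      if (!is.null(ref)) {
        dur <- series$t[k] - ref$t
        travel <- ctv[k] - ref$ctv
        yf1 <- contacts$cop[j]
        yf0 <- ref$cop - travel
        if (dur <= params$max_step && dur >= params$min_step) {
          z <- c((yf1 + yf0) / 2, (yf1 - yf0) / dur - travel / dur)
          K <- P %*% solve(P + params$R)
          x <- as.numeric(x + K %*% (z - acc / nacc))
          P <- (diag(2) - K) %*% P
          P <- (P + t(P)) / 2
        }
      }
      acc <- c(0, 0)
      nacc <- 0
      ref <- list(t = series$t[k], cop = contacts$cop[j], ctv = ctv[k])
    }
    p_out[k] <- x[1]
    v_out[k] <- x[2]
  }
  data.frame(t = series$t, p_kf = p_out, v_kf = v_out)
}

# force-plate series with no contacts and a pure fore-aft force channel
accel_only_series <- function(fy_total, mass = 70, fs = 1000) {
  n <- length(fy_total)
  force_plate_series(fz_l = numeric(n), fy_l = fy_total,
                     copy_l = rep(NA_real_, n), fz_r = numeric(n),
                     fy_r = numeric(n), copy_r = rep(NA_real_, n),
                     vtm = numeric(n), fs = fs, body_mass = mass)
}
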