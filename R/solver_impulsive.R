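# Adaptive Dormand-Prince RK45 with a bounded maximum step. Used for the
# impulsive comparator and the adaptive-solver benchmark variants; no ODE
# suite is assumed from the environment.
rk45_integrate <- function(f, t0, t1, y0, max_step, rtol = 1e-8, atol = 1e-10,
                           min_step = 1e-12) {
  # Dormand-Prince (ode45) tableau
  a21 <- 1 / 5
  a31 <- 3 / 40; a32 <- 9 / 40
  a41 <- 44 / 45; a42 <- -56 / 15; a43 <- 32 / 9
  a51 <- 19372 / 6561; a52 <- -25360 / 2187; a53 <- 64448 / 6561; a54 <- -212 / 729
  a61 <- 9017 / 3168; a62 <- -355 / 33; a63 <- 46732 / 5247; a64 <- 49 / 176
  a65 <- -5103 / 18656
  b1 <- 35 / 384; b3 <- 500 / 1113; b4 <- 125 / 192; b5 <- -2187 / 6784
  b6 <- 11 / 84
  e1 <- 71 / 57600; e3 <- -71 / 16695; e4 <- 71 / 1920; e5 <- -17253 / 339200
  e6 <- 22 / 525; e7 <- -1 / 40
  c2 <- 1 / 5; c3 <- 3 / 10; c4 <- 4 / 5; c5 <- 8 / 9

  t <- t0; y <- y0
  h <- min(max_step, t1 - t0)
  k1 <- f(t, y)
  n_evals <- 1
  while (t < t1 - 1e-13) {
    h <- min(h, max_step)
    last <- h >= t1 - t
    if (last) h <- t1 - t
    if (!last && h < min_step) {
      stop("rk45: step size underflow at t = ", t,
           " (right-hand side too stiff or discontinuous)", call. = FALSE)
    }
    k2 <- f(t + c2 * h, y + h * a21 * k1)
    k3 <- f(t + c3 * h, y + h * (a31 * k1 + a32 * k2))
    k4 <- f(t + c4 * h, y + h * (a41 * k1 + a42 * k2 + a43 * k3))
    k5 <- f(t + c5 * h, y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4))
    k6 <- f(t + h, y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5))
    ynew <- y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6)
    k7 <- f(t + h, ynew)
    n_evals <- n_evals + 6
    err <- h * abs(e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7)
    tol <- atol + rtol * max(abs(y), abs(ynew))
    if (!is.finite(ynew) || !is.finite(err)) {
      h <- h / 2
      next
    }
    if (err <= tol) {
      t <- t + h; y <- ynew; k1 <- k7 # FSAL
    }
    fac <- if (err > 0) 0.9 * (tol / err)^0.2 else 5
    h <- h * min(5, max(0.2, fac))
  }
  list(y = y, n_evals = n_evals)
}

#' Impulsive radiotherapy model (stop-and-restart integration)
#'
#' The conventional treatment model: untreated growth dynamics are integrated
#' between treatment times with an adaptive Runge-Kutta (Dormand-Prince)
#' method whose maximum step is bounded, and at each treatment time the state
#' is multiplied by the LQ surviving fraction, v -> v * SF. The returned
#' trajectory records both the pre- and post-impulse value at each treatment
#' time.
#'
#' Only ordinary (mu = 1) dynamics are supported: stopping and restarting the
#' integration would discard the history on which a Caputo fractional
#' derivative depends.
#'
#' @param p An [growth_parameters()] object.
#' @param r A [radiation_parameters()] object.
#' @param proto A [treatment_protocol()] object (only `times_days` and
#'   `dose_gy` are used; windows play no role in the impulsive model).
#' @param v0 Initial volume (cm^3).
#' @param t_end Final time (days).
#' @param mu Must be 1; any other value is an error.
#' @param max_step Maximum integrator step (days). Default 1/288.
#' @param rtol,atol Local error tolerances.
#' @param sample_times Optional extra times at which the state is recorded
#'   exactly (the integrator steps to them).
#' @return An `rg_trajectory` whose `times` contain the sample times, `t_end`,
#'   and each treatment time twice (pre- and post-impulse).
#' @export
solve_impulsive <- function(p, r, proto, v0, t_end, mu = 1, max_step = 1 / 288,
                            rtol = 1e-9, atol = 1e-12, sample_times = NULL) {
  stopifnot(inherits(p, "rg_growth"), inherits(r, "rg_radiation"),
            inherits(proto, "rg_protocol"))
  if (!identical(as.numeric(mu), 1)) {
    stop("solve_impulsive: only ordinary (mu = 1) models are supported; ",
         "the Caputo history would be lost at each restart", call. = FALSE)
  }
  sf <- lq_survival_fraction(r, proto$dose_gy)
  f <- function(t, v) growth_rate(p, v)
  taus <- proto$times_days[proto$times_days >= 0 & proto$times_days < t_end]
  marks <- sort(unique(c(taus, sample_times, t_end)))
  marks <- marks[marks > 0 & marks <= t_end + 1e-12]

  times <- 0; vols <- v0
  t_cur <- 0; v_cur <- v0; n_evals <- 0
  if (any(abs(taus) < 1e-12)) { # fraction delivered at the clock origin
    v_cur <- v_cur * sf
    times <- c(times, 0); vols <- c(vols, v_cur)
  }
  for (m in marks) {
    if (m > t_cur + 1e-13) {
      res <- rk45_integrate(f, t_cur, m, v_cur, max_step, rtol, atol)
      v_cur <- res$y; n_evals <- n_evals + res$n_evals
      t_cur <- m
    }
    times <- c(times, m); vols <- c(vols, v_cur)
    if (any(abs(taus - m) < 1e-12)) {
      v_cur <- v_cur * sf
      times <- c(times, m); vols <- c(vols, v_cur) # post-impulse record
    }
  }
  new_trajectory(times, vols, 1, max_step, "impulsive_rk45",
                 negative = any(vols < 0), n_evals = n_evals)
}

# Continuous-death analogue solved with the same adaptive RK45 (the `ode45`
# route); `hard = TRUE` uses exact indicator windows and is expected to be
# slow or to fail by step-size underflow.
solve_continuous_rk45 <- function(p, r, proto, v0, t_end, max_step = 1 / 288,
                                  rtol = 1e-8, atol = 1e-10,
                                  sample_times = NULL, hard = FALSE) {
  f <- function(t, v) treated_rhs(p, r, proto, t, v, hard = hard)
  marks <- sort(unique(c(sample_times, t_end)))
  marks <- marks[marks > 0 & marks <= t_end + 1e-12]
  times <- 0; vols <- v0
  t_cur <- 0; v_cur <- v0; n_evals <- 0
  for (m in marks) {
    res <- rk45_integrate(f, t_cur, m, v_cur, max_step, rtol, atol)
    v_cur <- res$y; n_evals <- n_evals + res$n_evals; t_cur <- m
    times <- c(times, m); vols <- c(vols, v_cur)
  }
  new_trajectory(times, vols, 1, max_step, "continuous_rk45",
                 negative = any(vols < 0), n_evals = n_evals)
}

#' Convergence of the continuous death rate to the impulsive model
#'
#' For a sequence of shrinking treatment-window lengths, integrates the
#' continuous-death model (Caputo solver at mu = 1, step `tw/4` so every
#' window is resolved) and compares it with the impulsive model at off-window
#' sample times. As tw -> 0 each smoothed window tends to a Dirac impulse
#' carrying the same LQ kill, so the deviation must shrink with tw.
#'
#' @param p,r,proto,v0,t_end As in [solve_impulsive()]; `proto$tw_days` is
#'   overridden by each element of `tw_list`.
#' @param tw_list Positive, decreasing window lengths (days).
#' @param sample_times Off-window comparison times; default midpoints between
#'   consecutive treatment times plus `t_end`.
#' @return A data.frame with one row per `tw`: end volumes of both models and
#'   the maximum absolute deviation over the sample times.
#' @export
compare_death_models <- function(p, r, proto, v0, t_end,
                                 tw_list = c(1 / 48, 1 / 96, 1 / 144, 1 / 288),
                                 sample_times = NULL) {
  if (any(tw_list <= 0) || any(diff(tw_list) >= 0)) {
    stop("compare_death_models: tw_list must be positive and decreasing",
         call. = FALSE)
  }
  taus <- proto$times_days
  if (is.null(sample_times)) {
    mids <- if (length(taus) > 1) (taus[-1] + taus[-length(taus)]) / 2 else numeric(0)
    sample_times <- sort(unique(c(mids, taus[length(taus)] + 0.5, t_end)))
    sample_times <- sample_times[sample_times > 0 & sample_times <= t_end]
  }
  imp <- solve_impulsive(p, r, proto, v0, t_end, sample_times = sample_times)
  v_imp <- trajectory_at_post(imp, sample_times)

  rows <- lapply(tw_list, function(tw) {
    pr <- treatment_protocol(proto$dose_gy, proto$times_days, tw)
    h <- tw / 4
    tr <- solve_caputo_abm(treated_model(p, r, pr), v0, t_end, mu = 1, h = h)
    v_cont <- trajectory_at(tr, sample_times)
    data.frame(tw = tw,
               end_volume_continuous = v_cont[length(v_cont)],
               end_volume_impulsive = v_imp[length(v_imp)],
               max_deviation = max(abs(v_cont - v_imp)))
  })
  do.call(rbind, rows)
}

# Interpolation on an impulsive trajectory taking the post-impulse branch at
# duplicated treatment times (sample times are off-window so either works
# except exactly at a treatment time).
trajectory_at_post <- function(traj, times) {
  idx <- !duplicated(traj$times, fromLast = TRUE)
  approx(traj$times[idx], traj$volumes[idx], xout = times)$y
}

# Pre-impulse branch: matches the measurement convention that a volume taken
# on a treatment day precedes that day's fraction.
trajectory_at_pre <- function(traj, times) {
  idx <- !duplicated(traj$times)
  approx(traj$times[idx], traj$volumes[idx], xout = times)$y
}
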