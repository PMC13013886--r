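# Dual-detector run-and-tumble navigation model. Head and tail sensory
# inputs are integrated into confidence variables Q_H and Q_T with a single
# memory timescale; their difference sets the speed (orthokinesis) and the
# tumble rate (klinokinesis), and the head detector additionally gates
# directed taxis turns toward the source.

#' Model parameters for the dual-detector navigator
#'
#' Defaults follow the published baseline locomotion values (tumble rate
#' 0.067/s, speed 0.064 +/- 0.03 mm/s, rotational diffusivity 0.02 rad^2/s,
#' memory rate 1/60 s^-1, unit sensitivities, unit speed-noise s.d.).
#' Quantities the source leaves free (klinokinesis strength, turning-kernel
#' mixture, taxis threshold, capture radius) are exposed here with the
#' package defaults discussed in the methods vignette.
#'
#' @param gamma0 Baseline tumble rate (1/s).
#' @param U0 Baseline speed (mm/s).
#' @param U1 Speed modulation magnitude (mm/s).
#' @param lambda_K Klinokinesis strength (dimensionless).
#' @param D_R Rotational diffusivity (rad^2/s).
#' @param k1 Confidence decay rate, the inverse memory timescale (1/s).
#' @param k2_H,k2_T Head and tail input sensitivities (1/s).
#' @param eta_sd S.d. of the per-step Gaussian speed noise.
#' @param eta_mode `"draw"` redraws the speed noise every step; `"constant"`
#'   treats `eta_sd` as a fixed offset.
#' @param q_noise_sd S.d. of the Gaussian readout noise applied to each
#'   confidence when it enters the motor mapping (relative to the unit
#'   confidence scale). The stored confidences are noise-free.
#' @param alpha Turning-kernel mixture weight of the uniform component.
#' @param sigma Width (rad) of the reversal-biased wrapped Gaussian
#'   component, centred at pi.
#' @param C0 Reference concentration (mol/m^3), the droplet surface value.
#' @param Cdot0 Reference concentration rate (mol/m^3/s).
#' @param taxis_threshold Concentration above which taxis turns are armed.
#' @param taxis_mode When is an armed taxis turn executed? In
#'   `"tumble-gated"` mode (default) a reorientation event drawn at the
#'   tumble rate is made perfectly accurate toward the source instead of
#'   random, so directed turns are rate-limited by the klinokinesis
#'   machinery (a worm heading down-gradient loses head confidence, its
#'   tumble rate rises, and the resulting turn is a corrective taxis turn).
#'   In `"continuous"` mode the heading is overridden on every step on
#'   which the arming conditions hold.
#' @param q_clamp Interval to which both confidences are clamped.
#' @param capture_radius Distance (mm) from the source at which a worm
#'   counts as having found it (and is frozen in place thereafter).
#' @return An object of class `model_params`.
#' @export
model_params <- function(gamma0 = 0.067, U0 = 0.064, U1 = 0.03,
                         lambda_K = 2, D_R = 0.02, k1 = 1 / 60,
                         k2_H = 1, k2_T = 1, eta_sd = 1,
                         eta_mode = c("draw", "constant"),
                         q_noise_sd = 0.05,
                         alpha = 0.3, sigma = 0.6,
                         C0 = 0.01, Cdot0 = C0 / 60,
                         taxis_threshold = 0.1 * C0,
                         taxis_mode = c("tumble-gated", "continuous"),
                         q_clamp = c(-1, 1), capture_radius = 3) {
  eta_mode <- match.arg(eta_mode)
  taxis_mode <- match.arg(taxis_mode)
  stopifnot(gamma0 >= 0, U0 >= 0, U1 >= 0, D_R >= 0, k1 >= 0,
            k2_H >= 0, k2_T >= 0, eta_sd >= 0, q_noise_sd >= 0,
            alpha >= 0, alpha <= 1, sigma > 0, C0 > 0, Cdot0 > 0,
            length(q_clamp) == 2, q_clamp[1] < q_clamp[2],
            capture_radius > 0)
  structure(as.list(environment()), class = "model_params")
}

#' Model parameters referenced to a navigation-plane field
#'
#' Links the sensory reference scales to the concentration field a cohort
#' actually navigates. The tail detector's preferred concentration `C0` is
#' placed one decade below the peak concentration at the source position on
#' the plane, so the arena spans all three tail regimes: a quiescent far
#' field (`C << C0`), an "anchoring" band at moderate concentration where
#' the tail slows the worm and raises tumbling, and a suppressed tail
#' (`Q_T -> -1`) near the source that produces the sprint. The reference
#' rate and taxis threshold scale with `C0` as in [model_params()].
#'
#' @param slice A `field_slice` the cohort will navigate.
#' @param c0_factor `C0` as a fraction of the source-position peak.
#' @param ... Further arguments passed to [model_params()].
#' @return A [model_params()] object.
#' @export
arena_params <- function(slice, c0_factor = 0.1, ...) {
  ref <- reference_concentration(slice)
  if (ref <= 0) stop("slice has no positive concentration at the source")
  model_params(C0 = c0_factor * ref, ...)
}

#' Single-worm state
#'
#' @param r Position (mm), length-2.
#' @param theta Heading (rad), wrapped to `(-pi, pi]`.
#' @param Q_H,Q_T Head and tail confidence variables.
#' @param head_enabled,tail_enabled Detector enable flags; a disabled
#'   detector's confidence is frozen at zero.
#' @param last_C Concentration sampled at the previous step (for the
#'   along-trajectory rate), `NA` before the first sample.
#' @return An object of class `worm_state`.
#' @export
worm_state <- function(r = c(0, 0), theta = 0, Q_H = 0, Q_T = 0,
                       head_enabled = TRUE, tail_enabled = TRUE,
                       last_C = NA_real_) {
  structure(list(r = as.numeric(r), theta = wrap_angle(theta),
                 Q_H = Q_H, Q_T = Q_T,
                 head_enabled = head_enabled, tail_enabled = tail_enabled,
                 last_C = last_C),
            class = "worm_state")
}

#' Wrap angles to (-pi, pi]
#'
#' @param theta Angles (rad).
#' @return Wrapped angles.
#' @export
wrap_angle <- function(theta) {
  out <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  out[out <= -pi] <- pi  # map the open end onto +pi
  out
}

#' Sensory input functions of the head and tail detectors
#'
#' The head input is gradient-sensing: proportional to the experienced
#' concentration rate, gated sigmoidally by the absolute concentration. The
#' tail input is threshold-sensing: it peaks at the reference concentration
#' `C0`, falls off log-normally below it, and above `C0` turns negative as
#' `1 - log(C/C0)^2`, floored at -1 so that the steady tail confidence obeys
#' the limiting behaviour Q_T -> 0 (C -> 0), 1 (C -> C0), -1 (C -> Inf).
#'
#' @param C Concentration (mol/m^3), vectorised.
#' @param Cdot Along-trajectory concentration rate (mol/m^3/s).
#' @param params A [model_params()].
#' @return A list with components `f_H` and `f_T`.
#' @export
sensory_inputs <- function(C, Cdot, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(C < 0)) stop("concentration must be nonnegative")
  lg <- ifelse(C > 0, log(C / params$C0), -Inf)
  f_H <- (Cdot / params$Cdot0) * (1 + tanh(lg)) / 2
  f_H[C == 0] <- 0
  f_T <- ifelse(C <= params$C0,
                exp(-lg^2),
                pmax(1 - lg^2, -1))
  f_T[C == 0] <- 0
  list(f_H = f_H, f_T = f_T)
}

#' One Euler step of the confidence dynamics dQ/dt = -k1 Q + k2 f
#'
#' @param Q Current confidence (vectorised).
#' @param f Sensory input.
#' @param k1 Decay rate (1/s).
#' @param k2 Input sensitivity (1/s).
#' @param dt Time step (s); must satisfy `dt * k1 < 1`.
#' @param clamp Clamping interval.
#' @return Updated, clamped confidence.
#' @export
update_confidence <- function(Q, f, k1, k2, dt, clamp = c(-1, 1)) {
  stopifnot(dt > 0, dt * k1 < 1)
  pmin(pmax(Q + dt * (-k1 * Q + k2 * f), clamp[1]), clamp[2])
}

#' Motor mapping from confidences to speed and tumble rate
#'
#' `gamma = gamma0 * exp(-lambda_K * (Q_H - Q_T))` (klinokinesis) and
#' `U = max(0, U0 + U1 * (Q_H - Q_T + eta))` (orthokinesis with speed
#' noise).
#'
#' @param Q_H,Q_T Confidences (vectorised).
#' @param eta Speed-noise draw(s).
#' @param params A [model_params()].
#' @return A list with components `U` (mm/s) and `gamma` (1/s).
#' @export
motor_state <- function(Q_H, Q_T, eta, params) {
  stopifnot(inherits(params, "model_params"))
  dq <- Q_H - Q_T
  list(U = pmax(0, params$U0 + params$U1 * (dq + eta)),
       gamma = params$gamma0 * exp(-params$lambda_K * dq))
}

#' Draw tumble reorientation angles
#'
#' Mixture kernel: with probability `alpha` the increment is uniform on
#' `(-pi, pi]`; otherwise it is drawn from a wrapped Gaussian centred at pi
#' (reversal-biased) with width `sigma`. Returned wrapped to `(-pi, pi]`.
#'
#' @param n Number of draws.
#' @param alpha Mixture weight of the uniform component.
#' @param sigma Wrapped-Gaussian width (rad).
#' @return Signed heading increments (rad).
#' @export
draw_tumble_angle <- function(n, alpha = 0.3, sigma = 0.6) {
  stopifnot(alpha >= 0, alpha <= 1, sigma > 0)
  u <- stats::runif(n) < alpha
  out <- numeric(n)
  out[u] <- stats::runif(sum(u), -pi, pi)
  out[!u] <- pi + sigma * stats::rnorm(sum(!u))
  wrap_angle(out)
}

#' Analytic density of the tumble-angle mixture kernel
#'
#' Normalised density on `(-pi, pi]`; the wrapped Gaussian is summed over
#' enough wraps for machine-precision convergence. Used as the oracle for
#' kernel goodness-of-fit tests.
#'
#' @param theta Angles (rad).
#' @param alpha,sigma Kernel parameters as in [draw_tumble_angle()].
#' @return Density values.
#' @export
tumble_kernel_density <- function(theta, alpha = 0.3, sigma = 0.6) {
  wg <- 0
  for (k in -6:6) wg <- wg + stats::dnorm(theta, mean = pi + 2 * pi * k,
                                          sd = sigma)
  alpha / (2 * pi) + (1 - alpha) * wg
}

# reflect positions (and headings) at the circular wall
.reflect_wall <- function(x, y, theta, radius) {
  r2 <- x^2 + y^2
  out <- r2 > radius^2
  if (any(out)) {
    r <- sqrt(r2[out])
    nx <- x[out] / r; ny <- y[out] / r
    excess <- r - radius
    x[out] <- x[out] - 2 * excess * nx
    y[out] <- y[out] - 2 * excess * ny
    vx <- cos(theta[out]); vy <- sin(theta[out])
    dot <- vx * nx + vy * ny
    theta[out] <- atan2(vy - 2 * dot * ny, vx - 2 * dot * nx)
  }
  list(x = x, y = y, theta = theta)
}

#' Advance a single worm by one time step
#'
#' Reference (scalar) implementation of the update rule: sample the field,
#' update confidences, map to motor state, apply rotational noise, possibly
#' tumble, apply the taxis override (heading set exactly toward the source
#' when the head detector is enabled, the concentration exceeds the taxis
#' threshold and the experienced concentration rate is negative), advance
#' the position, and reflect at the plate wall. [run_cohort()] applies the
#' same rule vectorised over worms.
#'
#' @param state A [worm_state()].
#' @param slice A `field_slice`.
#' @param t Current time (s).
#' @param dt Time step (s).
#' @param params A [model_params()].
#' @param source_xy Source position (mm); defaults to the slice metadata.
#' @return The updated `worm_state`.
#' @export
step_worm <- function(state, slice, t, dt, params,
                      source_xy = slice$source_xy) {
  stopifnot(inherits(state, "worm_state"), dt > 0)
  C <- sample_concentration(slice, state$r[1], state$r[2], t)
  Cdot <- if (is.na(state$last_C)) 0 else (C - state$last_C) / dt
  f <- sensory_inputs(C, Cdot, params)
  Q_H <- if (state$head_enabled)
    update_confidence(state$Q_H, f$f_H, params$k1, params$k2_H, dt,
                      params$q_clamp) else 0
  Q_T <- if (state$tail_enabled)
    update_confidence(state$Q_T, f$f_T, params$k1, params$k2_T, dt,
                      params$q_clamp) else 0
  eta <- if (params$eta_mode == "draw") params$eta_sd * stats::rnorm(1)
         else params$eta_sd
  qn <- if (params$q_noise_sd > 0) params$q_noise_sd * stats::rnorm(2)
        else c(0, 0)
  m <- motor_state(Q_H + qn[1], Q_T + qn[2], eta, params)
  theta <- state$theta + sqrt(2 * params$D_R * dt) * stats::rnorm(1)
  tumbled <- stats::runif(1) < 1 - exp(-m$gamma * dt)
  armed <- state$head_enabled && C > params$taxis_threshold && Cdot < 0
  do_taxis <- if (params$taxis_mode == "tumble-gated") tumbled && armed
              else armed
  if (tumbled && !do_taxis && !armed)
    theta <- theta + draw_tumble_angle(1, params$alpha, params$sigma)
  if (do_taxis)
    theta <- atan2(source_xy[2] - state$r[2], source_xy[1] - state$r[1])
  theta <- wrap_angle(theta)
  x <- state$r[1] + m$U * dt * cos(theta)
  y <- state$r[2] + m$U * dt * sin(theta)
  rf <- .reflect_wall(x, y, theta, slice$radius)
  worm_state(r = c(rf$x, rf$y), theta = rf$theta, Q_H = Q_H, Q_T = Q_T,
             head_enabled = state$head_enabled,
             tail_enabled = state$tail_enabled, last_C = C)
}

#' Simulate a cohort of navigating worms
#'
#' Vectorised simulation of `n_worms` independent agents under one of four
#' detector conditions: `"both"`, `"head_only"`, `"tail_only"`, `"none"`.
#' A disabled head detector freezes `Q_H` at zero and suppresses taxis
#' turns; a disabled tail detector freezes `Q_T` at zero. Worms start
#' uniformly in a disc with uniform random headings, and are frozen in place
#' once within `params$capture_radius` of the source (endpoint-assay
#' semantics).
#'
#' @param n_worms Number of worms.
#' @param condition Detector condition (see above).
#' @param slice A `field_slice` (gridded or analytic).
#' @param duration Simulated time (s).
#' @param dt Time step (s).
#' @param init List with `center` (mm, length-2) and `radius` (mm) of the
#'   start disc.
#' @param params A [model_params()].
#' @param seed RNG seed; identical seed and configuration reproduce the
#'   cohort bit-for-bit.
#' @param source_xy Source position (mm); defaults to the slice metadata.
#' @param record `"summary"` keeps per-worm accumulators only;
#'   `"thinned"` additionally stores positions, headings, speeds and
#'   confidences every `record_dt` seconds.
#' @param record_dt Recording interval (s) for `record = "thinned"`.
#' @return An object of class `cohort_result` with per-worm capture times,
#'   time-averaged x positions (`mean_x`, averaged over the pre-capture
#'   search phase; `mean_x_all` over the whole run including the frozen
#'   post-capture phase), maximum source distances, event counts and
#'   (optionally) thinned trajectories.
#' @export
run_cohort <- function(n_worms, condition = c("both", "head_only",
                                              "tail_only", "none"),
                       slice, duration, dt = 0.1,
                       init = list(center = c(0, 0), radius = 5),
                       params = model_params(), seed = 1,
                       source_xy = slice$source_xy,
                       record = c("thinned", "summary"),
                       record_dt = 10) {
  condition <- match.arg(condition)
  record <- match.arg(record)
  stopifnot(n_worms >= 1, duration > 0, dt > 0,
            inherits(params, "model_params"))
  if (sqrt(sum(init$center^2)) + init$radius > slice$radius)
    stop("start region extends outside the plate")
  head_on <- condition %in% c("both", "head_only")
  tail_on <- condition %in% c("both", "tail_only")
  sense <- head_on || tail_on

  set.seed(seed)
  n <- n_worms
  a <- stats::runif(n, 0, 2 * pi)
  rr <- init$radius * sqrt(stats::runif(n))
  x <- init$center[1] + rr * cos(a)
  y <- init$center[2] + rr * sin(a)
  theta <- stats::runif(n, -pi, pi)
  Q_H <- numeric(n); Q_T <- numeric(n)
  lastC <- rep(NA_real_, n)
  found <- logical(n)
  capture_time <- rep(NA_real_, n)
  sum_x <- numeric(n)
  sum_x_active <- numeric(n)
  n_active <- integer(n)
  d_max <- sqrt((x - source_xy[1])^2 + (y - source_xy[2])^2)
  n_tumbles <- integer(n); n_taxis <- integer(n)

  nsteps <- ceiling(duration / dt)
  do_rec <- record == "thinned"
  if (do_rec) {
    every <- max(1L, round(record_dt / dt))
    nrec <- floor(nsteps / every) + 1L
    rec_t <- numeric(nrec)
    rec_x <- matrix(NA_real_, nrec, n); rec_y <- rec_x
    rec_th <- rec_x; rec_U <- rec_x; rec_QH <- rec_x; rec_QT <- rec_x
    rec_x[1, ] <- x; rec_y[1, ] <- y; rec_th[1, ] <- theta
    rec_U[1, ] <- NA; rec_QH[1, ] <- Q_H; rec_QT[1, ] <- Q_T
    ri <- 1L
  }

  # initial captures (start disc normally excludes the capture zone)
  init_d <- sqrt((x - source_xy[1])^2 + (y - source_xy[2])^2)
  hit0 <- init_d <= params$capture_radius
  found[hit0] <- TRUE; capture_time[hit0] <- 0

  for (s in seq_len(nsteps)) {
    t_now <- (s - 1) * dt
    act <- !found
    if (sense) {
      C <- sample_concentration(slice, x, y, pmin(t_now, slice$times[length(slice$times)]))
      Cdot <- ifelse(is.na(lastC), 0, (C - lastC) / dt)
      f <- sensory_inputs(C, Cdot, params)
      if (head_on)
        Q_H[act] <- update_confidence(Q_H[act], f$f_H[act], params$k1,
                                      params$k2_H, dt, params$q_clamp)
      if (tail_on)
        Q_T[act] <- update_confidence(Q_T[act], f$f_T[act], params$k1,
                                      params$k2_T, dt, params$q_clamp)
      lastC <- C
    } else {
      C <- NULL; Cdot <- NULL
    }
    eta <- if (params$eta_mode == "draw") params$eta_sd * stats::rnorm(n)
           else rep(params$eta_sd, n)
    if (params$q_noise_sd > 0) {
      m <- motor_state(Q_H + params$q_noise_sd * stats::rnorm(n),
                       Q_T + params$q_noise_sd * stats::rnorm(n),
                       eta, params)
    } else m <- motor_state(Q_H, Q_T, eta, params)
    theta <- theta + sqrt(2 * params$D_R * dt) * stats::rnorm(n)
    tum <- stats::runif(n) < 1 - exp(-m$gamma * dt)
    tum <- tum & act
    armed <- if (head_on) act & C > params$taxis_threshold & Cdot < 0
             else rep(FALSE, n)
    if (params$taxis_mode == "tumble-gated") {
      tax <- tum & armed
      tum <- tum & !armed
    } else {
      tax <- armed
      tum <- tum & !armed
    }
    if (any(tum)) {
      theta[tum] <- theta[tum] +
        draw_tumble_angle(sum(tum), params$alpha, params$sigma)
      n_tumbles[tum] <- n_tumbles[tum] + 1L
    }
    if (any(tax)) {
      theta[tax] <- atan2(source_xy[2] - y[tax], source_xy[1] - x[tax])
      n_taxis[tax] <- n_taxis[tax] + 1L
    }
    theta <- wrap_angle(theta)
    step_len <- ifelse(act, m$U * dt, 0)
    x <- x + step_len * cos(theta)
    y <- y + step_len * sin(theta)
    rf <- .reflect_wall(x, y, theta, slice$radius)
    x <- rf$x; y <- rf$y; theta <- rf$theta

    d <- sqrt((x - source_xy[1])^2 + (y - source_xy[2])^2)
    hit <- act & d <= params$capture_radius
    if (any(hit)) { found[hit] <- TRUE; capture_time[hit] <- s * dt }
    d_max <- pmax(d_max, d)
    sum_x <- sum_x + x
    sum_x_active[act] <- sum_x_active[act] + x[act]
    n_active[act] <- n_active[act] + 1L
    if (do_rec && s %% every == 0L) {
      ri <- ri + 1L
      rec_t[ri] <- s * dt
      rec_x[ri, ] <- x; rec_y[ri, ] <- y; rec_th[ri, ] <- theta
      rec_U[ri, ] <- m$U; rec_QH[ri, ] <- Q_H; rec_QT[ri, ] <- Q_T
    }
  }

  out <- list(condition = condition, seed = seed, n_worms = n,
              duration = duration, dt = dt,
              source_xy = source_xy, capture_radius = params$capture_radius,
              capture_time = capture_time,
              mean_x = ifelse(n_active > 0, sum_x_active / n_active, x),
              mean_x_all = sum_x / nsteps,
              d_max = d_max,
              n_tumbles = n_tumbles, n_taxis = n_taxis,
              params = params)
  if (do_rec)
    out$trajectories <- list(times = rec_t[seq_len(ri)],
                             x = rec_x[seq_len(ri), , drop = FALSE],
                             y = rec_y[seq_len(ri), , drop = FALSE],
                             theta = rec_th[seq_len(ri), , drop = FALSE],
                             U = rec_U[seq_len(ri), , drop = FALSE],
                             Q_H = rec_QH[seq_len(ri), , drop = FALSE],
                             Q_T = rec_QT[seq_len(ri), , drop = FALSE])
  class(out) <- "cohort_result"
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort_result: %d worms, condition '%s', %.0f s (dt %.2g)\n",
              x$n_worms, x$condition, x$duration, x$dt))
  cat(sprintf("  success: %.1f%%  <x>: %.2f mm  mean d_max: %.1f mm\n",
              100 * mean(!is.na(x$capture_time)), mean(x$mean_x),
              mean(x$d_max)))
  invisible(x)
}
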