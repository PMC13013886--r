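# Trajectory-level analytics: speed series, stimulation-locked power
# spectra, 2-s behavioural motif classification, chemotaxis indices, and
# cohort summaries.

#' Construct or derive a speed series
#'
#' When given times and values, packages them with the sampling rate; when
#' given a trajectory data frame (`times`, `x`, `y`), computes the centred
#' finite-difference speed magnitude, optionally boxcar-smoothed, resampled
#' to a uniform rate if necessary.
#'
#' @param traj Either a data frame with columns `times`, `x`, `y`, or `NULL`
#'   when `times`/`values` are supplied directly.
#' @param smoothing_window Moving-average window (s); 0 disables smoothing.
#' @param times,values Direct specification of a uniformly sampled series.
#' @param stimulation_epochs Optional data frame of `on`/`off` times.
#' @return An object of class `speed_series`.
#' @export
speed_series <- function(traj = NULL, smoothing_window = 0,
                         times = NULL, values = NULL,
                         stimulation_epochs = NULL) {
  if (is.null(traj)) {
    stopifnot(!is.null(times), !is.null(values),
              length(times) == length(values))
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-8 * dt[1])
      stop("values series must be uniformly sampled")
    return(structure(list(times = times, values = values,
                          rate = 1 / dt[1],
                          stimulation_epochs = stimulation_epochs),
                     class = "speed_series"))
  }
  stopifnot(nrow(traj) >= 2)
  t <- traj$times
  n <- length(t)
  v <- numeric(n)
  v[1] <- sqrt((traj$x[2] - traj$x[1])^2 + (traj$y[2] - traj$y[1])^2) /
    (t[2] - t[1])
  v[n] <- sqrt((traj$x[n] - traj$x[n - 1])^2 +
                 (traj$y[n] - traj$y[n - 1])^2) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    v[i] <- sqrt((traj$x[i + 1] - traj$x[i - 1])^2 +
                   (traj$y[i + 1] - traj$y[i - 1])^2) / (t[i + 1] - t[i - 1])
  }
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1]) {
    tu <- seq(t[1], t[n], by = stats::median(dt))
    v <- stats::approx(t, v, xout = tu)$y
    t <- tu
  }
  if (smoothing_window > 0) {
    k <- max(1L, round(smoothing_window / (t[2] - t[1])))
    if (k %% 2 == 0) k <- k + 1L
    pad <- (k - 1L) / 2L
    vp <- c(rev(v[seq_len(pad) + 1L]), v,
            v[length(v) - seq_len(pad)])
    v <- as.numeric(stats::filter(vp, rep(1 / k, k), sides = 2))
    v <- v[(pad + 1L):(pad + length(t))]
  }
  structure(list(times = t, values = v, rate = 1 / (t[2] - t[1]),
                 stimulation_epochs = stimulation_epochs),
            class = "speed_series")
}

#' One-sided power spectrum with dominant-peak summary
#'
#' Single-taper periodogram (no taper, linear detrend) of a uniformly
#' sampled series. The dominant peak is the argmax over nonzero
#' frequencies; `peak_strength` quantifies the amplitude and sharpness of
#' the peak as the ratio of the peak power to the median power in a local
#' background band around it (excluding the peak and its immediate
#' neighbours), so a value near 1 means no stimulation-locked response.
#'
#' @param series A `speed_series`.
#' @param detrend Remove a linear trend first?
#' @param background_halfwidth Half-width (bins) of the local background
#'   band used for `peak_strength`.
#' @return A list with `frequencies` (Hz), `power`, `dominant_peak` (Hz)
#'   and `peak_strength`.
#' @export
power_spectrum <- function(series, detrend = TRUE,
                           background_halfwidth = 10) {
  stopifnot(inherits(series, "speed_series"))
  dt <- diff(series$times)
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1])
    stop("series must be uniformly sampled; resample first")
  n_cycles_warn <- NULL
  sp <- stats::spec.pgram(stats::ts(series$values, deltat = dt[1]),
                          taper = 0, detrend = detrend, plot = FALSE,
                          fast = FALSE)
  freq <- sp$freq
  pow <- sp$spec
  ipk <- which.max(pow)
  lo <- max(1L, ipk - background_halfwidth)
  hi <- min(length(pow), ipk + background_halfwidth)
  bg <- pow[setdiff(lo:hi, (ipk - 1):(ipk + 1))]
  strength <- if (length(bg) > 0 && stats::median(bg) > 0)
    pow[ipk] / stats::median(bg) else NA_real_
  if (!is.null(series$stimulation_epochs) &&
      nrow(series$stimulation_epochs) > 0) {
    period <- stats::median(diff(series$stimulation_epochs$on))
    if (is.finite(period) &&
        diff(range(series$times)) < 5 * period)
      warning("duration spans fewer than 5 stimulation cycles; ",
              "frequency resolution is poor")
  }
  list(frequencies = freq, power = pow,
       dominant_peak = freq[ipk], peak_strength = strength)
}

#' Classify behaviour into motifs over contiguous 2-s windows
#'
#' The signed along-body velocity is split into contiguous windows; within
#' each window the number of sign changes determines the label: none ->
#' `forward`/`backward` by sign; one -> `fwd_bwd` or `bwd_fwd` by the order
#' of the change; more than two -> `high_freq` (six-motif scheme).
#' Exactly two sign changes are resolved by the first transition observed
#' in the window (the documented tie rule). Windows with a sustained
#' self-proximity flag become `self_exploratory` (six-motif scheme, takes
#' precedence). The four-motif scheme coarsens `high_freq` and
#' `self_exploratory` windows onto the four core labels using the initial
#' and final directions. Zero velocities inherit the preceding sign.
#'
#' @param signed_velocity A `speed_series` whose `values` are signed
#'   (positive forward, negative backward).
#' @param window Window length (s).
#' @param scheme `"four"` or `"six"`.
#' @param proximity_channel Optional 0/1 (or logical) vector, same length
#'   as the velocity, marking near-body probing; required for the
#'   `self_exploratory` label.
#' @return An object of class `motif_sequence`: a data frame with columns
#'   `window_start` and `label`.
#' @export
classify_motifs <- function(signed_velocity, window = 2,
                            scheme = c("six", "four"),
                            proximity_channel = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(signed_velocity, "speed_series"))
  v <- signed_velocity$values
  t <- signed_velocity$times
  if (scheme == "six" && is.null(proximity_channel)) {
    warning("no proximity channel: self_exploratory cannot be assigned; ",
            "using the five remaining labels")
  }
  wlen <- max(2L, round(window * signed_velocity$rate))
  nwin <- floor(length(v) / wlen)
  if (nwin < 1) stop("series shorter than one window")
  # zeros inherit the preceding sign (leading zeros the following one)
  s <- sign(v)
  if (all(s == 0)) s[] <- 1
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 0
  for (i in rev(seq_along(s))) if (s[i] == 0) s[i] <- s[i + 1]
  labs <- character(nwin)
  starts <- numeric(nwin)
  for (w in seq_len(nwin)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    starts[w] <- t[idx[1]]
    sw <- s[idx]
    ch <- sum(diff(sw) != 0)
    first <- sw[1]; last <- sw[wlen]
    core <- if (ch == 0) {
      if (first > 0) "forward" else "backward"
    } else if (ch == 1) {
      if (first > 0) "fwd_bwd" else "bwd_fwd"
    } else if (ch == 2) {
      if (first > 0) "fwd_bwd" else "bwd_fwd"   # first-transition tie rule
    } else "high_freq"
    if (scheme == "six") {
      if (!is.null(proximity_channel) &&
          mean(proximity_channel[idx] != 0) > 0.5) {
        labs[w] <- "self_exploratory"
      } else labs[w] <- core
    } else {
      if (core == "high_freq") {
        core <- if (first > 0 && last > 0) "forward"
        else if (first < 0 && last < 0) "backward"
        else if (first > 0) "fwd_bwd" else "bwd_fwd"
      }
      labs[w] <- core
    }
  }
  lev <- if (scheme == "six")
    c("forward", "backward", "fwd_bwd", "bwd_fwd", "high_freq",
      "self_exploratory")
  else c("forward", "backward", "fwd_bwd", "bwd_fwd")
  out <- data.frame(window_start = starts,
                    label = factor(labs, levels = lev))
  attr(out, "scheme") <- scheme
  class(out) <- c("motif_sequence", "data.frame")
  out
}

#' Endpoint assay counts
#'
#' @param E Worms at the test (experimental) spot.
#' @param C Worms at the control spot.
#' @param N Worms at neither spot.
#' @param assay_type `"type1"` (small plates, no control spot) or
#'   `"type2"` (test and control spots).
#' @return An object of class `assay_counts`.
#' @export
assay_counts <- function(E, C = 0, N = 0,
                         assay_type = c("type2", "type1")) {
  assay_type <- match.arg(assay_type)
  stopifnot(E >= 0, C >= 0, N >= 0)
  structure(list(E = E, C = C, N = N, assay_type = assay_type),
            class = "assay_counts")
}

#' Chemotaxis index
#'
#' Type-2 assays: `(E - C) / (E + C + N)`. Type-1 assays (no control spot):
#' the fraction of worms that reached the test spot, `E / (E + C + N)`.
#'
#' @param counts An [assay_counts()].
#' @return The chemotaxis index (dimensionless).
#' @export
chemotaxis_index <- function(counts) {
  stopifnot(inherits(counts, "assay_counts"))
  total <- counts$E + counts$C + counts$N
  if (total == 0) stop("chemotaxis index undefined for zero total count")
  if (counts$assay_type == "type2") (counts$E - counts$C) / total
  else counts$E / total
}

#' Summarise a simulated cohort
#'
#' Computes the success curve (fraction of worms captured by each time), the
#' cohort mean of the per-worm time-averaged position along the source-to-
#' centre axis (`mean_x`; the axis is oriented so that the plate centre lies
#' at +x of the source, hence negative values mean biased toward the
#' source; the average runs over each worm's pre-capture search phase so
#' that worms frozen at the source do not trivially dominate), and the
#' per-worm maximum distance from the source with its histogram, mean and
#' variance.
#'
#' @param result A `cohort_result` from [run_cohort()].
#' @param source_xy Source position; defaults to the one used in the run.
#' @param capture_radius Capture radius; defaults to the one used.
#' @param curve_times Times at which to evaluate the success curve.
#' @return An object of class `cohort_summary`.
#' @export
cohort_summary <- function(result, source_xy = result$source_xy,
                           capture_radius = result$capture_radius,
                           curve_times = NULL) {
  stopifnot(inherits(result, "cohort_result"))
  if (is.null(curve_times))
    curve_times <- seq(0, result$duration, length.out = 61)
  ct <- result$capture_time
  frac <- vapply(curve_times,
                 function(tt) mean(!is.na(ct) & ct <= tt), numeric(1))
  h <- graphics::hist(result$d_max, breaks = "Sturges", plot = FALSE)
  structure(list(success_curve = data.frame(time = curve_times,
                                            fraction = frac),
                 success_final = frac[length(frac)],
                 mean_x = mean(result$mean_x),
                 d_max = result$d_max,
                 d_max_mean = mean(result$d_max),
                 d_max_var = stats::var(result$d_max),
                 d_max_hist = h,
                 condition = result$condition,
                 n_worms = result$n_worms),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort_summary (%s, n = %d): success %.1f%%, <x> = %.2f mm, d_max %.1f +/- %.1f mm\n",
              x$condition, x$n_worms, 100 * x$success_final, x$mean_x,
              x$d_max_mean, sqrt(x$d_max_var)))
  invisible(x)
}
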