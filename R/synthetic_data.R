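# Seeded generators for every synthetic input the analyses consume:
# two-channel calcium traces with fast/slow responder classes, stimulation-
# locked speed traces, linearly composed circuit triplets, endpoint assay
# counts, and analytic toy concentration fields.

#' Responder-class specification for synthetic calcium traces
#'
#' Imaged males split into two response classes: fast responders activate at
#' stimulus onset and sustain a slowly decaying plateau; slow responders
#' activate after a delay with a reduced peak amplitude.
#'
#' @param fast_fraction Probability that a trace is a fast responder.
#' @param slow_delay Activation delay of slow responders (s).
#' @param slow_amplitude_factor Peak amplitude of slow responders relative to
#'   fast ones.
#' @param amplitude Plateau amplitude of the fast class (dR/R0 units).
#' @param rise_time Activation rise time constant (s).
#' @param decay_time Slow plateau decay time constant (s).
#' @param noise_sd Multiplicative (log-normal) channel noise s.d.
#' @return An object of class `responder_spec`.
#' @export
responder_spec <- function(fast_fraction = 0.625, slow_delay = 150,
                           slow_amplitude_factor = 0.6, amplitude = 1,
                           rise_time = 10, decay_time = 600,
                           noise_sd = 0.02) {
  stopifnot(fast_fraction >= 0, fast_fraction <= 1,
            slow_amplitude_factor > 0, slow_amplitude_factor <= 1,
            slow_delay >= 0, amplitude > 0, rise_time > 0, decay_time > 0,
            noise_sd >= 0)
  structure(as.list(environment()), class = "responder_spec")
}

#' Periodic stimulation protocol
#'
#' @param on_duration Light-on interval (s).
#' @param off_duration Light-off interval (s).
#' @param n_cycles Number of on/off cycles.
#' @param pre_baseline Unstimulated lead-in (s).
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(on_duration, off_duration, n_cycles = 8,
                          pre_baseline = 0) {
  stopifnot(on_duration > 0, off_duration > 0, n_cycles >= 1,
            pre_baseline >= 0)
  structure(list(on_duration = on_duration, off_duration = off_duration,
                 n_cycles = n_cycles, pre_baseline = pre_baseline),
            class = "stim_protocol")
}

#' Construct a two-channel calcium trace
#'
#' @param times Sample times (s), strictly increasing.
#' @param gcamp Activity-dependent channel (a.u., positive).
#' @param reference Activity-independent reference channel (a.u., positive).
#' @param stim_onset Stimulus onset time (s).
#' @return An object of class `calcium_trace` (a data frame with attributes).
#' @export
calcium_trace <- function(times, gcamp, reference, stim_onset) {
  stopifnot(length(times) == length(gcamp),
            length(times) == length(reference),
            all(diff(times) > 0), all(gcamp > 0), all(reference > 0))
  out <- data.frame(times = times, gcamp = gcamp, reference = reference)
  attr(out, "stim_onset") <- stim_onset
  class(out) <- c("calcium_trace", "data.frame")
  out
}

# deterministic activity shape shared by both responder classes
.responder_shape <- function(t, onset, spec) {
  u <- pmax(t - onset, 0)
  spec$amplitude * (1 - exp(-u / spec$rise_time)) * exp(-u / spec$decay_time)
}

#' Generate synthetic two-channel calcium traces with responder classes
#'
#' Each trace is assigned fast/slow by a Bernoulli draw on
#' `spec$fast_fraction`. Fast responders activate at the stimulus onset; slow
#' responders share the same kinetic shape delayed by `spec$slow_delay` and
#' scaled by `spec$slow_amplitude_factor`, so at zero noise the slow/fast
#' peak ratio equals the amplitude factor exactly.
#'
#' @param n Number of traces.
#' @param spec A [responder_spec()].
#' @param sampling_rate Samples per second (Hz).
#' @param duration Trace length (s).
#' @param stim_onset Stimulus onset (s).
#' @param seed RNG seed.
#' @return A list with elements `traces` (list of [calcium_trace()]),
#'   `labels` (factor `fast`/`slow`) and `spec`.
#' @export
gen_calcium_traces <- function(n, spec = responder_spec(),
                               sampling_rate = 2, duration = 600,
                               stim_onset = 60, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  times <- seq(0, duration, by = 1 / sampling_rate)
  fast <- stats::runif(n) < spec$fast_fraction
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    onset <- stim_onset + if (fast[i]) 0 else spec$slow_delay
    amp <- if (fast[i]) 1 else spec$slow_amplitude_factor
    act <- amp * .responder_shape(times, onset, spec)
    ref <- exp(spec$noise_sd * stats::rnorm(length(times)))
    gc <- (1 + act) * exp(spec$noise_sd * stats::rnorm(length(times)))
    traces[[i]] <- calcium_trace(times, gc, ref, stim_onset)
  }
  list(traces = traces,
       labels = factor(ifelse(fast, "fast", "slow"),
                       levels = c("fast", "slow")),
       spec = spec)
}

#' Generate a stimulation-locked speed series
#'
#' Baseline crawling speed with an additive elevation during light-on epochs
#' plus Gaussian noise; the stimulation epochs are recorded on the result so
#' spectral analyses can relate peaks to the protocol period.
#'
#' @param protocol A [stim_protocol()].
#' @param response_gain Speed elevation during on-epochs (mm/s).
#' @param noise_sd Additive Gaussian noise s.d. (mm/s).
#' @param sampling_rate Samples per second (Hz).
#' @param baseline_speed Baseline speed (mm/s).
#' @param seed RNG seed.
#' @return A `speed_series` object (see [speed_series()]).
#' @export
gen_periodic_speed <- function(protocol, response_gain = 0.03,
                               noise_sd = 0.01, sampling_rate = 2,
                               baseline_speed = 0.064, seed = 1) {
  stopifnot(inherits(protocol, "stim_protocol"))
  set.seed(seed)
  period <- protocol$on_duration + protocol$off_duration
  duration <- protocol$pre_baseline + protocol$n_cycles * period
  times <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  tt <- times - protocol$pre_baseline
  on <- tt >= 0 & (tt %% period) < protocol$on_duration
  values <- baseline_speed + response_gain * on +
    noise_sd * stats::rnorm(length(times))
  starts <- protocol$pre_baseline + (seq_len(protocol$n_cycles) - 1) * period
  epochs <- data.frame(on = starts, off = starts + protocol$on_duration)
  structure(list(times = times, values = values, rate = sampling_rate,
                 stimulation_epochs = epochs, protocol = protocol),
            class = "speed_series")
}

#' Generate linearly composed circuit activity traces
#'
#' Two upstream activities (named for the head detector AWA and the tail
#' detector PHD) are smoothed, unit-variance random walks; the downstream
#' command-neuron trace (AVA) is their linear combination plus an intercept
#' and Gaussian noise. The generative coefficients are embedded so recovery
#' can be tested.
#'
#' @param coefficients Numeric `(a, b, c)`: AWA weight, PHD weight,
#'   intercept.
#' @param n_samples Number of time samples.
#' @param noise_sd S.d. of the additive noise on the composed trace.
#' @param smooth_window Boxcar length (samples) applied to the random walks.
#' @param seed RNG seed.
#' @return A data frame with columns `AWA`, `PHD`, `AVA` and attribute
#'   `generative` holding the coefficients.
#' @export
gen_circuit_traces <- function(coefficients = c(-0.7, 0.1, -0.2),
                               n_samples = 600, noise_sd = 0.05,
                               smooth_window = 11, seed = 1) {
  stopifnot(n_samples >= 10, length(coefficients) == 3)
  set.seed(seed)
  walk <- function() {
    w <- cumsum(stats::rnorm(n_samples + smooth_window))
    w <- stats::filter(w, rep(1 / smooth_window, smooth_window),
                       sides = 2)
    w <- w[!is.na(w)][seq_len(n_samples)]
    as.numeric(scale(w))
  }
  AWA <- walk(); PHD <- walk()
  AVA <- coefficients[1] * AWA + coefficients[2] * PHD + coefficients[3] +
    noise_sd * stats::rnorm(n_samples)
  out <- data.frame(AWA = AWA, PHD = PHD, AVA = AVA)
  attr(out, "generative") <- list(coefficients = coefficients,
                                  noise_sd = noise_sd, seed = seed)
  out
}

#' Generate endpoint assay counts
#'
#' Each trial distributes `n_worms` among the test spot, the control spot and
#' neither by a multinomial draw.
#'
#' @param n_worms Worms per trial.
#' @param p_test,p_control Per-worm probabilities of ending at each spot
#'   (`p_test + p_control <= 1`).
#' @param n_trials Number of trials.
#' @param assay_type `"type1"` (no control spot scored) or `"type2"`.
#' @param seed RNG seed.
#' @return A list of [assay_counts()] objects, one per trial.
#' @export
gen_endpoint_counts <- function(n_worms = 20, p_test, p_control,
                                n_trials = 10, assay_type = "type2",
                                seed = 1) {
  stopifnot(p_test >= 0, p_control >= 0, p_test + p_control <= 1)
  set.seed(seed)
  draws <- stats::rmultinom(n_trials, n_worms,
                            c(p_test, p_control, 1 - p_test - p_control))
  lapply(seq_len(n_trials), function(i)
    assay_counts(E = draws[1, i], C = draws[2, i], N = draws[3, i],
                 assay_type = assay_type))
}

#' Analytic toy concentration slices
#'
#' Closed-form 2-D fields with exact samplers, used as oracles for the
#' navigation model and the along-body contrast statistic.
#'
#' * `uniform`: `C = level` everywhere.
#' * `linear`: `C = level + gx*x + gy*y` (clamped at zero).
#' * `gaussian_hill`: `C = peak * exp(-((x-cx)^2+(y-cy)^2) / (2*width^2))`.
#'
#' All kinds are steady, so the exact time derivative is zero.
#'
#' @param kind One of `"uniform"`, `"linear"`, `"gaussian_hill"`.
#' @param params Named list of kind parameters (see Details above); missing
#'   entries take defaults `level = 1`, `gx = 0.1`, `gy = 0`, `peak = 1`,
#'   `cx = 0`, `cy = 0`, `width = 10`.
#' @param radius Plate radius (mm) attached for boundary handling.
#' @param source_xy Nominal source location attached for taxis turns.
#' @return A `field_slice` of kind `"analytic"`.
#' @export
gen_toy_field <- function(kind = c("uniform", "linear", "gaussian_hill"),
                          params = list(), radius = 40,
                          source_xy = c(0, 0)) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(level = 1, gx = 0.1, gy = 0, peak = 1,
                              cx = 0, cy = 0, width = 10), params)
  C_fun <- switch(kind,
    uniform = function(x, y, t) rep_len(p$level, length(x)),
    linear = function(x, y, t) pmax(p$level + p$gx * x + p$gy * y, 0),
    gaussian_hill = function(x, y, t)
      p$peak * exp(-((x - p$cx)^2 + (y - p$cy)^2) / (2 * p$width^2)))
  structure(list(kind = "analytic", C_fun = C_fun,
                 dCdt_fun = function(x, y, t) numeric(length(x)),
                 times = c(0, Inf), radius = radius,
                 source_xy = if (kind == "gaussian_hill") c(p$cx, p$cy)
                             else source_xy,
                 c0 = switch(kind, uniform = p$level, linear = p$level,
                             gaussian_hill = p$peak),
                 params = p, toy_kind = kind),
            class = "field_slice")
}
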