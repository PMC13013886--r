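# Calcium-trace analytics: ratiometric dR/R0 with Savitzky-Golay smoothing,
# sign-restricted response integrals, correlation screening, unit-interval
# normalisation, and the linear head/tail -> command-neuron decomposition.

# Savitzky-Golay with mirror padding so the interior filter applies
# everywhere (the plain convolution is undefined near the edges).
.sgolay_mirror <- function(x, p, n) {
  pad <- (n - 1) / 2
  xp <- c(rev(x[seq_len(pad) + 1L]), x, x[length(x) - seq_len(pad)])
  y <- signal::sgolayfilt(xp, p = p, n = n)
  y[(pad + 1L):(pad + length(x))]
}

#' Ratiometric dR/R0 trace from a two-channel recording
#'
#' Both channels are smoothed with a Savitzky-Golay filter (default
#' polynomial order 1, window length 13; mirror padding at the edges), the
#' ratio `R = gcamp / reference` is formed pointwise, the baseline `R0` is
#' the mean of `R` over the quiescent pre-stimulation epoch, and
#' `dRR0 = (R - R0) / R0`.
#'
#' @param trace A [calcium_trace()].
#' @param filter_order Savitzky-Golay polynomial order.
#' @param filter_length Savitzky-Golay window length (odd,
#'   `> filter_order`).
#' @param baseline_epoch Length-2 interval (s) defining the quiescent
#'   baseline; defaults to everything before the stimulus onset.
#' @return An object of class `ratio_trace`: a data frame with columns
#'   `times`, `R`, `dRR0` and attribute `R0`.
#' @export
ratio_trace <- function(trace, filter_order = 1, filter_length = 13,
                        baseline_epoch = NULL) {
  stopifnot(inherits(trace, "calcium_trace"),
            filter_length %% 2 == 1, filter_length > filter_order)
  if (any(trace$reference <= 0)) stop("reference channel must be positive")
  if (is.null(baseline_epoch))
    baseline_epoch <- c(trace$times[1], attr(trace, "stim_onset"))
  g <- .sgolay_mirror(trace$gcamp, filter_order, filter_length)
  r <- .sgolay_mirror(trace$reference, filter_order, filter_length)
  R <- g / r
  in_base <- trace$times >= baseline_epoch[1] &
    trace$times < baseline_epoch[2]
  if (!any(in_base)) stop("baseline epoch contains no samples")
  R0 <- mean(R[in_base])
  if (R0 <= 0) stop("baseline ratio must be positive")
  out <- data.frame(times = trace$times, R = R, dRR0 = (R - R0) / R0)
  attr(out, "R0") <- R0
  class(out) <- c("ratio_trace", "data.frame")
  out
}

#' Sign-restricted area under the curve of a response
#'
#' The baseline is the mean signal over a pre-stimulus window (or a value
#' supplied directly, e.g. the most-dilute-condition baseline in a
#' titration series). The baseline-subtracted signal is integrated by the
#' trapezoidal rule over the post-stimulus window, restricted to
#' sub-baseline intervals (`mode = "suppression"`, nonpositive result) or
#' supra-baseline intervals (`mode = "excitation"`, nonnegative result), so
#' the integral terminates naturally when the response disappears.
#'
#' @param times,values The activity series (e.g. a `ratio_trace`'s `times`
#'   and `dRR0`).
#' @param stim_time Stimulation time (s).
#' @param baseline_window Length (s) of the pre-stimulus baseline window.
#' @param integration_window Length (s) of the post-stimulus integration
#'   window.
#' @param mode `"suppression"` or `"excitation"`.
#' @param baseline Optional baseline value overriding the window mean.
#' @return An object of class `auc_result` with `baseline`, `auc`
#'   (signal x s), `mode` and `window`.
#' @export
auc_response <- function(times, values, stim_time,
                         baseline_window = 180, integration_window = 120,
                         mode = c("suppression", "excitation"),
                         baseline = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(times) == length(values))
  if (is.null(baseline)) {
    if (stim_time - baseline_window < times[1] - 1e-9)
      stop("baseline window extends before the trace")
    sel <- times >= stim_time - baseline_window & times < stim_time
    if (!any(sel)) stop("baseline window contains no samples")
    baseline <- mean(values[sel])
  }
  if (stim_time + integration_window > times[length(times)] + 1e-9)
    stop("integration window extends beyond the trace")
  sel <- times >= stim_time & times <= stim_time + integration_window
  dev <- values[sel] - baseline
  dev <- if (mode == "suppression") pmin(dev, 0) else pmax(dev, 0)
  auc <- pracma::trapz(times[sel], dev)
  structure(list(baseline = baseline, auc = auc, mode = mode,
                 window = c(stim_time, stim_time + integration_window)),
            class = "auc_result")
}

#' Screen candidate activity series by correlation with a reference
#'
#' Pearson correlation of each candidate against the reference; candidates
#' with correlation strictly above the cutoff are selected. Zero-variance
#' candidates are flagged and excluded with a warning. The full table is
#' returned so negatively correlated series can be inspected.
#'
#' @param candidates Named list (or data frame) of equal-length numeric
#'   series.
#' @param reference Numeric reference series.
#' @param cutoff Selection cutoff (strict inequality).
#' @return A list with `selected` (character vector) and `table` (data
#'   frame with `id`, `r`, `selected`, `flagged`).
#' @export
correlation_screen <- function(candidates, reference, cutoff = 0.55) {
  candidates <- as.list(candidates)
  stopifnot(length(candidates) >= 1,
            all(vapply(candidates, length, 1L) == length(reference)))
  ids <- names(candidates)
  if (is.null(ids)) ids <- paste0("series", seq_along(candidates))
  r <- numeric(length(candidates))
  flagged <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    if (stats::sd(candidates[[i]]) == 0) {
      flagged[i] <- TRUE
      r[i] <- NA_real_
    } else r[i] <- stats::cor(candidates[[i]], reference)
  }
  if (any(flagged))
    warning("zero-variance candidate(s) excluded: ",
            paste(ids[flagged], collapse = ", "))
  sel <- !flagged & !is.na(r) & r > cutoff
  list(selected = ids[sel],
       table = data.frame(id = ids, r = r, selected = sel,
                          flagged = flagged))
}

#' Normalise a series to the unit interval
#'
#' `(x - min) / (max - min)`. A constant series cannot be scaled; it is
#' returned as all zeros with attribute `degenerate = TRUE`.
#'
#' @param x Numeric series.
#' @return Normalised series, with a `degenerate` attribute.
#' @export
normalize_unit_interval <- function(x) {
  stopifnot(length(x) >= 1)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out <- numeric(length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

#' Fit a target activity as a linear combination of regressor activities
#'
#' Ordinary least squares with intercept, as used to decompose the reversal
#' command neuron's activity into weighted head- and tail-detector
#' contributions over the window where both are active.
#'
#' @param target Numeric response series.
#' @param regressors Named data frame (or list) of regressor series.
#' @return An object of class `circuit_fit` with `coefficients` (named,
#'   regressors first), `intercept`, `residual_rms` and the underlying
#'   `lm` fit.
#' @export
fit_linear_combination <- function(target, regressors) {
  regressors <- as.data.frame(regressors)
  stopifnot(nrow(regressors) == length(target),
            length(target) >= ncol(regressors) + 4)
  X <- cbind(1, as.matrix(regressors))
  if (qr(X)$rank < ncol(X))
    stop("collinear regressors: design matrix is rank deficient")
  dat <- cbind(data.frame(.target = target), regressors)
  fit <- stats::lm(.target ~ ., data = dat)
  cf <- stats::coef(fit)
  structure(list(coefficients = cf[-1], intercept = unname(cf[1]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 fit = fit),
            class = "circuit_fit")
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat("circuit_fit:",
      paste(sprintf("%s = %.3f", names(x$coefficients), x$coefficients),
            collapse = ", "),
      sprintf ("; intercept = %.3f (residual rms %.3g)\n",
               x$intercept, x$residual_rms))
  invisible(x)
}

#' Compare dual-stimulation response with the sum of single-site responses
#'
#' Reports the sum of the head-only and tail-only response integrals next
#' to the dual-stimulation integral, their difference and ratio; an
#' additive circuit gives a difference near zero.
#'
#' @param auc_head,auc_tail,auc_dual [auc_response()] results with matching
#'   modes and integration windows.
#' @return A list with `sum`, `dual`, `difference` (`dual - sum`) and
#'   `ratio` (`dual / sum`, `NA` when the sum is zero).
#' @export
dual_vs_sum <- function(auc_head, auc_tail, auc_dual) {
  for (a in list(auc_head, auc_tail, auc_dual))
    stopifnot(inherits(a, "auc_result"))
  if (auc_head$mode != auc_tail$mode || auc_head$mode != auc_dual$mode)
    stop("AUC modes do not match")
  w <- rbind(auc_head$window, auc_tail$window, auc_dual$window)
  if (max(abs(diff(w[, 2] - w[, 1]))) > 1e-9)
    stop("integration windows do not match")
  s <- auc_head$auc + auc_tail$auc
  list(sum = s, dual = auc_dual$auc, difference = auc_dual$auc - s,
       ratio = if (s != 0) auc_dual$auc / s else NA_real_)
}
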