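# Optimal turn-angle analysis: how should a crawler that estimates the
# local concentration gradient from two successive directional-derivative
# samples choose the turn angle between the two sampling directions so the
# estimated gradient direction is least uncertain?
#
# The two derivative samples are built from three concentration readings
# along the path (start, turn point, end); the turn-point reading is shared
# by both derivatives, so with iid reading noise the derivative errors are
# anticorrelated with covariance proportional to [[2, -1], [-1, 2]]. A
# plain iid-derivative noise model is also available.

.deriv_noise_cov <- function(noise_model) {
  switch(noise_model,
         "path-readings" = matrix(c(2, -1, -1, 2), 2),
         "iid-derivative" = diag(2),
         stop("unknown noise model"))
}

#' Least-squares gradient estimate from directional-derivative samples
#'
#' Fits `d_i = g . u(theta_i) + eps_i` by ordinary least squares and
#' propagates the sample-noise covariance to the estimate.
#'
#' @param directions Sampling directions (rad).
#' @param derivatives Measured directional derivatives.
#' @param noise_sd Per-sample noise s.d. (scales the covariance).
#' @param noise_cov Optional sample-noise correlation matrix (defaults to
#'   the identity, iid samples).
#' @return A list with `gradient` (length-2), `direction` (rad),
#'   `covariance` (2x2 covariance of the gradient estimate) and
#'   `direction_var` (delta-method variance of the direction estimate,
#'   rad^2).
#' @export
estimate_gradient_lsq <- function(directions, derivatives, noise_sd = 0,
                                  noise_cov = NULL) {
  stopifnot(length(directions) >= 2,
            length(directions) == length(derivatives))
  X <- cbind(cos(directions), sin(directions))
  if (abs(det(crossprod(X))) < 1e-12)
    stop("sampling directions are collinear; gradient is unidentifiable")
  if (is.null(noise_cov)) noise_cov <- diag(length(directions))
  B <- solve(crossprod(X)) %*% t(X)
  g <- drop(B %*% derivatives)
  Sg <- noise_sd^2 * B %*% noise_cov %*% t(B)
  phi <- atan2(g[2], g[1])
  m2 <- sum(g^2)
  e_perp <- c(-sin(phi), cos(phi))
  dir_var <- if (m2 > 0) drop(t(e_perp) %*% Sg %*% e_perp) / m2 else Inf
  list(gradient = g, direction = phi, covariance = Sg,
       direction_var = dir_var)
}

#' Two-sample turn design
#'
#' @param theta1 First sampling direction (rad), measured in the same frame
#'   as `grad_direction`.
#' @param delta Turn angle to the second sampling direction (rad).
#' @param noise_sd Reading noise s.d. in units of the per-leg concentration
#'   increment `|g| L` (so 0.3 means the noise is 30% of the signal a leg
#'   accumulates when aligned with the gradient).
#' @param grad_direction True gradient direction (rad).
#' @param grad_magnitude True gradient magnitude (signal units; enters only
#'   through the noise scaling).
#' @param noise_model `"path-readings"` (three readings, shared turn-point
#'   reading, anticorrelated derivative errors; the default) or
#'   `"iid-derivative"`.
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(theta1, delta, noise_sd = 0.3,
                            grad_direction = 0, grad_magnitude = 1,
                            noise_model = c("path-readings",
                                            "iid-derivative")) {
  noise_model <- match.arg(noise_model)
  stopifnot(noise_sd > 0, grad_magnitude > 0)
  structure(list(theta1 = theta1, delta = delta, noise_sd = noise_sd,
                 grad_direction = grad_direction,
                 grad_magnitude = grad_magnitude,
                 noise_model = noise_model),
            class = "sampling_design")
}

# Gauss-Hermite nodes/weights for a standard normal
.gh_normal <- function(n) {
  g <- pracma::gaussHermite(n)
  list(z = sqrt(2) * g$x, w = g$w / sqrt(pi))
}

#' Direction uncertainty of a two-sample turn design
#'
#' Dispersion (rad) of the least-squares gradient-direction estimate.
#' `method = "analytic"` uses the delta-method variance (small-noise
#' limit); `method = "quadrature"` evaluates the root mean squared angular
#' error of the nonlinear estimator exactly by two-dimensional
#' Gauss-Hermite quadrature over the derivative noise, which is the
#' appropriate measure at finite noise. A zero turn angle makes the two
#' directions collinear and the uncertainty infinite.
#'
#' @param design A [sampling_design()].
#' @param method `"quadrature"` (default) or `"analytic"`.
#' @param n_nodes Gauss-Hermite nodes per dimension.
#' @return Direction dispersion (rad); `Inf` for a collinear design.
#' @export
direction_uncertainty <- function(design,
                                  method = c("quadrature", "analytic"),
                                  n_nodes = 32) {
  method <- match.arg(method)
  stopifnot(inherits(design, "sampling_design"))
  d <- design$delta
  if (abs(sin(d)) < 1e-9) return(Inf)
  psi1 <- design$theta1 - design$grad_direction
  X <- rbind(c(cos(psi1), sin(psi1)),
             c(cos(psi1 + d), sin(psi1 + d)))
  B <- solve(X)
  S <- design$noise_sd^2 * .deriv_noise_cov(design$noise_model)
  if (method == "analytic") {
    Sg <- B %*% S %*% t(B)
    return(sqrt(Sg[2, 2]))  # gradient along +x in the rotated frame
  }
  gh <- .gh_normal(n_nodes)
  L <- t(chol(S))
  Z1 <- rep(gh$z, times = n_nodes)
  Z2 <- rep(gh$z, each = n_nodes)
  W <- rep(gh$w, times = n_nodes) * rep(gh$w, each = n_nodes)
  e1 <- L[1, 1] * Z1
  e2 <- L[2, 1] * Z1 + L[2, 2] * Z2
  d0 <- X %*% c(1, 0)
  g1 <- B[1, 1] * (d0[1] + e1) + B[1, 2] * (d0[2] + e2)
  g2 <- B[2, 1] * (d0[1] + e1) + B[2, 2] * (d0[2] + e2)
  sqrt(sum(W * atan2(g2, g1)^2))
}

# worst-case-over-orientation direction variance of a turn angle
# (largest eigenvalue of the gradient-estimate covariance; closed form)
.worstcase_dirvar <- function(delta, noise_sd, noise_model) {
  if (abs(sin(delta)) < 1e-9) return(Inf)
  X <- rbind(c(1, 0), c(cos(delta), sin(delta)))
  B <- solve(X)
  S <- noise_sd^2 * .deriv_noise_cov(noise_model)
  max(eigen(B %*% S %*% t(B), symmetric = TRUE,
            only.values = TRUE)$values)
}

#' Optimal turn angle for the second directional sample
#'
#' Finds the turn angle minimising the direction uncertainty of the
#' two-sample least-squares gradient estimate.
#'
#' For a fixed initial orientation (numeric `initial_orientation`, rad,
#' relative to the gradient) the finite-noise dispersion
#' ([direction_uncertainty()], quadrature) is swept over the turn-angle
#' grid; the optimum is reported with the sign convention that the turn is
#' directed away from the gradient when the initial orientation is within
#' 90 degrees of it, and toward the gradient otherwise.
#'
#' For `initial_orientation = "uniform"` the worm cannot know its
#' orientation relative to the gradient, so the default rule minimises the
#' worst case over orientations of the direction variance
#' (`orientation_rule = "worst-case"`). Under the path-readings noise model
#' this criterion has a sharp optimum at the turn angle that makes the
#' three sampled points an equilateral triangle -- 120 degrees -- where the
#' gradient information becomes isotropic. `orientation_rule = "mean"`
#' minimises the orientation-averaged dispersion instead (optimum near 105
#' degrees; see the methods vignette).
#'
#' Ties on the grid resolve to the first (smallest) angle.
#'
#' @param initial_orientation `"uniform"` or a fixed orientation (rad,
#'   relative to the gradient direction).
#' @param noise_sd Reading noise s.d. (units of `|g| L`).
#' @param grid_deg Turn-angle grid resolution (degrees, <= 1).
#' @param noise_model See [sampling_design()].
#' @param orientation_rule Aggregation over unknown orientation,
#'   `"worst-case"` or `"mean"` (uniform case only).
#' @param n_nodes Gauss-Hermite nodes for the quadrature dispersion.
#' @return A list with `delta_star_deg` (signed for fixed orientations,
#'   magnitude for `"uniform"`), `delta_star_rad`, and `curve` (data frame
#'   of `delta_deg` and `uncertainty`).
#' @export
optimal_second_angle <- function(initial_orientation = "uniform",
                                 noise_sd = 0.3, grid_deg = 0.5,
                                 noise_model = c("path-readings",
                                                 "iid-derivative"),
                                 orientation_rule = c("worst-case", "mean"),
                                 n_nodes = 32) {
  noise_model <- match.arg(noise_model)
  orientation_rule <- match.arg(orientation_rule)
  stopifnot(grid_deg <= 1, grid_deg > 0)
  deltas_deg <- seq(grid_deg, 180 - grid_deg, by = grid_deg)
  deltas <- deltas_deg * pi / 180

  if (identical(initial_orientation, "uniform")) {
    if (orientation_rule == "worst-case") {
      unc <- vapply(deltas, .worstcase_dirvar, numeric(1),
                    noise_sd = noise_sd, noise_model = noise_model)
      unc <- sqrt(unc)
    } else {
      th1s <- seq(0, 2 * pi, length.out = 49)[-49]
      unc <- vapply(deltas, function(d) {
        mean(vapply(th1s, function(t1)
          direction_uncertainty(
            sampling_design(t1, d, noise_sd, noise_model = noise_model),
            method = "quadrature", n_nodes = n_nodes)^2, numeric(1)))
      }, numeric(1))
      unc <- sqrt(unc)
    }
    i <- which.min(unc)
    return(list(delta_star_deg = deltas_deg[i],
                delta_star_rad = deltas[i],
                curve = data.frame(delta_deg = deltas_deg,
                                   uncertainty = unc),
                orientation = "uniform", rule = orientation_rule))
  }

  th1 <- as.numeric(initial_orientation)
  unc <- vapply(deltas, function(d)
    direction_uncertainty(
      sampling_design(th1, d, noise_sd, noise_model = noise_model),
      method = "quadrature", n_nodes = n_nodes), numeric(1))
  i <- which.min(unc)
  mag <- deltas_deg[i]
  # away from the gradient when qualitatively aligned, toward it otherwise
  rel <- wrap_angle(th1)
  sgn <- if (abs(rel) < pi / 2) {
    if (rel >= 0) 1 else -1           # keep rotating away
  } else {
    if (rel >= 0) -1 else 1           # rotate back toward the gradient
  }
  list(delta_star_deg = sgn * mag, delta_star_rad = sgn * mag * pi / 180,
       curve = data.frame(delta_deg = deltas_deg, uncertainty = unc),
       orientation = th1)
}
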