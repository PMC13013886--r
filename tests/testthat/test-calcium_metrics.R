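# Ratiometric dR/R0, sign-restricted AUC, correlation screening,
# normalisation and the linear circuit decomposition.

make_trace <- function(g, ref, dt = 0.5, stim = NULL) {
  times <- (seq_along(g) - 1) * dt
  calcium_trace(times, g, ref,
                stim_onset = if (is.null(stim)) times[length(times)] / 2
                             else stim)
}

test_that("constant and step traces give the expected dR/R0", {
  tr <- make_trace(rep(2, 100), rep(1, 100), stim = 25)
  rt <- ratio_trace(tr)
  expect_equal(rt$R, rep(2, 100))
  expect_equal(rt$dRR0, rep(0, 100))

  # step at t = 30; baseline epoch ends before the filter smear reaches it
  g <- c(rep(2, 60), rep(4, 60))
  tr <- make_trace(g, rep(1, 120), stim = 25)
  rt <- ratio_trace(tr)
  # away from the filter-width neighbourhood of the step, dRR0 is 0 then 1
  expect_equal(rt$dRR0[10:50], rep(0, 41))
  expect_equal(rt$dRR0[70:110], rep(1, 41))
})

test_that("order-1 Savitzky-Golay preserves affine signals", {
  n <- 80
  times <- seq(0, 39.5, by = 0.5)
  g <- 3 + 0.05 * times          # exactly linear in both channels
  ref <- rep(2, n)
  rt <- ratio_trace(make_trace(g, ref, stim = 10))
  # interior points: machine precision; mirror padding also preserves the
  # constant reference, so only the gcamp edges are approximate
  expect_equal(rt$R[7:(n - 6)], (g / 2)[7:(n - 6)], tolerance = 1e-12)
})

test_that("dR/R0 is invariant under common rescaling of both channels", {
  set.seed(4)
  g <- 2 + abs(cumsum(rnorm(200, sd = 0.05)))
  ref <- 1 + abs(cumsum(rnorm(200, sd = 0.02)))
  a <- ratio_trace(make_trace(g, ref, stim = 40))
  b <- ratio_trace(make_trace(5.7 * g, 5.7 * ref, stim = 40))
  expect_equal(a$dRR0, b$dRR0, tolerance = 1e-12)
})

test_that("sign-restricted AUC handles steps, zero deviation and scaling", {
  dt <- 0.01
  times <- seq(0, 400, by = dt)
  base <- rep(1, length(times))
  expect_equal(auc_response(times, base, 200, mode = "suppression")$auc, 0)
  expect_equal(auc_response(times, base, 200, mode = "excitation")$auc, 0)

  v <- base
  v[times >= 210 & times < 270] <- 0.5    # -0.5 step lasting 60 s
  sup <- auc_response(times, v, 200, mode = "suppression")
  expect_equal(sup$auc, -30, tolerance = 1e-3)
  expect_lte(sup$auc, 0)
  exc <- auc_response(times, v, 200, mode = "excitation")
  expect_equal(exc$auc, 0)

  # linearity in the deviation within a mode
  v2 <- base + 3 * (v - base)
  sup3 <- auc_response(times, v2, 200, mode = "suppression")
  expect_equal(sup3$auc, 3 * sup$auc, tolerance = 1e-9)

  # explicit baseline override (titration-series usage)
  sup_b <- auc_response(times, v, 200, mode = "suppression", baseline = 1)
  expect_equal(sup_b$auc, sup$auc, tolerance = 1e-9)
})

test_that("correlation screen selects by strict cutoff and flags degenerate input", {
  set.seed(11)
  n <- 500
  z1 <- as.numeric(scale(rnorm(n)))
  z2 <- rnorm(n)
  z2 <- as.numeric(scale(stats::residuals(lm(z2 ~ z1))))
  mix <- function(r) r * z1 + sqrt(1 - r^2) * z2
  cands <- list(self = z1, neg = -z1, r06 = mix(0.6), r05 = mix(0.5),
                flat = rep(1, n))
  expect_warning(sc <- correlation_screen(cands, z1, cutoff = 0.55),
                 "zero-variance")
  expect_true("self" %in% sc$selected)
  expect_true("r06" %in% sc$selected)
  expect_false("r05" %in% sc$selected)
  expect_false("neg" %in% sc$selected)
  expect_equal(sc$table$r[sc$table$id == "self"], 1, tolerance = 1e-12)
  expect_equal(sc$table$r[sc$table$id == "neg"], -1, tolerance = 1e-12)
  expect_equal(sc$table$r[sc$table$id == "r06"], 0.6, tolerance = 1e-9)
  expect_true(sc$table$flagged[sc$table$id == "flat"])
})

test_that("unit-interval normalisation maps extremes and ignores affine maps", {
  set.seed(5)
  x <- rnorm(50)
  nx <- normalize_unit_interval(x)
  expect_equal(min(nx), 0)
  expect_equal(max(nx), 1)
  ny <- normalize_unit_interval(2.5 * x + 7)
  expect_equal(as.numeric(nx), as.numeric(ny), tolerance = 1e-12)
  nz <- normalize_unit_interval(rep(3, 10))
  expect_equal(as.numeric(nz), rep(0, 10))
  expect_true(attr(nz, "degenerate"))
})

test_that("linear circuit fit recovers generative coefficients and satisfies normal equations", {
  set.seed(6)
  reg <- data.frame(AWA = as.numeric(scale(cumsum(rnorm(300)))),
                    PHD = as.numeric(scale(cumsum(rnorm(300)))))
  target <- -0.7 * reg$AWA + 0.1 * reg$PHD - 0.2
  fit <- fit_linear_combination(target, reg)
  expect_equal(unname(fit$coefficients), c(-0.7, 0.1), tolerance = 1e-10)
  expect_equal(fit$intercept, -0.2, tolerance = 1e-10)
  expect_lt(fit$residual_rms, 1e-10)

  # orthonormal regressors, target equal to the first
  q <- qr.Q(qr(matrix(rnorm(200 * 2), 200)))
  fitq <- fit_linear_combination(q[, 1], data.frame(a = q[, 1], b = q[, 2]))
  expect_equal(unname(fitq$coefficients), c(1, 0), tolerance = 1e-10)
  expect_equal(fitq$intercept, 0, tolerance = 1e-10)

  # residual orthogonal to regressors and intercept
  noisy <- target + rnorm(300, sd = 0.1)
  fitn <- fit_linear_combination(noisy, reg)
  r <- stats::residuals(fitn$fit)
  expect_lt(abs(sum(r)), 1e-8)
  expect_lt(abs(sum(r * reg$AWA)), 1e-8)
  expect_lt(abs(sum(r * reg$PHD)), 1e-8)

  expect_error(fit_linear_combination(target,
                                      data.frame(a = reg$AWA, b = reg$AWA)),
               "collinear")
})

test_that("dual-vs-sum comparison reports additivity and sub-additivity", {
  dt <- 0.05
  times <- seq(0, 400, by = dt)
  mk <- function(depth) {
    v <- rep(1, length(times))
    v[times >= 210 & times < 260] <- 1 - depth
    auc_response(times, v, 200, mode = "suppression", baseline = 1)
  }
  zero <- mk(0); head <- mk(0.2); tail <- mk(0.3)
  cmp0 <- dual_vs_sum(zero, zero, head)
  expect_equal(cmp0$sum, 0)
  expect_equal(cmp0$difference, head$auc)

  dual_add <- mk(0.5)
  cmp <- dual_vs_sum(head, tail, dual_add)
  expect_equal(cmp$difference, 0, tolerance = 1e-9)

  dual_half <- mk(0.25)
  cmp2 <- dual_vs_sum(head, tail, dual_half)
  expect_equal(cmp2$ratio, 0.5, tolerance = 1e-9)

  other <- auc_response(times, rep(1, length(times)), 200,
                        integration_window = 60, mode = "suppression")
  expect_error(dual_vs_sum(head, tail, other), "windows")
})
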