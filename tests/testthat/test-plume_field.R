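# Bilayer diffusion solver, slicing/samplers, and the along-body contrast.

small_setup <- function(c0 = 0.01) {
  list(geom = plate_geometry(radius = 10, dx = 2, dz = 1),
       trans = transport_params(),
       src = source_spec(center_xy = c(-4, 0), c0 = c0))
}

test_that("zero source gives an identically zero field", {
  s <- small_setup(c0 = 0)
  f <- solve_bilayer_diffusion(s$geom, s$trans, s$src, duration = 60,
                               output_times = c(0, 30, 60))
  expect_true(all(f$values == 0))
})

test_that("mass is conserved and the field stays nonnegative", {
  s <- small_setup()
  f <- solve_bilayer_diffusion(s$geom, s$trans, s$src, duration = 300,
                               output_times = seq(0, 300, 60))
  m <- field_mass(f)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-3)
  expect_gte(min(f$values), 0)
})

test_that("a centred source yields a reflection-symmetric field", {
  geom <- plate_geometry(radius = 10, dx = 2, dz = 1)
  f <- solve_bilayer_diffusion(geom, transport_params(),
                               source_spec(center_xy = c(0, 0)),
                               duration = 120,
                               output_times = c(0, 60, 120))
  nv <- f$values
  expect_lt(max(abs(nv - nv[rev(seq_along(f$x)), , , ])), 1e-10)
  expect_lt(max(abs(nv - nv[, rev(seq_along(f$y)), , ])), 1e-10)
})

test_that("air leads agar early; spatial variance decays toward uniformity", {
  s <- small_setup()
  f <- solve_bilayer_diffusion(s$geom, s$trans, s$src, duration = 1200,
                               output_times = c(0, 30, 600, 1200))
  z_air <- f$z > 0
  mask_idx <- which(f$mask)
  layer_mean <- function(k, zsel) {
    v <- f$values[, , zsel, k, drop = FALSE]
    mean(apply(v, 3, function(m) mean(m[mask_idx])))
  }
  expect_gt(layer_mean(2, z_air), layer_mean(2, !z_air))
  v_of <- function(k) stats::var(as.numeric(f$values[, , , k]))
  expect_gt(v_of(2), v_of(3))
  expect_gt(v_of(3), v_of(4))
})

test_that("long-time two-layer column equilibrates to mass / volume", {
  # uniform lateral coverage makes the problem one-dimensional in z;
  # a faster agar diffusivity keeps the equilibration time short without
  # changing the conserved-equilibrium property being checked
  geom <- plate_geometry(radius = 5, dx = 1, dz = 1)
  f <- solve_bilayer_diffusion(geom, transport_params(D_agar = 0.05),
                               source_spec(center_xy = c(0, 0),
                                           footprint_radius = 5, c0 = 0.01),
                               duration = 4000,
                               output_times = c(0, 4000))
  nz <- length(f$z)
  c_eq <- 0.01 * 1 / (geom$air_thickness + geom$agar_thickness)
  final <- f$values[, , , 2]
  vals <- final[rep(f$mask, nz) & final >= 0]
  inplate <- apply(final, 3, function(m) m[f$mask])
  expect_lt(max(abs(inplate - c_eq)) / c_eq, 0.01)
})

test_that("an over-long explicit step and an out-of-plate source are rejected", {
  s <- small_setup()
  expect_error(solve_bilayer_diffusion(s$geom, s$trans, s$src, 60, dt = 10),
               "unstable")
  expect_error(solve_bilayer_diffusion(s$geom, s$trans,
                                       source_spec(center_xy = c(9.5, 0)),
                                       60),
               "outside")
})

test_that("slicing returns stored planes and exact nodal samples", {
  s <- small_setup()
  f <- solve_bilayer_diffusion(s$geom, s$trans, s$src, duration = 300,
                               output_times = seq(0, 300, 60))
  sl <- slice_field(f, -0.5)  # cell centre with dz = 1
  k_z <- which(f$z == -0.5)
  in_plate <- which(f$mask, arr.ind = TRUE)
  for (r in seq_len(4)) {
    i <- in_plate[r, 1]; j <- in_plate[r, 2]
    expect_equal(sl$values[i, j, 3], f$values[i, j, k_z, 3])
    expect_equal(sample_concentration(sl, f$x[i], f$y[j], f$times[3]),
                 f$values[i, j, k_z, 3])
  }
  expect_error(slice_field(f, 1), "agar")
  expect_error(slice_field(f, -20), "agar")
})

test_that("sampled dC/dt matches a finite difference of stored frames", {
  s <- small_setup()
  f <- solve_bilayer_diffusion(s$geom, s$trans, s$src, duration = 600,
                               output_times = seq(0, 600, 60))
  sl <- slice_field(f, -0.5)
  i <- which(f$mask, arr.ind = TRUE)[10, ]
  x0 <- f$x[i[1]]; y0 <- f$y[i[2]]
  # forward difference between frames 5 and 6 is the stored rate there
  fd <- (sl$values[i[1], i[2], 6] - sl$values[i[1], i[2], 5]) / 60
  expect_equal(sample_dCdt(sl, x0, y0, sl$times[5] + 10), fd)
  # and agrees with a centred difference within the frames' curvature
  cd <- (sl$values[i[1], i[2], 6] - sl$values[i[1], i[2], 4]) / 120
  expect_equal(fd, cd, tolerance = 0.5)
})

test_that("contrast is zero on uniform fields and exact on linear fields", {
  uni <- gen_toy_field("uniform", list(level = 2), radius = 10)
  cu <- head_tail_contrast(uni, body_length = 1, n_orientations = 8,
                           times = 0)
  expect_true(all(cu$ratio == 0))

  # small plate so the linear field stays strictly positive everywhere
  lin <- gen_toy_field("linear", list(level = 1, gx = 0.1), radius = 8)
  cl <- head_tail_contrast(lin, body_length = 1, n_orientations = 4,
                           times = 0)
  # orientation along +x at the origin: |C(+0.5) - C(-0.5)| / C(0) = 0.1
  at0 <- cl[abs(cl$x) < 1e-9 & abs(cl$y) < 1e-9 & cl$theta == 0, ]
  expect_equal(at0$ratio, 0.1)
  # analytic value for every sample: |gx cos(theta)| * L / C(mid)
  expected <- abs(0.1 * cos(cl$theta)) / (1 + 0.1 * cl$x)
  expect_equal(cl$ratio, expected, tolerance = 1e-9)

  expect_error(head_tail_contrast(uni, min_body_concentration = 0),
               "guard")
})

test_that("contrast percentiles are monotone and flagging is honoured", {
  sl <- arena_slice_coarse()
  ctr <- head_tail_contrast(sl, body_length = 1, n_orientations = 8)
  q <- contrast_percentile(ctr, c(0.5, 0.9, 0.99))
  expect_true(all(diff(q) >= 0))
  expect_true(any(ctr$flagged))
  expect_gte(contrast_percentile(ctr, 0.99, include_flagged = TRUE),
             q[3] * 0.99)
})
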