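# Two-layer (air over agar) volatile transport in a circular Petri-dish arena,
# solved on a uniform Cartesian grid with a conservative finite-difference
# scheme, plus interpolating samplers and the along-body contrast statistic.

#' Plate geometry for the bilayer arena
#'
#' Describes a circular Petri dish half-filled with agar, with a layer of air
#' between the agar surface and the lid. The vertical origin sits at the
#' air--agar interface: agar occupies `z < 0`, air `z > 0`.
#'
#' @param radius Plate radius (mm).
#' @param air_thickness Thickness of the air layer under the lid (mm).
#' @param agar_thickness Thickness of the agar layer (mm).
#' @param dx Lateral grid spacing (mm).
#' @param dz Vertical grid spacing (mm).
#' @return An object of class `plate_geometry`.
#' @export
plate_geometry <- function(radius, air_thickness = 4, agar_thickness = 9,
                           dx = 2, dz = 1) {
  stopifnot(radius > 0, air_thickness > 0, agar_thickness > 0,
            dx > 0, dz > 0)
  if (2 * radius / dx < 10)
    stop("grid too coarse: need at least 10 lateral cells across the plate")
  if (air_thickness / dz < 1 || agar_thickness / dz < 1)
    stop("vertical spacing exceeds a layer thickness")
  structure(list(radius = radius, air_thickness = air_thickness,
                 agar_thickness = agar_thickness, dx = dx, dz = dz),
            class = "plate_geometry")
}

#' Transport parameters for the volatile pheromone
#'
#' @param D_air Diffusivity in air (mm^2/s).
#' @param D_agar Diffusivity in agar (mm^2/s).
#' @param interface_rule Interfacial condition; only concentration continuity
#'   (no partition coefficient) is implemented.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(D_air = 1.6, D_agar = 1e-3,
                             interface_rule = "concentration-continuous") {
  stopifnot(D_air > 0, D_agar > 0)
  if (D_air < D_agar) stop("D_air must be >= D_agar")
  interface_rule <- match.arg(interface_rule, "concentration-continuous")
  structure(list(D_air = D_air, D_agar = D_agar,
                 interface_rule = interface_rule),
            class = "transport_params")
}

#' Pheromone droplet source on the plate lid
#'
#' @param center_xy Lateral position of the droplet centre (mm, plate centre
#'   at the origin).
#' @param footprint_radius Radius of the droplet footprint on the lid (mm).
#' @param c0 Initial concentration at the droplet surface (mol/m^3).
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(center_xy = c(0, 0), footprint_radius = 1.5,
                        c0 = 0.01) {
  stopifnot(length(center_xy) == 2, footprint_radius > 0, c0 >= 0)
  structure(list(center_xy = as.numeric(center_xy),
                 footprint_radius = footprint_radius, c0 = c0),
            class = "source_spec")
}

# cell-centred axes for a geometry
.grid_axes <- function(geometry) {
  nx <- ceiling(2 * geometry$radius / geometry$dx)
  x <- (seq_len(nx) - (nx + 1) / 2) * geometry$dx
  nza <- round(geometry$agar_thickness / geometry$dz)
  nzr <- round(geometry$air_thickness / geometry$dz)
  z <- c(-geometry$agar_thickness + (seq_len(nza) - 0.5) * geometry$dz,
         (seq_len(nzr) - 0.5) * geometry$dz)
  list(x = x, y = x, z = z, nza = nza)
}

#' Solve volatile transport in the two-layer arena
#'
#' Explicit conservative finite differences on a uniform Cartesian grid.
#' Diffusivity is piecewise constant per layer; vertical face diffusivities
#' across the air--agar interface are harmonic means, which enforces flux and
#' concentration continuity. The circular wall is represented by masking
#' cells outside the plate and zeroing the conductance of every masked face,
#' so the no-flux condition holds discretely and the total dissolved amount
#' is conserved to rounding error.
#'
#' @param geometry A [plate_geometry()].
#' @param transport A [transport_params()].
#' @param source A [source_spec()]; the droplet footprint initialises the top
#'   (lid-adjacent) air cells at `c0`, everything else at zero.
#' @param duration Simulated time (s).
#' @param output_times Times (s) at which to store frames; must lie in
#'   `[0, duration]`.
#' @param dt Optional fixed time step (s). The default picks a stable step
#'   automatically; supplying a step above the stability limit is an error.
#' @return An object of class `concentration_field` with elements `times`,
#'   `x`, `y`, `z`, `values` (array `[x, y, z, time]`, mol/m^3), the inputs,
#'   and the lateral `mask`.
#' @export
solve_bilayer_diffusion <- function(geometry, transport, source, duration,
                                    output_times = seq(0, duration, by = 60),
                                    dt = NULL) {
  stopifnot(inherits(geometry, "plate_geometry"),
            inherits(transport, "transport_params"),
            inherits(source, "source_spec"), duration > 0)
  output_times <- sort(unique(c(0, output_times)))
  if (any(output_times < 0 | output_times > duration))
    stop("output_times must lie within [0, duration]")
  if (sqrt(sum(source$center_xy^2)) + source$footprint_radius >
      geometry$radius)
    stop("source footprint extends outside the plate")

  ax <- .grid_axes(geometry)
  x <- ax$x; y <- ax$y; z <- ax$z
  nx <- length(x); ny <- length(y); nz <- length(z)
  dxl <- geometry$dx; dzl <- geometry$dz
  Dz <- ifelse(z < 0, transport$D_agar, transport$D_air)

  mask2 <- outer(x^2, y^2, "+") <= geometry$radius^2
  dt_stable <- 0.9 / (2 * max(Dz) * (2 / dxl^2 + 1 / dzl^2))
  if (is.null(dt)) dt <- dt_stable
  else if (dt > dt_stable)
    stop(sprintf("unstable time step: dt = %g exceeds stability limit %g",
                 dt, dt_stable))

  # face conductances (zero at masked faces and walls)
  pairx <- mask2[-nx, ] & mask2[-1, ]          # (nx-1, ny)
  pairy <- mask2[, -ny] & mask2[, -1]          # (nx, ny-1)
  Dfz <- 2 / (1 / Dz[-nz] + 1 / Dz[-1])        # harmonic mean, length nz-1

  C <- array(0, c(nx, ny, nz))
  foot <- outer(x - source$center_xy[1], y - source$center_xy[2],
                function(a, b) a^2 + b^2) <= source$footprint_radius^2
  foot <- foot & mask2
  if (!any(foot)) { # coarse grid: seed the nearest in-plate cell
    d2 <- outer(x - source$center_xy[1], y - source$center_xy[2],
                function(a, b) a^2 + b^2)
    d2[!mask2] <- Inf
    foot <- d2 == min(d2)
  }
  C[, , nz][foot] <- source$c0

  values <- array(0, c(nx, ny, nz, length(output_times)))
  values[, , , 1] <- C
  t_now <- 0
  for (k in seq_along(output_times)[-1]) {
    span <- output_times[k] - t_now
    nsub <- max(1L, ceiling(span / dt))
    h <- span / nsub
    for (s in seq_len(nsub)) {
      dC <- array(0, c(nx, ny, nz))
      fx <- (C[-1, , , drop = FALSE] - C[-nx, , , drop = FALSE]) *
        array(rep(pairx, nz), c(nx - 1, ny, nz)) *
        rep(Dz, each = (nx - 1) * ny) / dxl^2
      dC[-nx, , ] <- dC[-nx, , ] + fx
      dC[-1, , ] <- dC[-1, , ] - fx
      fy <- (C[, -1, , drop = FALSE] - C[, -ny, , drop = FALSE]) *
        array(rep(pairy, nz), c(nx, ny - 1, nz)) *
        rep(Dz, each = nx * (ny - 1)) / dxl^2
      dC[, -ny, ] <- dC[, -ny, ] + fy
      dC[, -1, ] <- dC[, -1, ] - fy
      fz <- (C[, , -1, drop = FALSE] - C[, , -nz, drop = FALSE]) *
        rep(Dfz, each = nx * ny) / dzl^2
      fz <- fz * array(mask2, c(nx, ny, nz - 1))
      dC[, , -nz] <- dC[, , -nz] + fz
      dC[, , -1] <- dC[, , -1] - fz
      C <- C + h * dC
    }
    t_now <- output_times[k]
    values[, , , k] <- C
  }

  structure(list(times = output_times, x = x, y = y, z = z, values = values,
                 geometry = geometry, transport = transport, source = source,
                 mask = mask2, dt = dt),
            class = "concentration_field")
}

#' Total dissolved amount per stored frame
#'
#' @param field A `concentration_field`.
#' @return Numeric vector, one total amount (mol, using mm^3 cell volumes
#'   scaled to m^3) per stored time.
#' @export
field_mass <- function(field) {
  cell <- field$geometry$dx^2 * field$geometry$dz * 1e-9  # mm^3 -> m^3
  apply(field$values, 4, sum) * cell
}

#' Extract a lateral cross-section with interpolating samplers
#'
#' Takes a horizontal plane inside the agar layer (the depth at which crawling
#' worms sample the field). Values are interpolated linearly between the two
#' adjacent grid planes; with the default vertical spacing the conventional
#' plane `z = -0.5` mm falls exactly on a cell centre.
#'
#' @param field A `concentration_field`.
#' @param plane_z Plane height (mm), negative inside the agar.
#' @return An object of class `field_slice` usable with
#'   [sample_concentration()], [sample_dCdt()], [head_tail_contrast()] and
#'   [run_cohort()].
#' @export
slice_field <- function(field, plane_z = -0.5) {
  stopifnot(inherits(field, "concentration_field"))
  if (plane_z >= 0 || plane_z <= -field$geometry$agar_thickness)
    stop("plane_z must lie inside the agar layer")
  z <- field$z
  if (plane_z <= z[1]) { i0 <- 1L; w <- 0 }
  else {
    i0 <- max(which(z <= plane_z))
    if (i0 == length(z)) { i0 <- length(z) - 1L; w <- 1 }
    else w <- (plane_z - z[i0]) / (z[i0 + 1] - z[i0])
  }
  vals <- (1 - w) * field$values[, , i0, , drop = FALSE] +
    w * field$values[, , min(i0 + 1L, length(z)), , drop = FALSE]
  dim(vals) <- dim(field$values)[c(1, 2, 4)]
  # ghost values outside the circular wall: replicate the nearest in-plate
  # values outward so interpolation near the rim respects the no-flux wall
  # (a zero-filled exterior would fake steep rim gradients)
  if (any(!field$mask)) {
    nx <- dim(vals)[1]; ny <- dim(vals)[2]
    for (k in seq_len(dim(vals)[3])) {
      V <- vals[, , k]
      V[!field$mask] <- NA
      while (anyNA(V)) {
        isna <- is.na(V)
        nb_sum <- matrix(0, nx, ny); nb_n <- matrix(0, nx, ny)
        for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          S <- matrix(NA_real_, nx, ny)
          xi <- seq_len(nx) - sh[1]; yi <- seq_len(ny) - sh[2]
          ok_x <- xi >= 1 & xi <= nx; ok_y <- yi >= 1 & yi <= ny
          S[ok_x, ok_y] <- V[xi[ok_x], yi[ok_y]]
          have <- !is.na(S)
          nb_sum[have] <- nb_sum[have] + S[have]
          nb_n[have] <- nb_n[have] + 1
        }
        fill <- isna & nb_n > 0
        if (!any(fill)) break
        V[fill] <- nb_sum[fill] / nb_n[fill]
      }
      V[is.na(V)] <- 0
      vals[, , k] <- V
    }
  }
  structure(list(kind = "grid", plane_z = plane_z, x = field$x, y = field$y,
                 times = field$times, values = vals,
                 radius = field$geometry$radius,
                 source_xy = field$source$center_xy, c0 = field$source$c0),
            class = "field_slice")
}

# bilinear interpolation on the lateral grid of one frame (matrix V)
.bilinear <- function(xg, yg, V, px, py) {
  dxl <- xg[2] - xg[1]
  fx <- (px - xg[1]) / dxl
  fy <- (py - yg[1]) / dxl
  i <- pmin(pmax(floor(fx), 0), length(xg) - 2)
  j <- pmin(pmax(floor(fy), 0), length(yg) - 2)
  tx <- pmin(pmax(fx - i, 0), 1)
  ty <- pmin(pmax(fy - j, 0), 1)
  i <- i + 1L; j <- j + 1L
  n <- length(xg)
  V00 <- V[i + (j - 1L) * n]; V10 <- V[i + 1L + (j - 1L) * n]
  V01 <- V[i + j * n];        V11 <- V[i + 1L + j * n]
  (1 - tx) * (1 - ty) * V00 + tx * (1 - ty) * V10 +
    (1 - tx) * ty * V01 + tx * ty * V11
}

#' Sample concentration from a field slice
#'
#' Bilinear in space and linear in time for gridded slices; exact closed form
#' for analytic toy slices (see [gen_toy_field()]).
#'
#' @param slice A `field_slice`.
#' @param x,y Lateral coordinates (mm), vectorised.
#' @param t Time (s), a scalar or a vector matching `x`.
#' @return Concentrations (mol/m^3).
#' @export
sample_concentration <- function(slice, x, y, t) {
  stopifnot(inherits(slice, "field_slice"))
  if (slice$kind == "analytic") return(slice$C_fun(x, y, t))
  tt <- rep_len(t, length(x))
  if (min(tt) < slice$times[1] - 1e-9 ||
      max(tt) > slice$times[length(slice$times)] + 1e-9)
    stop("sample time outside the stored frame range")
  out <- numeric(length(x))
  k <- findInterval(tt, slice$times, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(slice$times) - 1L)
  for (kk in unique(k)) {
    sel <- which(k == kk)
    w <- (tt[sel] - slice$times[kk]) /
      (slice$times[kk + 1] - slice$times[kk])
    a <- .bilinear(slice$x, slice$y, slice$values[, , kk], x[sel], y[sel])
    b <- .bilinear(slice$x, slice$y, slice$values[, , kk + 1], x[sel], y[sel])
    out[sel] <- (1 - w) * a + w * b
  }
  out
}

#' Sample the local time derivative of concentration
#'
#' For gridded slices the rate is the forward difference between the stored
#' frames bracketing `t` (constant within each frame interval).
#'
#' @inheritParams sample_concentration
#' @return Concentration rates (mol/m^3/s).
#' @export
sample_dCdt <- function(slice, x, y, t) {
  stopifnot(inherits(slice, "field_slice"))
  if (slice$kind == "analytic") return(slice$dCdt_fun(x, y, t))
  tt <- rep_len(t, length(x))
  out <- numeric(length(x))
  k <- findInterval(tt, slice$times, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(slice$times) - 1L)
  for (kk in unique(k)) {
    sel <- which(k == kk)
    dtk <- slice$times[kk + 1] - slice$times[kk]
    a <- .bilinear(slice$x, slice$y, slice$values[, , kk], x[sel], y[sel])
    b <- .bilinear(slice$x, slice$y, slice$values[, , kk + 1], x[sel], y[sel])
    out[sel] <- (b - a) / dtk
  }
  out
}

#' Along-body concentration contrast |C(head) - C(tail)| / C(body)
#'
#' Quantifies how much concentration difference a worm of the given body
#' length could read between its two ends, sampled over the plate area, the
#' stored frames and a uniform grid of body orientations. Samples whose
#' midpoint concentration falls below `min_body_concentration` are flagged
#' rather than dropped: near the plate edge the midpoint concentration is
#' close to zero and the ratio is numerically noisy.
#'
#' @param slice A `field_slice`.
#' @param body_length Head-to-tail separation (mm).
#' @param n_orientations Number of body orientations, uniform on `[0, 2*pi)`.
#' @param min_body_concentration Flagging threshold for the midpoint
#'   concentration; default `1e-6 * c0` of the slice source (or `1e-12` for
#'   slices without a source amplitude).
#' @param times Frame times to include (default: all stored frames, skipping
#'   the initial all-zero frame when present).
#' @return An object of class `contrast_distribution`: a data frame with
#'   columns `x`, `y`, `t`, `theta`, `ratio`, `flagged`, and a
#'   `percentile(q)` attribute-function operating on unflagged samples.
#' @export
head_tail_contrast <- function(slice, body_length = 1, n_orientations = 16,
                               min_body_concentration = NULL,
                               times = NULL) {
  stopifnot(inherits(slice, "field_slice"), body_length > 0,
            n_orientations >= 1)
  if (is.null(min_body_concentration)) {
    min_body_concentration <-
      if (!is.null(slice$c0) && slice$c0 > 0) 1e-6 * slice$c0 else 1e-12
  }
  if (min_body_concentration <= 0)
    stop("min_body_concentration must be positive (division guard)")
  if (is.null(times)) {
    times <- slice$times
    if (length(times) > 1 && slice$kind == "grid" &&
        all(slice$values[, , 1] == 0))
      times <- times[-1]
  }
  half <- body_length / 2
  if (slice$kind == "grid") {
    gx <- rep(slice$x, times = length(slice$y))
    gy <- rep(slice$y, each = length(slice$x))
  } else {
    ax <- seq(-slice$radius, slice$radius, by = slice$radius / 20)
    gx <- rep(ax, times = length(ax))
    gy <- rep(ax, each = length(ax))
  }
  keep <- gx^2 + gy^2 <= (slice$radius - half)^2
  gx <- gx[keep]; gy <- gy[keep]
  thetas <- seq(0, 2 * pi, length.out = n_orientations + 1)[-(n_orientations + 1)]

  res <- vector("list", length(times) * length(thetas))
  idx <- 0L
  for (tk in times) for (th in thetas) {
    idx <- idx + 1L
    ux <- cos(th) * half; uy <- sin(th) * half
    cb <- sample_concentration(slice, gx, gy, tk)
    ch <- sample_concentration(slice, gx + ux, gy + uy, tk)
    ct <- sample_concentration(slice, gx - ux, gy - uy, tk)
    flag <- cb < min_body_concentration
    ratio <- ifelse(cb > 0, abs(ch - ct) / cb, NA_real_)
    res[[idx]] <- data.frame(x = gx, y = gy, t = tk, theta = th,
                             ratio = ratio, flagged = flag)
  }
  out <- do.call(rbind, res)
  class(out) <- c("contrast_distribution", "data.frame")
  out
}

#' Reference concentration at the source on a navigation slice
#'
#' The model's reference concentration is the concentration at the
#' pheromone source; for navigation on a cross-section of the bilayer
#' field, the operative value is the concentration at the source's lateral
#' position on that plane. This helper returns its maximum over the stored
#' frames, the natural scale for the sensory functions of the navigator.
#'
#' @param slice A `field_slice`.
#' @param source_xy Source position (mm); defaults to the slice metadata.
#' @return Concentration (mol/m^3).
#' @export
reference_concentration <- function(slice, source_xy = slice$source_xy) {
  stopifnot(inherits(slice, "field_slice"))
  if (slice$kind == "analytic")
    return(slice$C_fun(source_xy[1], source_xy[2], 0))
  max(vapply(slice$times, function(tt)
    sample_concentration(slice, source_xy[1], source_xy[2], tt),
    numeric(1)))
}

#' Percentiles of the contrast distribution
#'
#' @param dist A `contrast_distribution`.
#' @param q Probabilities.
#' @param include_flagged Include samples flagged as numerically noisy
#'   (near-zero midpoint concentration)?
#' @return Quantiles of the contrast ratio.
#' @export
contrast_percentile <- function(dist, q, include_flagged = FALSE) {
  stopifnot(inherits(dist, "contrast_distribution"))
  r <- if (include_flagged) dist$ratio else dist$ratio[!dist$flagged]
  stats::quantile(r, probs = q, na.rm = TRUE, names = FALSE)
}
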