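#' Axial (Poiseuille) velocity profile
#'
#' Fully developed laminar through-flow in the lumen,
#' `u_z(r) = (2 Q / (pi R^2)) * (1 - (r/R)^2)`. At the creeping Reynolds
#' numbers of this device the axial entrance length is below one radius, so
#' entrance development of the axial profile is neglected.
#'
#' @param r Radial positions in m (vector).
#' @param geometry,operating Configuration objects.
#' @return Axial velocity u_z in m/s at each `r`.
#' @export
#' @examples
#' axial_profile(0)  # centreline, about 3.95e-4 m/s at defaults
axial_profile <- function(r, geometry = bioreactor_geometry(),
                          operating = operating_conditions()) {
  R <- geometry$lumen_radius
  u0 <- 2 * operating$flow_rate / (pi * R^2)
  ifelse(r <= R, u0 * (1 - (r / R)^2), 0)
}

# Axial grid over [-L_in, L + L_out], clustered just downstream of wall-BC
# discontinuities (z = -L_in inflow, z = 0 for the double design, z = L).
flow_z_grid <- function(geometry, n_z) {
  Lin <- geometry$inlet_anchor_length
  L <- geometry$lumen_length
  Lout <- geometry$outlet_anchor_length
  total <- Lin + L + Lout
  spans <- rbind(c(-Lin, 0), c(0, L), c(L, L + Lout))
  z <- numeric(0)
  for (k in seq_len(nrow(spans))) {
    n <- max(4L, round(n_z * (spans[k, 2] - spans[k, 1]) / total))
    s <- (seq_len(n) / n)^1.6  # cluster at the upstream edge of the span
    z <- c(z, spans[k, 1], spans[k, 1] + s * (spans[k, 2] - spans[k, 1]))
  }
  sort(unique(z))
}

# Wall azimuthal velocity per axial station. The scaffold (0 <= z <= L)
# always rotates; the inlet anchor span rotates only for the single_rotating
# design; the outlet anchor span is always static. Nodes exactly at a
# rotating/static interface are assigned to the rotating scaffold so the
# singular corner sits just outside the lumen summary span.
wall_swirl_bc <- function(z, geometry, operating) {
  R <- geometry$lumen_radius
  L <- geometry$lumen_length
  rotating <- if (geometry$inlet_design == "single_rotating") z <= L else (z >= 0 & z <= L)
  ifelse(rotating, operating$omega * R, 0)
}

# Nonuniform-grid FD coefficients for L[w] = w'' + w'/r - w/r^2 at interior
# nodes; returns list(lo, di, up) aligned with r[2:(n-1)].
swirl_operator_coefs <- function(r) {
  n <- length(r)
  i <- 2:(n - 1)
  hm <- r[i] - r[i - 1]
  hp <- r[i + 1] - r[i]
  d2lo <- 2 / (hm * (hm + hp)); d2up <- 2 / (hp * (hm + hp)); d2di <- -2 / (hm * hp)
  d1lo <- -hp / (hm * (hm + hp)); d1up <- hm / (hp * (hm + hp))
  d1di <- (hp - hm) / (hm * hp)
  list(lo = d2lo + d1lo / r[i],
       di = d2di + d1di / r[i] - 1 / r[i]^2,
       up = d2up + d1up / r[i])
}

thomas_solve <- function(lo, di, up, rhs) {
  n <- length(di)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- up[1] / di[1]; dp[1] <- rhs[1] / di[1]
  for (i in 2:n) {
    m <- di[i] - lo[i] * cp[i - 1]
    cp[i] <- if (i < n) up[i] / m else 0
    dp[i] <- (rhs[i] - lo[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Implicit z-marching of u_z(r) dw/dz = nu * (w'' + w'/r - w/r^2).
# r, z monotone grids; uz values on r; wallw values on z; w(:,1) is the
# inflow condition (zero swirl except the wall node).
swirl_march <- function(r, z, uz, wallw, nu) {
  if (is.unsorted(r, strictly = TRUE) || is.unsorted(z, strictly = TRUE)) {
    stop("swirl solver requires strictly monotone grids", call. = FALSE)
  }
  if (nu <= 0) stop("kinematic viscosity must be > 0", call. = FALSE)
  n_r <- length(r); n_z <- length(z)
  W <- matrix(0, n_r, n_z)
  W[n_r, 1] <- wallw[1]
  cf <- swirl_operator_coefs(r)
  i <- 2:(n_r - 1)
  for (k in 2:n_z) {
    dz <- z[k] - z[k - 1]
    a <- uz[i] / dz
    lo <- -nu * cf$lo
    di <- a - nu * cf$di
    up <- -nu * cf$up
    rhs <- a * W[i, k - 1]
    # fold Dirichlet BCs (w(0)=0, w(R)=wallw[k]) into the rhs
    rhs[length(i)] <- rhs[length(i)] - up[length(i)] * wallw[k]
    W[i, k] <- thomas_solve(lo, di, up, rhs)
    W[1, k] <- 0
    W[n_r, k] <- wallw[k]
  }
  W
}

# Independent oracle: one global sparse solve of the identically discretized
# parabolic problem (first-order upwind in z), via Matrix.
swirl_sparse <- function(r, z, uz, wallw, nu) {
  n_r <- length(r); n_z <- length(z)
  idx <- function(i, k) (k - 1) * n_r + i
  cf <- swirl_operator_coefs(r)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0); rhs <- numeric(n_r * n_z)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v)
  }
  for (k in seq_len(n_z)) {
    # boundary rows
    add(idx(1, k), idx(1, k), 1); rhs[idx(1, k)] <- 0
    add(idx(n_r, k), idx(n_r, k), 1); rhs[idx(n_r, k)] <- wallw[k]
    if (k == 1) {
      for (i in 2:(n_r - 1)) { add(idx(i, 1), idx(i, 1), 1); rhs[idx(i, 1)] <- 0 }
      next
    }
    dz <- z[k] - z[k - 1]
    for (i in 2:(n_r - 1)) {
      a <- uz[i] / dz
      row <- idx(i, k)
      add(row, row, a - nu * cf$di[i - 1])
      add(row, idx(i - 1, k), -nu * cf$lo[i - 1])
      add(row, idx(i + 1, k), -nu * cf$up[i - 1])
      add(row, idx(i, k - 1), -a)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_r * n_z, n_r * n_z))
  w <- Matrix::solve(A, rhs)
  matrix(as.numeric(w), n_r, n_z)
}

#' Solve the composite lumen flow field
#'
#' Builds the reduced-order steady laminar field inside the lumen and its
#' anchor extensions: Poiseuille axial flow [axial_profile()] (independent of
#' z, radial velocity identically zero) plus a developing azimuthal swirl
#' field `w(r, z)` obeying the advection--diffusion reduction of the
#' azimuthal momentum equation,
#' `u_z(r) dw/dz = nu (d2w/dr2 + (1/r) dw/dr - w/r^2)`,
#' marched implicitly in z from a zero-swirl inflow (the supply tubing is
#' static in both designs). The wall boundary condition is `omega * R` on
#' rotating spans and 0 on static anchor spans, per the design variant.
#'
#' @param geometry,operating,fluid Configuration objects.
#' @param n_r,n_z Grid resolution (minimum 32 x 64).
#' @param method `"march"` (implicit z-marching, the production route) or
#'   `"sparse"` (a single global sparse solve of the same discretized problem;
#'   the verification oracle).
#' @return An object of class `flow_field`: list with `r`, `z`, `uz` (on `r`),
#'   `w` (`n_r x n_z` matrix), and the configuration. Values between nodes are
#'   defined by bilinear interpolation.
#' @export
solve_swirl <- function(geometry = bioreactor_geometry(),
                        operating = operating_conditions(),
                        fluid = fluid_properties(),
                        n_r = 64, n_z = 128,
                        method = c("march", "sparse")) {
  method <- match.arg(method)
  if (n_r < 32 || n_z < 64) stop("grid must be at least 32 x 64", call. = FALSE)
  R <- geometry$lumen_radius
  r <- seq(0, R, length.out = n_r)
  z <- flow_z_grid(geometry, n_z)
  uz <- axial_profile(r, geometry, operating)
  wallw <- wall_swirl_bc(z, geometry, operating)
  nu <- fluid$viscosity / fluid$density
  W <- if (method == "march") swirl_march(r, z, uz, wallw, nu) else swirl_sparse(r, z, uz, wallw, nu)
  structure(list(r = r, z = z, uz = uz, w = W,
                 geometry = geometry, operating = operating, fluid = fluid,
                 method = method),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %s, %.3g mL/min, %g rpm; grid %d x %d (%s)\n",
              x$geometry$inlet_design, x$operating$flow_rate * 6e7,
              x$operating$rpm, length(x$r), length(x$z), x$method))
  invisible(x)
}

# Second-order one-sided derivative at the last node of a (possibly
# nonuniform) grid, applied to each column of V (or a vector).
wall_derivative <- function(r, V) {
  n <- length(r)
  if (n < 3) stop("grid too coarse for the second-order wall stencil", call. = FALSE)
  h1 <- r[n] - r[n - 1]
  h2 <- r[n - 1] - r[n - 2]
  c0 <- (2 * h1 + h2) / (h1 * (h1 + h2))
  c1 <- -(h1 + h2) / (h1 * h2)
  c2 <- h1 / (h2 * (h1 + h2))
  if (is.matrix(V)) c0 * V[n, ] + c1 * V[n - 1, ] + c2 * V[n - 2, ]
  else c0 * V[n] + c1 * V[n - 1] + c2 * V[n - 2]
}

#' Luminal wall shear stress profile
#'
#' Evaluates the wall shear components along the lumen from a [solve_swirl()]
#' field using second-order one-sided radial differences at the wall:
#'
#' * `tau_axial = mu * |du_z/dr|` at r = R (through-flow contribution);
#' * `tau_azimuthal = mu * |dw/dr|` at r = R, the lab-frame wall velocity
#'   gradient. This is the quantity general-purpose CFD post-processors report
#'   and the one the reference wall-shear figures print: for solid-body swirl
#'   it equals `mu * omega`. The true azimuthal viscous traction,
#'   `mu * |dw/dr - w/r|` (zero for solid-body rotation), is reported
#'   separately as `tau_azimuthal_traction`;
#' * `tau_mag = sqrt(tau_axial^2 + tau_azimuthal^2)`.
#'
#' The `summary` (min/max/mean) is area-weighted over the scaffold span
#' `0 <= z <= L` only (constant radius, so area weight is proportional to dz).
#'
#' @param field A `flow_field`.
#' @return An object of class `wall_shear_profile`: data.frame `profile` with
#'   columns `z_m`, `tau_axial_Pa`, `tau_azimuthal_Pa`,
#'   `tau_azimuthal_traction_Pa`, `tau_mag_Pa`, plus `summary` (min, max,
#'   mean of `tau_mag` over the scaffold).
#' @export
wall_shear <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  mu <- field$fluid$viscosity
  R <- field$geometry$lumen_radius
  L <- field$geometry$lumen_length
  duz <- wall_derivative(field$r, field$uz)
  dw <- wall_derivative(field$r, field$w)
  tau_ax <- rep(mu * abs(duz), length(field$z))
  tau_az <- mu * abs(dw)
  tau_tr <- mu * abs(dw - field$w[length(field$r), ] / R)
  tau_mag <- sqrt(tau_ax^2 + tau_az^2)
  prof <- data.frame(z_m = field$z, tau_axial_Pa = tau_ax,
                     tau_azimuthal_Pa = tau_az,
                     tau_azimuthal_traction_Pa = tau_tr,
                     tau_mag_Pa = tau_mag)
  inside <- field$z >= 0 & field$z <= L
  zi <- field$z[inside]; ti <- tau_mag[inside]
  wts <- diff(zi)
  mean_tau <- sum((ti[-1] + ti[-length(ti)]) / 2 * wts) / sum(wts)
  structure(list(profile = prof,
                 summary = c(min = min(ti), max = max(ti), mean = mean_tau)),
            class = "wall_shear_profile")
}

#' @export
print.wall_shear_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<wall_shear_profile> scaffold span: min %.3e  max %.3e  mean %.3e Pa\n",
              s["min"], s["max"], s["mean"]))
  invisible(x)
}

#' Wall-shear summary sweep over designs, rotation speeds and flow rates
#'
#' Runs [solve_swirl()] + [wall_shear()] for every combination and tabulates
#' the scaffold-span summary, in deterministic (nested, input-order) row
#' order.
#'
#' @param designs Character vector of inlet designs.
#' @param rpms Numeric vector of rotation speeds (rev/min).
#' @param flow_rates_mL_min Numeric vector of flow rates in mL/min.
#' @param geometry,fluid Shared configuration objects.
#' @param n_r,n_z Grid resolution passed to [solve_swirl()].
#' @return data.frame with columns `design`, `rpm`, `flow_mL_min`,
#'   `tau_min_Pa`, `tau_max_Pa`, `tau_mean_Pa`.
#' @export
wss_summary_sweep <- function(designs = c("single_rotating", "double_static"),
                              rpms = c(0, 1, 5, 15),
                              flow_rates_mL_min = 1.5,
                              geometry = bioreactor_geometry(),
                              fluid = fluid_properties(),
                              n_r = 64, n_z = 128) {
  if (!length(designs) || !length(rpms) || !length(flow_rates_mL_min)) {
    stop("sweep lists must be non-empty", call. = FALSE)
  }
  rows <- list()
  for (d in designs) for (rpm in rpms) for (q in flow_rates_mL_min) {
    g <- geometry; g$inlet_design <- d
    op <- operating_conditions(flow_rate = q * 1e-6 / 60, rpm = rpm)
    ws <- wall_shear(solve_swirl(g, op, fluid, n_r = n_r, n_z = n_z))
    rows[[length(rows) + 1]] <- data.frame(
      design = d, rpm = rpm, flow_mL_min = q,
      tau_min_Pa = ws$summary["min"], tau_max_Pa = ws$summary["max"],
      tau_mean_Pa = ws$summary["mean"], row.names = NULL)
  }
  do.call(rbind, rows)
}
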