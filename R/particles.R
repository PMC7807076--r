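#' Particle momentum relaxation time (Stokes drag)
#'
#' `tau_p = rho_p * d_p^2 / (18 mu)`, the time constant of the linear-drag
#' particle momentum equation in the Stokes limit (drag coefficient
#' `C_D = 24/Re_p`). Also guards the validity of that limit: errors when the
#' particle Reynolds number at terminal slip exceeds 0.1.
#'
#' @param particles,fluid Configuration objects.
#' @param gravity_magnitude Used only for the validity guard.
#' @return Relaxation time in s (about 5.83e-6 s at defaults).
#' @export
relaxation_time <- function(particles = particle_properties(),
                            fluid = fluid_properties(),
                            gravity_magnitude = 9.81) {
  tau <- particles$density * particles$diameter^2 / (18 * fluid$viscosity)
  vs <- abs(particles$density - fluid$density) * gravity_magnitude *
    particles$diameter^2 / (18 * fluid$viscosity)
  re_p <- fluid$density * vs * particles$diameter / fluid$viscosity
  if (re_p > 0.1) {
    stop(sprintf(
      "particle Reynolds number at terminal slip is %.3g > 0.1; Stokes drag invalid",
      re_p), call. = FALSE)
  }
  tau
}

#' Gravitational settling velocity
#'
#' Terminal Stokes settling speed
#' `v_s = (rho_p - rho) * g * d_p^2 / (18 mu)`, directed along gravity
#' (negative for buoyant particles).
#'
#' @param particles,fluid Configuration objects.
#' @param gravity_magnitude Gravitational acceleration, m/s^2.
#' @return Settling speed in m/s (about 2.73e-6 m/s at defaults).
#' @export
settling_velocity <- function(particles = particle_properties(),
                              fluid = fluid_properties(),
                              gravity_magnitude = 9.81) {
  (particles$density - fluid$density) * gravity_magnitude *
    particles$diameter^2 / (18 * fluid$viscosity)
}

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Inject particles at the scaffold inlet
#'
#' Draws initial particle positions area-uniformly over the design's entry
#' locus at z = 0: a centred disk of radius `inlet_port_radius` for the
#' single-rotating design, the entry annulus for the double-static design.
#' Initial velocity equals the local fluid velocity.
#'
#' Because the composite field has zero radial velocity, each particle also
#' carries an entrance-redistribution drift: over an entrance length of two
#' radii its radial position relaxes linearly from the port radius to a
#' radius drawn area-uniformly over the full cross-section (quantile
#' coupling, preserving the angular position). This stands in for the
#' three-dimensional entrance flow that spreads the injected bolus across the
#' lumen; without it the reduced field could deposit nothing. See the methods
#' vignette for the rationale and its limits.
#'
#' @param n Number of particles (default from protocol, 11000).
#' @param geometry,protocol Configuration objects.
#' @param seed Integer seed; identical seeds give identical injections.
#' @return data.frame of class `particle_injection` with columns
#'   `particle_id`, `r0_m` (port radius), `theta_deg`, `r1_m` (post-entrance
#'   radius), `slope` (entrance dr/dz).
#' @export
inject_particles <- function(n = NULL, geometry = bioreactor_geometry(),
                             protocol = seeding_protocol(), seed = 1) {
  if (is.null(n)) n <- protocol$n_particles
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  R <- geometry$lumen_radius
  df <- with_seed(seed, {
    u <- stats::runif(n)
    theta <- stats::runif(n, 0, 360)
    r1 <- R * sqrt(u)
    r0 <- if (geometry$inlet_design == "single_rotating") {
      geometry$inlet_port_radius * sqrt(u)
    } else {
      ri <- geometry$inlet_port_annulus_radius - geometry$inlet_port_annulus_halfwidth
      ro <- geometry$inlet_port_annulus_radius + geometry$inlet_port_annulus_halfwidth
      sqrt(ri^2 + u * (ro^2 - ri^2))
    }
    data.frame(particle_id = seq_len(n), r0_m = r0, theta_deg = theta,
               r1_m = r1, slope = (r1 - r0) / (2 * R))
  })
  structure(df, class = c("particle_injection", "data.frame"),
            geometry = geometry, seed = seed, entrance_len = 2 * R)
}

tracking_args <- function(field, particles, fluid, operating, protocol, mode) {
  geometry <- field$geometry
  list(
    rg = field$r, zg = field$z, W = field$w, uz = field$uz,
    R = geometry$lumen_radius, L = geometry$lumen_length,
    entrance_len = 2 * geometry$lumen_radius,
    vs = settling_velocity(particles, fluid, operating$gravity_magnitude),
    gx = operating$gravity_direction[1], gy = operating$gravity_direction[2],
    tau_p = relaxation_time(particles, fluid, operating$gravity_magnitude),
    path_step = protocol$path_step_m * (if (mode == "equilibrium") 1 else 0.1),
    max_path = protocol$path_step_m * protocol$max_steps,
    dtheta_max = if (mode == "equilibrium") 0.1 else 0.005,
    mode = if (mode == "equilibrium") 0L else 1L
  )
}

records_from_matrix <- function(m, ids) {
  fate <- factor(c("trapped", "escaped", "incomplete")[m[, "fate"]],
                 levels = c("trapped", "escaped", "incomplete"))
  data.frame(particle_id = ids, fate = fate,
             z_m = m[, "z_m"],
             theta_deg = ifelse(fate == "trapped", m[, "theta_deg"], NA_real_),
             time_s = m[, "time_s"], path_length_m = m[, "path_length_m"])
}

#' Integrate a single particle trajectory
#'
#' Advances one particle through a [solve_swirl()] field until it is trapped
#' at the lumen wall, escapes past the outlet, or exceeds the protocol path
#' cap. The default integrator is the overdamped equilibrium closure
#' `u_p = u + v_s ghat + tau_p (w^2/r) rhat` (valid because the Stokes number
#' is far below one); `mode = "full"` integrates the inertial momentum
#' equation with exact (exponential) linear-drag substeps and serves as the
#' oracle for the default.
#'
#' @param field A `flow_field`.
#' @param r0,theta_deg Initial radial position (m) and angle (degrees from
#'   top).
#' @param slope Entrance-redistribution drift dr/dz (0 disables it).
#' @param particles,fluid,operating,protocol Configuration objects.
#' @param mode `"equilibrium"` or `"full"`.
#' @param thin Record every `thin`-th step of the trajectory.
#' @return list with `record` (fate, contact/exit position, time, path) and
#'   `trajectory` (matrix of time, x, y, z, path).
#' @export
integrate_trajectory <- function(field, r0, theta_deg = 0, slope = 0,
                                 particles = particle_properties(),
                                 fluid = fluid_properties(),
                                 operating = field$operating,
                                 protocol = seeding_protocol(),
                                 mode = c("equilibrium", "full"),
                                 thin = 10L) {
  mode <- match.arg(mode)
  R <- field$geometry$lumen_radius
  if (!is.finite(r0) || r0 < 0 || r0 >= R) {
    stop("r0 must lie inside the lumen [0, R)", call. = FALSE)
  }
  a <- tracking_args(field, particles, fluid, operating, protocol, mode)
  res <- .track_one(r0, theta_deg * pi / 180, slope,
                    a$rg, a$zg, a$W, a$uz, a$R, a$L, a$entrance_len,
                    a$vs, a$gx, a$gy, a$tau_p, a$path_step, a$max_path,
                    a$dtheta_max, a$mode, as.integer(thin))
  rec <- res$record
  res$record <- records_from_matrix(matrix(rec, 1, 7,
                                           dimnames = list(NULL, names(rec))), 1L)
  res
}

#' Run a full perfusion seeding simulation
#'
#' Builds (or reuses) the flow field, injects `protocol$n_particles`
#' particles, integrates every trajectory, and tallies fates. This is the
#' package's top-level simulation entry point.
#'
#' @param geometry,operating,fluid,particles,protocol Configuration objects.
#' @param seed Integer seed for the particle injection.
#' @param field Optional precomputed `flow_field` (must match the
#'   configuration); avoids re-solving the swirl field across replicate runs.
#' @param mode Trajectory integrator, `"equilibrium"` (default) or `"full"`.
#' @param n_r,n_z Flow grid resolution when `field` is not supplied.
#' @param quiet Suppress the fate-tally log line.
#' @return Object of class `seeding_run`: list with `records` (one
#'   `deposition record` row per particle: id, fate, z, theta at contact,
#'   time, path length), `tally` (named counts trapped/escaped/incomplete),
#'   and the configuration (as attributes used by downstream analysis).
#' @export
run_seeding <- function(geometry = bioreactor_geometry(),
                        operating = operating_conditions(),
                        fluid = fluid_properties(),
                        particles = particle_properties(),
                        protocol = seeding_protocol(),
                        seed = 1, field = NULL,
                        mode = c("equilibrium", "full"),
                        n_r = 64, n_z = 128, quiet = FALSE) {
  mode <- match.arg(mode)
  if (is.null(field)) {
    field <- solve_swirl(geometry, operating, fluid, n_r = n_r, n_z = n_z)
  } else {
    stopifnot(inherits(field, "flow_field"))
    if (!identical(field$geometry$inlet_design, geometry$inlet_design) ||
        abs(field$operating$rpm - operating$rpm) > 1e-12 ||
        abs(field$operating$flow_rate - operating$flow_rate) > 1e-18) {
      stop("supplied field does not match the requested configuration", call. = FALSE)
    }
  }
  inj <- inject_particles(protocol$n_particles, geometry, protocol, seed)
  a <- tracking_args(field, particles, fluid, operating, protocol, mode)
  m <- .track_particles(cbind(inj$r0_m, inj$theta_deg * pi / 180, inj$slope),
                        a$rg, a$zg, a$W, a$uz, a$R, a$L, a$entrance_len,
                        a$vs, a$gx, a$gy, a$tau_p, a$path_step, a$max_path,
                        a$dtheta_max, a$mode)
  records <- records_from_matrix(m, inj$particle_id)
  tally <- c(trapped = sum(records$fate == "trapped"),
             escaped = sum(records$fate == "escaped"),
             incomplete = sum(records$fate == "incomplete"))
  stopifnot(sum(tally) == nrow(records))
  if (!quiet) {
    message(sprintf(
      "seeding run [%s, %g rpm, %.3g mL/min, seed %d]: trapped %d (%.1f%%), escaped %d, incomplete %d",
      geometry$inlet_design, operating$rpm, operating$flow_rate * 6e7, seed,
      tally["trapped"], 100 * tally["trapped"] / sum(tally),
      tally["escaped"], tally["incomplete"]))
  }
  structure(list(records = records, tally = tally,
                 geometry = geometry, operating = operating, fluid = fluid,
                 particles = particles, protocol = protocol, seed = seed,
                 mode = mode),
            class = "seeding_run")
}

#' @export
print.seeding_run <- function(x, ...) {
  cat(sprintf("<seeding_run> %s, %g rpm, seed %d: %d trapped / %d escaped / %d incomplete\n",
              x$geometry$inlet_design, x$operating$rpm, x$seed,
              x$tally["trapped"], x$tally["escaped"], x$tally["incomplete"]))
  invisible(x)
}
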