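test_that("axial profile is the Poiseuille parabola", {
  expect_equal(axial_profile(0), 2 * 2.5e-8 / (pi * 6.35e-3^2))  # 3.947e-4
  expect_equal(axial_profile(6.35e-3), 0)                        # no-slip
  expect_equal(axial_profile(seq(0, 6e-3, length.out = 5),
                             operating = operating_conditions(flow_rate = 0)),
               rep(0, 5))
  # flux closes: integral of u_z over the section equals Q
  r <- seq(0, 6.35e-3, length.out = 2001)
  q <- sum(axial_profile(r) * 2 * pi * r) * diff(r)[1]
  expect_equal(q, 2.5e-8, tolerance = 1e-5)
})

test_that("swirl solver boundary behaviour and asymptotics", {
  f0 <- ts_field("single_rotating", 0)
  expect_true(all(f0$w == 0))                       # no rotation -> no swirl
  expect_equal(f0$uz[length(f0$r)], 0)              # wall no-slip

  f5 <- ts_field("single_rotating", 5)
  expect_true(all(f5$w >= -1e-15))
  # wall BC: Omega*R on the scaffold span, 0 on the outlet anchor
  omR <- f5$operating$omega * 6.35e-3
  iw <- length(f5$r)
  expect_equal(unname(f5$w[iw, f5$z >= 0 & f5$z <= 0.05]),
               rep(omR, sum(f5$z >= 0 & f5$z <= 0.05)))
  expect_equal(unname(f5$w[iw, f5$z > 0.05]), rep(0, sum(f5$z > 0.05)))
  # solid-body asymptote: by mid-scaffold the swirl is rigid rotation
  idx <- f5$z >= 0.025 & f5$z <= 0.05
  dev <- max(abs(sweep(f5$w[, idx], 1, f5$operating$omega * f5$r, "-")))
  expect_lt(dev, 0.01 * omR)

  expect_error(solve_swirl(n_r = 16, n_z = 128), "at least")
  expect_error(solve_swirl(fluid = fluid_properties(viscosity = -1)), "> 0")
})

test_that("wall shear at 0 rpm equals the analytic Poiseuille value for any Q", {
  for (q_mlmin in c(1.5, 3, 6, 12)) {
    op <- operating_conditions(flow_rate = q_mlmin * 1e-6 / 60)
    ws <- wall_shear(solve_swirl(operating = op))
    analytic <- 4 * 1e-3 * op$flow_rate / (pi * 6.35e-3^3)
    expect_equal(unname(ws$summary["mean"]), analytic, tolerance = 5e-3)
    expect_equal(unname(ws$summary["max"]), unname(ws$summary["min"]),
                 tolerance = 1e-9)
  }
})

test_that("azimuthal traction vanishes for solid-body swirl, lab gradient is mu*Omega", {
  f5 <- ts_field("single_rotating", 5)
  ws <- wall_shear(f5)
  mid <- ws$profile$z_m >= 0.025 & ws$profile$z_m <= 0.05
  expect_lt(max(ws$profile$tau_azimuthal_traction_Pa[mid]),
            1e-3 * f5$operating$omega * 1e-3)
  expect_equal(ws$profile$tau_azimuthal_Pa[mid],
               rep(1e-3 * f5$operating$omega, sum(mid)), tolerance = 1e-6)
  # component bound
  expect_true(all(ws$profile$tau_mag_Pa + 1e-15 >=
                  pmax(ws$profile$tau_axial_Pa, ws$profile$tau_azimuthal_Pa)))
  # Q = 0, Omega = 0 -> all zeros
  w0 <- wall_shear(solve_swirl(operating = operating_conditions(flow_rate = 0)))
  expect_true(all(w0$profile$tau_mag_Pa == 0))
})

test_that("double-static design: strong swirl development at the scaffold inlet", {
  ws <- wall_shear(ts_field("double_static", 5))
  pr <- ws$profile
  first_in <- which(pr$z_m > 0)[1]
  near_out <- which.min(abs(pr$z_m - 0.9 * 0.05))
  expect_gte(pr$tau_azimuthal_traction_Pa[first_in],
             10 * max(pr$tau_azimuthal_traction_Pa[near_out], 1e-15))
  # the developing-boundary-layer peak exceeds the downstream plateau
  expect_gt(max(pr$tau_mag_Pa[pr$z_m > 0 & pr$z_m < 0.01]),
            1.5 * pr$tau_mag_Pa[near_out])
})

test_that("z-marching agrees with the independent global sparse solve", {
  g <- bioreactor_geometry(inlet_design = "double_static")
  op <- operating_conditions(rpm = 5)
  wm <- wall_shear(solve_swirl(g, op, n_r = 64, n_z = 128, method = "march"))$profile
  ws <- wall_shear(solve_swirl(g, op, n_r = 64, n_z = 128, method = "sparse"))$profile
  sel <- wm$z_m >= 0 & wm$z_m <= 0.05 & ws$tau_azimuthal_Pa > 1e-8
  rel <- abs(wm$tau_azimuthal_Pa[sel] - ws$tau_azimuthal_Pa[sel]) /
    ws$tau_azimuthal_Pa[sel]
  expect_lt(max(rel), 0.01)
})

test_that("slab-limit similarity: wall-driven swirl relaxes with the erfc profile", {
  nu <- 1e-6; U <- 0.01; Rbig <- 0.05
  r <- sort(unique(c(0, Rbig - rev(c(0, 10^seq(log10(1e-5), log10(Rbig * 0.9),
                                               length.out = 150))))))
  z <- seq(0, 0.05, length.out = 400)
  W <- tracheoseed:::swirl_march(r, z, rep(U, length(r)), rep(1, length(z)), nu)
  for (zq in c(0.02, 0.04)) {
    zi <- which.min(abs(z - zq))
    eta <- (Rbig - r) / (2 * sqrt(nu * z[zi] / U))
    exact <- 2 * stats::pnorm(-eta * sqrt(2))  # erfc(eta)
    expect_lt(max(abs(W[, zi] - exact)), 0.02)
  }
})

test_that("sweep table reproduces the reported monotone trends", {
  tab <- ts_memo("sweep_rpm", wss_summary_sweep("single_rotating", c(0, 1, 5, 15), 1.5))
  expect_equal(nrow(tab), 4)
  expect_true(all(diff(tab$tau_mean_Pa) > 0))  # mean WSS increasing in rpm

  tabq <- ts_memo("sweep_q", wss_summary_sweep("single_rotating", 5, c(1.5, 3, 6, 12)))
  expect_true(all(diff(tabq$tau_mean_Pa) > 0))
  # rotation dominates: relative span of the flow sweep is smaller than the
  # rpm sweep's at fixed flow
  span <- function(x) max(x) / min(x)
  expect_lt(span(tabq$tau_mean_Pa), span(tab$tau_mean_Pa[tab$rpm > 0]))

  # single inlet gives the more uniform shear profile over the scaffold span
  for (rpm in c(1, 5, 15)) {
    ps <- wall_shear(ts_field("single_rotating", rpm))$profile
    pd <- wall_shear(ts_field("double_static", rpm))$profile
    in_s <- ps$z_m >= 0 & ps$z_m <= 0.05
    in_d <- pd$z_m >= 0 & pd$z_m <= 0.05
    expect_lte(stats::var(ps$tau_mag_Pa[in_s]), stats::var(pd$tau_mag_Pa[in_d]))
  }
  expect_error(wss_summary_sweep(character(0), 1, 1.5), "non-empty")
})

test_that("grid convergence of the wall-shear summary (default design)", {
  for (rpm in c(0, 1, 5, 15)) {
    w1 <- wall_shear(solve_swirl(operating = operating_conditions(rpm = rpm),
                                 n_r = 64, n_z = 128))$summary
    w2 <- wall_shear(solve_swirl(operating = operating_conditions(rpm = rpm),
                                 n_r = 128, n_z = 256))$summary
    expect_lt(abs(w1["mean"] - w2["mean"]) / w2["mean"], 0.02)
    expect_lt(abs(w1["max"] - w2["max"]) / w2["max"], 0.10)
  }
})
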