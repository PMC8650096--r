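test_that("Kozeny-Carman permeability matches hand evaluation", {
  ## d^2 eps^3 / (180 (1-eps)^2) at eps = 0.5, d = 15 um
  expect_equal(permeability_from_porosity(0.5, 15), 6.25e-13,
               tolerance = 1e-12)
  k <- permeability_from_porosity(c(0.2, 0.5, 0.7, 0.9))
  expect_true(all(diff(k) > 0))
  expect_lt(permeability_from_porosity(1e-6), 1e-25)
  expect_error(permeability_from_porosity(0), "strictly")
  expect_error(permeability_from_porosity(1), "strictly")
})

test_that("duct flow matches the series solution", {
  grid <- make_duct_grid(width_um = 200, height_um = 100, length_um = 200,
                         spacing = 5)
  q_ml_h <- 0.01
  bc <- flow_bc(NA, q_ml_h)
  flow <- solve_flow(grid, fluid_properties(),
                     spheroid_properties(0.5), bc)
  h <- grid$spacing
  q_target <- ml_h_to_m3_s(q_ml_h)
  ## flow-rate recovery at an interior cross-section and at the outlet
  for (i in c(10, 20, 35, grid$shape[1] + 1)) {
    q_sec <- sum(flow$u[i, , ]) * h^2
    expect_lt(abs(q_sec - q_target) / q_target, 0.01)
  }
  ## velocity profile vs analytic series, midway down the duct
  ny <- grid$shape[2]; nz <- grid$shape[3]
  prof_num <- flow$u[30, , ]
  yrel <- (seq_len(ny) - 0.5) * h; zrel <- (seq_len(nz) - 0.5) * h
  prof_ref <- duct_profile(200e-6, 100e-6, yrel, zrel)
  prof_ref <- prof_ref * q_target / (sum(prof_ref) * h^2)
  expect_lt(max(abs(prof_num - prof_ref)) / max(prof_ref), 0.02)
  ## residual history dropped at least four orders
  expect_lt(utils::tail(flow$residual_history, 1), 1e-4)
})

test_that("zero inflow yields an identically zero field", {
  grid <- build_domain(dsc_design(), geometry_config(), 20)
  flow <- solve_flow(grid, fluid_properties(), spheroid_properties(0.5),
                     flow_bc(0, 0))
  expect_true(all(flow$u == 0) && all(flow$v == 0) && all(flow$w == 0))
  expect_true(all(flow$p[!is.na(flow$p)] == 0))
})

test_that("a uniform porous slab reproduces Darcy's pressure drop", {
  grid <- make_duct_grid(width_um = 100, height_um = 100, length_um = 400,
                         spacing = 10, porosity = 0.5,
                         slab_x = c(150, 250))
  sph <- spheroid_properties(0.5)
  flow <- solve_flow(grid, fluid_properties(), sph, flow_bc(NA, 0.01))
  u_darcy <- ml_h_to_m3_s(0.01) / (100e-6 * 100e-6)
  dp_ref <- 1e-3 * 100e-6 * u_darcy / sph$permeability
  p_up <- mean(flow$p[10, , ])    # x = 95 um
  p_dn <- mean(flow$p[31, , ])    # x = 305 um
  ## subtract the pure-duct drop over the same distance
  dp_duct <- duct_pressure_gradient(ml_h_to_m3_s(0.01), 100e-6, 100e-6,
                                    1e-3) * 110e-6
  dp_num <- (p_up - p_dn) - dp_duct
  expect_lt(abs(dp_num - dp_ref) / dp_ref, 0.05)
})

test_that("Stokes linearity: scaling the inflow scales the whole field", {
  d1 <- dsc_design(phi = 0.7)
  r1 <- coarse_flow(d1)
  d2 <- dsc_design(phi = 0.7, q1 = 0.02, q2 = 0.02)
  r2 <- coarse_flow(d2)
  expect_equal(r2$flow$u, 2 * r1$flow$u, tolerance = 1e-8)
  expect_equal(r2$flow$v, 2 * r1$flow$v, tolerance = 1e-8)
  pm <- !is.na(r1$flow$p)
  expect_equal(r2$flow$p[pm], 2 * r1$flow$p[pm], tolerance = 1e-8)
})

test_that("global mass balance closes and divergence is at tolerance", {
  r <- coarse_flow(dsc_design(phi = 0.9))
  expect_lt(abs(r$flow$q_in - r$flow$q_out) / r$flow$q_in, 0.005)
  expect_lt(max_divergence(r$flow), 1e-4)
  rs <- coarse_flow(ssc_design())
  expect_lt(abs(rs$flow$q_in - rs$flow$q_out) / rs$flow$q_in, 0.005)
})

test_that("symmetric design with co-current equal rates gives a mirror field", {
  r <- coarse_flow(dsc_design(phi = 0.5), arrangement = "co")
  cv <- cell_velocity(r$flow)
  ny <- r$grid$shape[2]
  expect_equal(cv$speed, cv$speed[, ny:1, ], tolerance = 1e-6)
})

test_that("shear rate recovers analytic fields", {
  grid <- make_duct_grid(100, 100, 100, spacing = 10)
  ## rigid fluid at rest
  expect_true(all(shear_rate_field(as_flow_field(grid)) == 0))
  ## plane Couette u = G z: constant shear everywhere
  G <- 50
  d <- grid$shape
  zc <- ((seq_len(d[3])) - 0.5) * grid$spacing
  u <- array(rep(G * zc, each = (d[1] + 1) * d[2]),
             c(d[1] + 1, d[2], d[3]))
  gam <- shear_rate_field(as_flow_field(grid, u = u))
  expect_equal(as.vector(gam), rep(G, length(gam)), tolerance = 1e-10)
  ## Poiseuille duct: wall-adjacent shear exceeds the centreline value
  flow <- solve_flow(make_duct_grid(200, 100, 100, spacing = 5),
                     fluid_properties(), spheroid_properties(0.5),
                     flow_bc(NA, 0.01))
  gam <- shear_rate_field(flow)
  mid <- dim(gam) %/% 2
  g_center <- gam[mid[1], mid[2], mid[3]]
  expect_gt(gam[mid[1], 2, mid[3]], 3 * g_center)
  expect_gt(gam[mid[1], mid[2], 2], 3 * g_center)
  expect_lt(g_center, 0.15 * max(gam))
})

test_that("the row ladder yields consistent cross-channel pressures", {
  geom <- geometry_config(); fl <- fluid_properties()
  dp60 <- row_cross_pressure(dsc_design(), geom, fl, flow_bc(0.01, 0.01))
  expect_gt(dp60, 0)
  ## linear in the flow rates
  dp2x <- row_cross_pressure(dsc_design(), geom, fl, flow_bc(0.02, 0.02))
  expect_equal(dp2x, 2 * dp60, tolerance = 1e-12)
  ## narrower connectors short-circuit the channels less
  d20 <- design_point(0.5, 120, wr = 20, hr = 20, wl = 20, hl = 20)
  expect_gt(row_cross_pressure(d20, geom, fl, flow_bc(0.01, 0.01)), dp60)
  ## no cross-flow possible for SSC or co-current cells
  expect_equal(row_cross_pressure(ssc_design(), geom, fl,
                                  flow_bc(NA, 0.01)), 0)
  expect_equal(row_cross_pressure(dsc_design(), geom, fl,
                                  flow_bc(0.01, 0.01, arrangement = "co")),
               0)
  ## explicit override wins
  expect_equal(row_cross_pressure(dsc_design(), geom, fl,
                                  flow_bc(0.01, 0.01,
                                          cross_pressure = 0.5)), 0.5)
})

test_that("boundary conditions respect the channel topology", {
  grid <- build_domain(ssc_design(), geometry_config(), 20)
  expect_error(solve_flow(grid, fluid_properties(),
                          spheroid_properties(0.5), flow_bc(0.01, 0.01)),
               "q1 must be absent")
  gridd <- build_domain(dsc_design(), geometry_config(), 20)
  expect_error(solve_flow(gridd, fluid_properties(),
                          spheroid_properties(0.5), flow_bc(NA, 0.01)),
               "requires a left channel")
})
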