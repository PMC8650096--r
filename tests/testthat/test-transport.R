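test_that("a quiescent closed domain holds its uniform concentration", {
  grid <- make_duct_grid(100, 100, 100, spacing = 10)
  flow <- as_flow_field(grid)        # zero velocity -> boundaries are walls
  hist <- solve_transport(grid, flow, transport_properties(), t_end = 100,
                          dt = 10, c0 = 3e-3)
  f <- checkpoint_field(hist, 100)
  expect_equal(as.vector(f[!is.na(f)]), rep(3e-3, sum(!is.na(f))),
               tolerance = 1e-12)
  expect_lt(mass_balance_report(hist), 1e-10)
})

test_that("diffusion into a sphere follows the analytic series", {
  grid <- make_sphere_grid(radius_um = 50, box_um = 140, spacing = 5,
                           porosity = 0.5)
  props <- transport_properties()
  d_eff <- effective_diffusivity(props, 0.5)
  ## effective sphere radius from the voxelized volume
  a_eff <- (3 * region_measure(grid, "SPHEROID") / (4 * pi))^(1 / 3)
  t_ref <- a_eff^2 / d_eff
  c0 <- props$inlet_concentration
  fo <- c(0.1, 0.3, 1)
  hist <- solve_transport(grid, as_flow_field(grid), props,
                          t_end = max(fo) * t_ref, dt = t_ref / 100,
                          checkpoints = fo * t_ref,
                          probes = list(core = rep(70, 3)),
                          dirichlet = list(mask = grid$labels ==
                                             REGIONS[["WELL"]],
                                           value = c0))
  for (f in fo) {
    num <- checkpoint_field(hist, f * t_ref)
    core <- num[grid$shape[1] %/% 2, grid$shape[2] %/% 2,
                grid$shape[3] %/% 2]
    ref <- c0 * sphere_center_concentration(f)
    expect_lt(abs(core - ref) / c0, 0.03)
  }
  ## at t = a^2/D_eff the center has essentially equilibrated
  expect_lt(abs(checkpoint_field(hist, t_ref)[14, 14, 14] / c0 - 1), 0.03)
})

test_that("an advected front travels at the plug speed", {
  grid <- make_duct_grid(width_um = 50, height_um = 50, length_um = 400,
                         spacing = 5)
  U <- 1e-4
  flow <- as_flow_field(grid, u = U)
  props <- transport_properties(diffusivity = 1e-13)
  dt <- 0.025                       # CFL 0.5
  hist <- solve_transport(grid, flow, props, t_end = 100 * dt, dt = dt,
                          checkpoints = 100 * dt)
  cline <- checkpoint_field(hist, 100 * dt)[, 5, 5]
  x_front <- (which(cline < 0.5 * props$inlet_concentration)[1] - 1) *
    grid$spacing
  expect_lt(abs(x_front - U * 100 * dt), grid$spacing + 1e-12)
})

test_that("flux fields recover analytic gradients", {
  grid <- make_duct_grid(100, 100, 200, spacing = 10)
  props <- transport_properties()
  d <- grid$shape
  ## uniform concentration: zero diffusive flux
  fl <- flux_fields(array(5e-3, d), as_flow_field(grid, u = 1e-4), props)
  expect_true(all(fl$dif_mag == 0))
  expect_true(all(fl$adv_mag > 0))
  ## zero velocity: zero advective flux
  fl0 <- flux_fields(array(5e-3, d), as_flow_field(grid), props)
  expect_true(all(fl0$adv_mag == 0))
  ## 1-D linear profile c = c0 x / L: |J| = D c0 / L everywhere
  c0 <- 1e-2; L <- 200e-6
  xc <- (seq_len(d[1]) - 0.5) * grid$spacing
  conc <- array(rep(c0 * xc / L, times = d[2] * d[3]), d)
  fl1 <- flux_fields(conc, as_flow_field(grid), props)
  expect_equal(as.vector(fl1$dif_mag),
               rep(props$diffusivity * c0 / L, prod(d)), tolerance = 1e-10)
  ## diffusive flux points against the gradient
  expect_true(all(fl1$dif_x < 0))
})

test_that("transport runs close the global mass balance", {
  r <- coarse_flow(dsc_design(phi = 0.5))
  props <- transport_properties()
  h1 <- solve_transport(r$grid, r$flow, props, t_end = 600, dt = 60)
  expect_lt(mass_balance_report(h1), 0.005)
  h2 <- solve_transport(r$grid, r$flow, props, t_end = 600, dt = 30)
  expect_lt(mass_balance_report(h2), 0.005)
})

test_that("concentrations respect the discrete maximum principle", {
  r <- coarse_flow(dsc_design(phi = 0.9))
  props <- transport_properties()
  hist <- solve_transport(r$grid, r$flow, props, t_end = 1800, dt = 60,
                          checkpoints = c(600, 1800))
  cin <- props$inlet_concentration
  for (t in c(600, 1800)) {
    f <- checkpoint_field(hist, t)
    ## bounded by the boundary data up to sparse-LU round-off
    expect_gte(min(f, na.rm = TRUE), -cin * 1e-5)
    expect_lte(max(f, na.rm = TRUE), cin * (1 + 1e-5))
  }
})

test_that("the spheroid-core trace is monotone under perfusion", {
  rec <- simulate_design(ssc_design(phi = 0.6), spacing = 20,
                         t_end = 1800, dt = 60)
  core <- rec$probe_traces$core
  expect_true(all(diff(core) >= -1e-15))
  expect_gt(utils::tail(core, 1), 0)
})

test_that("long-time perfusion saturates open regions at the inlet level", {
  r <- coarse_flow(ssc_design(phi = 0.9))
  props <- transport_properties()
  hist <- solve_transport(r$grid, r$flow, props, t_end = 7200, dt = 240)
  f <- checkpoint_field(hist, 7200)
  for (reg in c("CHANNEL_R", "WELL", "SPHEROID")) {
    cz <- f; cz[is.na(cz)] <- 0
    expect_gt(volume_average(cz, r$grid, reg),
              0.95 * props$inlet_concentration)
  }
})
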