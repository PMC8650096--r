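test_that("volume averages match direct summation", {
  gd <- build_domain(dsc_design(radius = 80), geometry_config(), 10)
  d <- gd$shape
  expect_equal(volume_average(array(4.2, d), gd, "SPHEROID"), 4.2)
  ## field = z over the spheroid (symmetric about the well mid-height)
  zc <- (seq_len(d[3]) - 0.5) * gd$spacing
  fz <- array(rep(zc, each = d[1] * d[2]), d)
  expect_lt(abs(volume_average(fz, gd, "SPHEROID") - 50e-6),
            gd$spacing / 2)
  ## brute-force oracle on a random field
  set.seed(42)
  f <- array(stats::runif(prod(d)), d)
  m <- gd$labels == REGIONS[["WELL"]]
  expect_equal(volume_average(f, gd, "WELL"),
               sum(f[m] * gd$spacing^3) / (sum(m) * gd$spacing^3))
  expect_error(volume_average(f, gd, "BOGUS"), "unknown region")
  expect_error(volume_average(f[, , 1], gd, "WELL"), "congruent")
})

test_that("metric extraction isolates transport modes", {
  ## pure-diffusion configuration: sphere fed by a clamped bath
  grid <- make_sphere_grid(50, 140, 10, porosity = 0.5)
  props <- transport_properties()
  flow <- as_flow_field(grid)
  hist <- solve_transport(grid, flow, props, t_end = 10, dt = 1,
                          dirichlet = list(mask = grid$labels ==
                                             REGIONS[["WELL"]],
                                           value = 1e-2))
  met <- compute_metrics(flow, hist, 10)
  expect_equal(met[["velocity"]], 0)
  expect_equal(met[["shear_rate"]], 0)
  expect_equal(met[["advective_flux"]], 0)
  expect_gt(met[["concentration"]], 0)
  expect_gt(met[["diffusive_flux"]], 0)
  expect_identical(classify_transport_mode(met), "DIFFUSION_DOMINANT")

  ## zero-flow, zero-drug: all metrics vanish
  hist0 <- solve_transport(grid, flow, transport_properties(
    inlet_concentration = 0), t_end = 10, dt = 5)
  met0 <- compute_metrics(flow, hist0, 10)
  expect_true(all(unclass(met0) == 0))
  expect_error(classify_transport_mode(met0), "undefined")
})

test_that("doubling the inflow doubles the flow metrics", {
  r1 <- coarse_flow(dsc_design(phi = 0.7))
  r2 <- coarse_flow(dsc_design(phi = 0.7, q1 = 0.02, q2 = 0.02))
  v1 <- volume_average(cell_velocity(r1$flow)$speed, r1$grid, "SPHEROID")
  v2 <- volume_average(cell_velocity(r2$flow)$speed, r2$grid, "SPHEROID")
  s1 <- volume_average(shear_rate_field(r1$flow), r1$grid, "SPHEROID")
  s2 <- volume_average(shear_rate_field(r2$flow), r2$grid, "SPHEROID")
  expect_equal(v2, 2 * v1, tolerance = 1e-8)
  expect_equal(s2, 2 * s1, tolerance = 1e-8)
})

test_that("the dominance rule classifies reference flux ratios", {
  mk <- function(adv, dif) c(advective_flux = adv, diffusive_flux = dif)
  expect_identical(classify_transport_mode(mk(23, 1)), "ADVECTION_DOMINANT")
  expect_identical(classify_transport_mode(mk(1, 2.3)), "MIXED")
  expect_identical(classify_transport_mode(mk(10, 1)), "ADVECTION_DOMINANT")
  expect_identical(classify_transport_mode(mk(1, 10)), "DIFFUSION_DOMINANT")
  expect_identical(classify_transport_mode(mk(9.99, 1)), "MIXED")
  expect_identical(classify_transport_mode(mk(0, 1)), "DIFFUSION_DOMINANT")
})

test_that("min-max normalization maps columns onto [0, 1]", {
  expect_equal(as.vector(minmax_normalize(matrix(c(1, 3, 5)))),
               c(0, 0.5, 1))
  expect_equal(as.vector(minmax_normalize(matrix(c(7, 7)))), c(0, 0))
  set.seed(1)
  m <- matrix(stats::rnorm(40), 8, 5)
  n1 <- minmax_normalize(m)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_true(all(apply(n1, 2, min) == 0) && all(apply(n1, 2, max) == 1))
  expect_equal(minmax_normalize(n1), n1)   # idempotent on normalized data
})

test_that("complete-linkage clustering matches a brute-force oracle", {
  ## two identical rows merge at height zero
  two <- matrix(c(1, 2, 3, 1, 2, 3), 2, byrow = TRUE)
  expect_equal(cluster_designs(two)$height, 0)
  ## hand-computed 1-D case {0, 1, 10}
  tr <- cluster_designs(matrix(c(0, 1, 10)))
  expect_equal(tr$height, c(1, 10))
  expect_identical(sort(tr$merge[1, ]), c(-2L, -1L))
  ## random matrices vs O(n^3) oracle
  set.seed(99)
  for (i in 1:20) {
    m <- matrix(stats::runif(40), 8, 5)
    expect_equal(cluster_designs(m)$height, complete_linkage_oracle(m),
                 tolerance = 1e-12)
  }
  expect_error(cluster_designs(matrix(1, 1, 5)), "at least 2")
})

test_that("heatmap export writes clustered, bit-exact artifacts", {
  set.seed(3)
  raw <- matrix(stats::runif(60, 1, 9), 12, 5,
                dimnames = list(sprintf("D%02d", 1:12), METRIC_NAMES))
  dm <- design_matrix(raw, evaluation_time = 7200, scenario = "equal")
  tree <- cluster_designs(dm)
  prefix <- file.path(tempfile("hm"), "run")
  paths <- heatmap_export(dm, tree, prefix, cell_px = 6)
  mat <- utils::read.csv(paths[["matrix"]], stringsAsFactors = FALSE)
  expect_identical(mat$name, rownames(dm$normalized)[tree$order])
  back <- as.matrix(mat[, METRIC_NAMES])
  expect_identical(as.vector(back),
                   as.vector(dm$normalized[tree$order, ]))
  mrg <- utils::read.csv(paths[["merges"]])
  expect_equal(mrg$height, tree$height)
  expect_equal(mrg$size[nrow(mrg)], 12)
  img <- png::readPNG(paths[["heatmap"]])
  expect_equal(dim(img)[1:2], c(12 * 6, 5 * 6))
})

test_that("design queries find geometries switched by flow ratio alone", {
  base <- matrix(1, 4, 5, dimnames = list(paste0("G", 1:4), METRIC_NAMES))
  un <- base
  un["G2", "shear_rate"] <- 3       # planted: shear x3, others unchanged
  un["G3", ] <- 3                   # everything changes
  expect_identical(design_query(base, un, "shear_rate", 2, 1.1), "G2")
  expect_identical(design_query(base, un, "shear_rate", Inf, 1.1),
                   character(0))
  ## loosening the tolerance can only grow the result set
  r1 <- design_query(base, un, "shear_rate", 2, 1.05)
  r2 <- design_query(base, un, "shear_rate", 2, 5)
  expect_true(all(r1 %in% r2))
  expect_true("G3" %in% r2)
})
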