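## Shared fixtures: small factor tables and coarse designs that keep the
## suite fast while exercising every code path.

## report every expectation: some end-to-end reproduction checks are known
## to fail under the reconstructed geometry and must not mask later tests
options(testthat.progress.max_fails = 500)

## two-level factor table (SSC + DSC, two porosities); 60 um connectors so a
## 20 um grid resolves them
tiny_factors <- function() {
  factor_table(q1 = c(0.01, 0.02), q2 = 0.01, wl = c(0.1, 60), wr = 60,
               hl = 60, hr = 60, radius = 80, phi = c(0.2, 0.9))
}

## reference DSC design (all connectors 60 um)
dsc_design <- function(phi = 0.5, radius = 120, q1 = 0.01, q2 = 0.01) {
  design_point(phi = phi, radius = radius, wr = 60, hr = 60, wl = 60,
               hl = 60, q1 = q1, q2 = q2)
}

## matched SSC design (left connector closed)
ssc_design <- function(phi = 0.5, radius = 120, q2 = 0.01) {
  design_point(phi = phi, radius = radius, wr = 60, hr = 60, wl = 0.1,
               hl = 0.1, q1 = 0, q2 = q2)
}

## quick coarse flow solve for a design
coarse_flow <- function(design, spacing = 20, arrangement = "counter") {
  grid <- build_domain(design, geometry_config(), spacing)
  sph <- spheroid_properties(design$phi)
  q1 <- if (design$topology == "SSC") NA_real_ else design$q1_ml_h
  bc <- flow_bc(q1, design$q2_ml_h, arrangement = arrangement)
  list(grid = grid,
       flow = solve_flow(grid, fluid_properties(), sph, bc))
}

## brute-force complete-linkage agglomerative clustering (O(n^3) oracle)
complete_linkage_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in seq((i + 1), m)) {
      dij <- max(d[clusters[[i]], clusters[[j]]])
      if (dij < best[1]) best <- c(dij, i, j)
    }
    heights[s] <- best[1]
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}
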