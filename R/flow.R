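## Steady Stokes-Brinkman flow through the unit cell on a staggered
## (MAC) finite-volume grid.

#' Convert a flow rate from ml/h to m^3/s
#'
#' @param q flow rate in ml/h (0.01 ml/h = 2.7778e-12 m^3/s).
#' @return Flow rate in m^3/s.
#' @export
ml_h_to_m3_s <- function(q) q * 1e-6 / 3600

#' Fluid properties
#'
#' Aqueous cell-culture medium defaults. The body force is identically zero
#' (no gravity or external fields).
#'
#' @param density fluid density (kg/m^3).
#' @param viscosity dynamic viscosity (Pa s).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1000, viscosity = 1e-3) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity, body_force = 0),
            class = "fluid_properties")
}

#' Spheroid permeability from porosity (Kozeny-Carman)
#'
#' kappa = d_g^2 * eps^3 / (180 * (1 - eps)^2), with d_g the cell grain
#' diameter. Strictly increasing in porosity and positive on (0, 1).
#'
#' @param porosity void fraction in (0, 1).
#' @param grain_diameter_um cell grain diameter (um); 15 um is a typical
#'   epithelial cell size.
#' @return Permeability in m^2.
#' @export
permeability_from_porosity <- function(porosity, grain_diameter_um = 15) {
  if (any(porosity <= 0) || any(porosity >= 1))
    stop("porosity must lie strictly in (0, 1)")
  stopifnot(grain_diameter_um > 0)
  d <- grain_diameter_um * 1e-6
  d^2 * porosity^3 / (180 * (1 - porosity)^2)
}

#' Porous-spheroid material properties
#'
#' The spheroid is a permeable (Darcy/Brinkman) obstacle. Its permeability is
#' derived from porosity by [permeability_from_porosity()] unless given
#' explicitly. The internal mass source is identically zero.
#'
#' @param porosity void fraction in (0, 1).
#' @param grain_diameter_um cell grain diameter for the permeability law (um).
#' @param permeability optional explicit permeability (m^2), overriding the
#'   Kozeny-Carman value.
#' @return An object of class `spheroid_properties`.
#' @export
spheroid_properties <- function(porosity, grain_diameter_um = 15,
                                permeability = NULL) {
  if (is.null(permeability))
    permeability <- permeability_from_porosity(porosity, grain_diameter_um)
  stopifnot(permeability > 0)
  structure(list(porosity = porosity, grain_diameter_um = grain_diameter_um,
                 permeability = permeability, mass_source = 0),
            class = "spheroid_properties")
}

#' Flow boundary conditions for the unit cell
#'
#' Each supply channel carries a prescribed flow rate through a fully
#' developed rectangular-duct inlet profile; walls are no-slip; outlets are at
#' a reference pressure. The unit cell represents one well of an
#' `n_wells_row`-well serpentine supply row; under the default
#' counter-current arrangement the two channels of a DSC design flow in
#' opposite directions and the cross-channel pressure difference seen by the
#' well depends on its position along the row (`row_fraction`, measured from
#' the left channel's inlet). That cross-pressure, computed from the chained
#' duct pressure drops of the row, is applied as the left channel's outlet
#' reference pressure and is what drives through-flow across the well. Set
#' `arrangement = "co"` for co-current channels (both outlets at the same
#' reference; a symmetric design then has zero cross-flow), or supply
#' `cross_pressure` to impose the offset directly.
#'
#' @param q1_ml_h,q2_ml_h left and right supply flow rates (ml/h). For SSC
#'   designs (no left channel) `q1_ml_h` must be `NA` or 0.
#' @param arrangement `"counter"` (default) or `"co"` channel flow directions.
#' @param row_fraction well position along the supply row in (0, 1).
#' @param cross_pressure optional explicit cross-channel pressure offset (Pa)
#'   overriding the row model.
#' @param outlet_pressure reference pressure at the right channel outlet (Pa).
#' @return An object of class `flow_bc`.
#' @export
flow_bc <- function(q1_ml_h, q2_ml_h, arrangement = c("counter", "co"),
                    row_fraction = NULL, cross_pressure = NULL,
                    outlet_pressure = 0) {
  arrangement <- match.arg(arrangement)
  if (!is.na(q1_ml_h)) stopifnot(q1_ml_h >= 0)
  stopifnot(q2_ml_h >= 0)
  if (!is.null(row_fraction))
    stopifnot(row_fraction > 0, row_fraction < 1)
  structure(list(q1 = if (is.na(q1_ml_h)) NA_real_ else ml_h_to_m3_s(q1_ml_h),
                 q2 = ml_h_to_m3_s(q2_ml_h),
                 q1_ml_h = q1_ml_h, q2_ml_h = q2_ml_h,
                 arrangement = arrangement, row_fraction = row_fraction,
                 cross_pressure = cross_pressure,
                 outlet_pressure = outlet_pressure, wall = "no-slip"),
            class = "flow_bc")
}

#' Fully developed rectangular-duct velocity profile
#'
#' Classical Fourier-series solution for pressure-driven laminar flow in a
#' rectangular duct, evaluated at points `(y, z)` of the cross-section
#' (origin at the duct corner). Returned values are proportional to the axial
#' velocity; scale them to a target flow rate or centreline speed as needed.
#'
#' @param width,height duct cross-section dimensions (same length unit as
#'   `y`, `z`).
#' @param y,z coordinates within `[0, width] x [0, height]`.
#' @param nterms number of odd series terms.
#' @return Numeric array of relative axial velocities (outer product over
#'   `y` and `z` when both are vectors).
#' @export
duct_profile <- function(width, height, y, z, nterms = 60) {
  ## half-dimensions: cos-series along the height, cosh along the width
  a <- height / 2; b <- width / 2
  yy <- y - b; zz <- z - a
  out <- matrix(0, length(y), length(z))
  for (m in seq_len(nterms)) {
    n <- 2 * m - 1
    k <- n * pi / (2 * a)
    ## cosh(k yy)/cosh(k b) computed via exponentials to avoid overflow
    ratio <- outer(exp(k * (abs(yy) - b)) * (1 + exp(-2 * k * abs(yy))) /
                     (1 + exp(-2 * k * b)), rep(1, length(z)))
    term <- (-1)^((n - 1) / 2) / n^3 * (1 - ratio) *
      outer(rep(1, length(y)), cos(k * zz))
    out <- out + term
  }
  out
}

#' Pressure gradient sustaining a given duct flow rate
#'
#' Series solution for the flow rate of a rectangular duct, inverted for the
#' axial pressure gradient magnitude. Used by the serpentine-row pressure
#' model and by the Darcy/duct validation oracles.
#'
#' @param q flow rate (m^3/s).
#' @param width,height duct cross-section (m).
#' @param viscosity dynamic viscosity (Pa s).
#' @param nterms number of odd series terms.
#' @return Pressure gradient -dp/dx (Pa/m).
#' @export
duct_pressure_gradient <- function(q, width, height, viscosity = 1e-3,
                                   nterms = 60) {
  n <- 2 * seq_len(nterms) - 1
  corr <- 1 - (192 * height) / (pi^5 * width) *
    sum(tanh(n * pi * width / (2 * height)) / n^5)
  q * 12 * viscosity / (width * height^3 * corr)
}

## Hydraulic resistance (Pa s / m^3) of one rectangular duct
duct_resistance <- function(width_m, height_m, length_m, viscosity) {
  duct_pressure_gradient(1, max(width_m, height_m), min(width_m, height_m),
                         viscosity) * length_m
}

#' Cross-channel pressure offset from the serpentine-row network
#'
#' The unit cell represents one of `n_wells_row` wells chained along a
#' counter-current pair of supply channels. By Stokes linearity the row is a
#' resistor ladder: channel segments of one unit-cell pitch between well
#' nodes, and one cross-well resistor (the two connectors in series, plus
#' the well cavity) bridging the channels at every node. Solving the ladder
#' gives the channel pressure profiles, including the short-circuiting of
#' the channels through the wells, and hence the cross-channel pressure
#' difference seen by every well. That difference is what drives
#' through-flow across a well. By default the unit cell represents the
#' average well of the row: the row mean of the absolute cross-pressures
#' (the signed value vanishes by antisymmetry for the exact mid-row well
#' under equal rates, so no single position is representative). Set
#' `row_fraction` in the boundary conditions to model a specific well
#' position instead.
#'
#' @param design one-row `design_table` (provides the connector dimensions).
#' @param geom a [geometry_config()].
#' @param fluid a [fluid_properties()].
#' @param bc a [flow_bc()].
#' @return Cross-channel pressure difference p_left - p_right (Pa) at the
#'   representative well.
#' @export
row_cross_pressure <- function(design, geom, fluid, bc) {
  if (!is.null(bc$cross_pressure)) return(bc$cross_pressure)
  if (bc$arrangement != "counter" || is.na(bc$q1) ||
      design$topology[1] == "SSC") return(0)
  mu <- fluid$viscosity
  w <- geom$channel_width * 1e-6; h <- geom$channel_height * 1e-6
  pitch <- geom$unit_cell_pitch * 1e-6
  rc <- duct_resistance(w, h, pitch, mu)
  lc <- geom$connector_length * 1e-6
  rw <- duct_resistance(design$wl_um[1] * 1e-6, design$hl_um[1] * 1e-6,
                        lc, mu) +
    duct_resistance(design$wr_um[1] * 1e-6, design$hr_um[1] * 1e-6, lc, mu) +
    duct_resistance(2 * design$radius_um[1] * 1e-6,
                    geom$well_depth * 1e-6,
                    2 * design$radius_um[1] * 1e-6, mu)
  N <- as.integer(geom$n_wells_row)
  if (N < 2) return(0)
  ## ladder: left nodes 1..N (inlet source at 1, outlet via rc/2 after N),
  ## right nodes N+1..2N counter-current (source at 2N, outlet after N+1)
  n <- 2L * N
  G <- matrix(0, n, n)
  addc <- function(i, j, g) {
    G[i, i] <<- G[i, i] + g
    if (j > 0) {
      G[j, j] <<- G[j, j] + g
      G[i, j] <<- G[i, j] - g; G[j, i] <<- G[j, i] - g
    }
  }
  gs <- 1 / rc; gw <- 1 / rw
  for (i in seq_len(N - 1)) {
    addc(i, i + 1L, gs); addc(N + i, N + i + 1L, gs)
  }
  for (i in seq_len(N)) addc(i, N + i, gw)
  addc(N, 0L, 2 * gs)
  addc(N + 1L, 0L, 2 * gs)
  b <- numeric(n); b[1] <- bc$q1; b[n] <- bc$q2
  p <- solve(G, b)
  dp <- p[1:N] - p[(N + 1):n]
  if (is.null(bc$row_fraction)) return(mean(abs(dp)))
  iw <- max(1L, min(N, as.integer(round(bc$row_fraction * N))))
  dp[iw]
}

## 3D array shift with fill
shift3 <- function(a, di, dj, dk, fill) {
  d <- dim(a); out <- array(fill, d)
  si <- seq_len(d[1]) - di; sj <- seq_len(d[2]) - dj; sk <- seq_len(d[3]) - dk
  oki <- si >= 1 & si <= d[1]; okj <- sj >= 1 & sj <= d[2]
  okk <- sk >= 1 & sk <= d[3]
  out[oki, okj, okk] <- a[si[oki], sj[okj], sk[okk]]
  out
}

#' Solve steady Stokes-Brinkman flow through the unit cell
#'
#' Steady incompressible creeping flow on a staggered (MAC) finite-volume
#' grid: viscous momentum balance in open regions, an added Brinkman drag
#' mu/kappa * u inside the spheroid, no-slip walls, fully developed duct
#' profiles at the channel inlets and reference pressures at the outlets.
#' Inertia is dropped (Re ~ 1e-2 at these scales), which makes the problem
#' linear; the linearity is exploited by the design sweep and verified by the
#' test suite.
#'
#' The saddle-point system is solved by augmented-Lagrangian Uzawa iteration:
#' the grad-div-augmented momentum block is factorized once (sparse
#' Cholesky), then pressure updates contract the continuity residual by
#' several orders of magnitude per iteration. Iterations stop when the
#' relative residual has dropped by at least `-log10(tol)` orders.
#'
#' @param grid a [build_domain()] grid.
#' @param fluid a [fluid_properties()].
#' @param sph a [spheroid_properties()] (matching the design's porosity).
#' @param bc a [flow_bc()].
#' @param tol relative residual-drop tolerance.
#' @param maxit iteration cap.
#' @param gamma0 dimensionless augmentation factor.
#' @return An object of class `flow_field`: staggered face velocities `u`,
#'   `v`, `w` (m/s), cell pressures `p` (Pa, `NA` in solid), the residual
#'   history, mass-balance audit (`q_in`, `q_out`, m^3/s) and a reference to
#'   the grid.
#' @export
solve_flow <- function(grid, fluid, sph, bc, tol = 1e-4, maxit = 50,
                       gamma0 = 1e6) {
  lab <- grid$labels; d <- dim(lab); nx <- d[1]; ny <- d[2]; nz <- d[3]
  h <- grid$spacing; mu <- fluid$viscosity
  open <- lab != REGIONS[["SOLID"]]
  has_left <- any(lab == REGIONS[["CHANNEL_L"]])
  if (!has_left && !is.na(bc$q1) && bc$q1 > 0)
    stop("SSC topology: the left channel does not exist, q1 must be absent")
  if (has_left && is.na(bc$q1))
    stop("DSC topology requires a left channel flow rate q1")

  drag <- array(0, d)
  drag[lab == REGIONS[["SPHEROID"]]] <- mu / sph$permeability

  ## ---- face status: 1 unknown, 2 prescribed (inlet), 0 zero (wall) ----
  ustat <- array(0L, c(nx + 1, ny, nz))
  uA <- array(FALSE, dim(ustat)); uA[2:(nx + 1), , ] <- open
  uB <- array(FALSE, dim(ustat)); uB[1:nx, , ] <- open
  ustat[uA & uB] <- 1L
  uval <- array(0, dim(ustat))
  pghost <- array(0, dim(ustat))   # outlet ghost pressures (east/west bdry)

  ## per-channel boundary conditions
  p_off_left <- row_cross_pressure(grid$design, grid$geom, fluid, bc) +
    bc$outlet_pressure
  chans <- list()
  if (has_left)
    chans$L <- list(code = REGIONS[["CHANNEL_L"]], q = bc$q1,
                    inlet_low = TRUE, p_out = p_off_left)
  chans$R <- list(code = REGIONS[["CHANNEL_R"]], q = bc$q2,
                  inlet_low = !(bc$arrangement == "counter" && has_left),
                  p_out = bc$outlet_pressure)
  axes <- grid_axes(grid)
  any_inlet <- FALSE
  for (ch in chans) {
    m_lo <- lab[1, , ] == ch$code      # boundary cells at x = 0
    m_hi <- lab[nx, , ] == ch$code     # boundary cells at x = Lx
    if (!any(m_lo) || !any(m_hi))
      stop("topology error: channel does not span the unit cell; no open ",
           "path from inlet to outlet")
    ## duct profile over the channel rectangle, scaled to the flow rate
    ys <- range(which(apply(m_lo, 1, any))); zs <- range(which(apply(m_lo, 2, any)))
    wd <- (ys[2] - ys[1] + 1) * h; ht <- (zs[2] - zs[1] + 1) * h
    yrel <- (seq(ys[1], ys[2]) - ys[1] + 0.5) * h
    zrel <- (seq(zs[1], zs[2]) - zs[1] + 0.5) * h
    prof <- duct_profile(wd, ht, yrel, zrel)
    full <- array(0, c(ny, nz))
    full[ys[1]:ys[2], zs[1]:zs[2]] <- prof
    full[!m_lo] <- 0
    if (ch$q > 0) { full <- full * ch$q / (sum(full) * h^2); any_inlet <- TRUE }
    else full[] <- 0
    if (ch$inlet_low) {
      sl <- ustat[1, , ]; sl[m_lo] <- 2L; ustat[1, , ] <- sl
      vv <- uval[1, , ]; vv[m_lo] <- full[m_lo]; uval[1, , ] <- vv
      sl <- ustat[nx + 1, , ]; sl[m_hi] <- 1L; ustat[nx + 1, , ] <- sl
      pg <- pghost[nx + 1, , ]; pg[m_hi] <- ch$p_out; pghost[nx + 1, , ] <- pg
    } else {
      sl <- ustat[nx + 1, , ]; sl[m_hi] <- 2L; ustat[nx + 1, , ] <- sl
      vv <- uval[nx + 1, , ]; vv[m_hi] <- -full[m_hi]; uval[nx + 1, , ] <- vv
      sl <- ustat[1, , ]; sl[m_lo] <- 1L; ustat[1, , ] <- sl
      pg <- pghost[1, , ]; pg[m_lo] <- ch$p_out; pghost[1, , ] <- pg
    }
  }

  vstat <- array(0L, c(nx, ny + 1, nz))
  vA <- array(FALSE, dim(vstat)); vA[, 2:(ny + 1), ] <- open
  vB <- array(FALSE, dim(vstat)); vB[, 1:ny, ] <- open
  vstat[vA & vB] <- 1L
  wstat <- array(0L, c(nx, ny, nz + 1))
  wA <- array(FALSE, dim(wstat)); wA[, , 2:(nz + 1)] <- open
  wB <- array(FALSE, dim(wstat)); wB[, , 1:nz] <- open
  wstat[wA & wB] <- 1L

  uid <- array(0L, dim(ustat)); nU <- sum(ustat == 1L)
  uid[ustat == 1L] <- seq_len(nU)
  vid <- array(0L, dim(vstat)); nV <- sum(vstat == 1L)
  vid[vstat == 1L] <- nU + seq_len(nV)
  wid <- array(0L, dim(wstat)); nW <- sum(wstat == 1L)
  wid[wstat == 1L] <- nU + nV + seq_len(nW)
  pid <- array(0L, d); nP <- sum(open); pid[open] <- seq_len(nP)
  nF <- nU + nV + nW

  mh2 <- mu / h^2
  facedrag <- function(dd, axis) {
    tA <- array(0, dd); tB <- array(0, dd)
    if (axis == 1) { tA[2:dd[1], , ] <- drag; tB[1:(dd[1] - 1), , ] <- drag }
    if (axis == 2) { tA[, 2:dd[2], ] <- drag; tB[, 1:(dd[2] - 1), ] <- drag }
    if (axis == 3) { tA[, , 2:dd[3]] <- drag; tB[, , 1:(dd[3] - 1)] <- drag }
    (tA + tB) / 2
  }

  AI <- vector("list", 64); AJ <- vector("list", 64); AX <- vector("list", 64)
  na <- 0L
  adda <- function(i, j, x) {
    na <<- na + 1L; AI[[na]] <<- i; AJ[[na]] <<- j; AX[[na]] <<- x
  }
  ba <- numeric(nF)

  ## momentum rows for one face family; viscous 7-point Laplacian with
  ## no-slip walls via ghost reflection (tangential) / zero face (normal)
  assemble_momentum <- function(stat, idarr, valarr, fdr, pg, axis) {
    dd <- dim(stat)
    cA <- array(FALSE, dd); cB <- array(FALSE, dd)
    if (axis == 1) { cA[2:dd[1], , ] <- open; cB[1:(dd[1] - 1), , ] <- open }
    if (axis == 2) { cA[, 2:dd[2], ] <- open; cB[, 1:(dd[2] - 1), ] <- open }
    if (axis == 3) { cA[, , 2:dd[3]] <- open; cB[, , 1:(dd[3] - 1)] <- open }
    unk <- which(stat == 1L)
    if (!length(unk)) return(invisible(NULL))
    ind <- arrayInd(unk, dd); rows <- idarr[unk]
    ctr <- numeric(length(unk)); r <- numeric(length(unk))
    for (dir in 1:3) for (s in c(-1L, 1L)) {
      nb <- ind; nb[, dir] <- nb[, dir] + s
      inside <- nb[, dir] >= 1 & nb[, dir] <= dd[dir]
      nlin <- (pmin(pmax(nb[, 3], 1), dd[3]) - 1) * dd[1] * dd[2] +
        (pmin(pmax(nb[, 2], 1), dd[2]) - 1) * dd[1] +
        pmin(pmax(nb[, 1], 1), dd[1])
      nst <- ifelse(inside, stat[nlin], -1L)
      isu <- which(nst == 1L)
      if (length(isu)) {
        adda(rows[isu], idarr[nlin[isu]], rep(-mh2, length(isu)))
        ctr[isu] <- ctr[isu] + 1
      }
      isp <- which(nst == 2L)
      if (length(isp)) {
        r[isp] <- r[isp] + mh2 * valarr[nlin[isp]]
        ctr[isp] <- ctr[isp] + 1
      }
      rest <- which(nst == 0L | nst == -1L)
      if (length(rest)) {
        if (dir == axis) {
          ## zero face at distance h, or free (Neumann) ghost past an
          ## inlet/outlet boundary
          ctr[rest] <- ctr[rest] + ifelse(inside[rest], 1, 0)
        } else {
          bothclosed <- rep(TRUE, length(rest))
          ok <- which(inside[rest])
          if (length(ok))
            bothclosed[ok] <- !(cA[nlin[rest[ok]]] | cB[nlin[rest[ok]]])
          ctr[rest] <- ctr[rest] + ifelse(bothclosed, 2, 1)
        }
      }
    }
    adda(rows, rows, ctr * mh2 + fdr[unk])
    ## outlet ghost-pressure contribution to the pressure gradient
    if (!is.null(pg)) {
      west <- which(ind[, 1] == 1L & pg[unk] != 0)
      if (length(west)) r[west] <- r[west] + pg[unk[west]] / h
      east <- which(ind[, 1] == dd[1] & pg[unk] != 0)
      if (length(east)) r[east] <- r[east] - pg[unk[east]] / h
    }
    ba[rows] <<- ba[rows] + r
    invisible(NULL)
  }
  assemble_momentum(ustat, uid, uval, facedrag(dim(ustat), 1), pghost, 1)
  assemble_momentum(vstat, vid, array(0, dim(vstat)),
                    facedrag(dim(vstat), 2), NULL, 2)
  assemble_momentum(wstat, wid, array(0, dim(wstat)),
                    facedrag(dim(wstat), 3), NULL, 3)
  A <- Matrix::sparseMatrix(i = unlist(AI[seq_len(na)]),
                            j = unlist(AJ[seq_len(na)]),
                            x = unlist(AX[seq_len(na)]), dims = c(nF, nF))

  ## ---- continuity operator B (cells x faces) and prescribed part g ----
  cells <- which(open); ind <- arrayInd(cells, d); prow <- pid[cells]
  BI <- vector("list", 6); BJ <- vector("list", 6); BX <- vector("list", 6)
  nb_ <- 0L; g <- numeric(nP)
  addb <- function(i, j, x) {
    nb_ <<- nb_ + 1L; BI[[nb_]] <<- i; BJ[[nb_]] <<- j; BX[[nb_]] <<- x
  }
  ih <- 1 / h
  contrib <- function(stat, idarr, valarr, offs, sgn) {
    dd <- dim(stat)
    nb <- ind
    nb[, 1] <- nb[, 1] + offs[1]; nb[, 2] <- nb[, 2] + offs[2]
    nb[, 3] <- nb[, 3] + offs[3]
    lin <- (nb[, 3] - 1) * dd[1] * dd[2] + (nb[, 2] - 1) * dd[1] + nb[, 1]
    st <- stat[lin]
    isu <- which(st == 1L)
    addb(prow[isu], idarr[lin[isu]], rep(sgn * ih, length(isu)))
    isp <- which(st == 2L)
    if (length(isp))
      g[prow[isp]] <<- g[prow[isp]] - sgn * ih * valarr[lin[isp]]
  }
  z2 <- function(dd) array(0, dd)
  contrib(ustat, uid, uval, c(1, 0, 0), +1)
  contrib(ustat, uid, uval, c(0, 0, 0), -1)
  contrib(vstat, vid, z2(dim(vstat)), c(0, 1, 0), +1)
  contrib(vstat, vid, z2(dim(vstat)), c(0, 0, 0), -1)
  contrib(wstat, wid, z2(dim(wstat)), c(0, 0, 1), +1)
  contrib(wstat, wid, z2(dim(wstat)), c(0, 0, 0), -1)
  B <- Matrix::sparseMatrix(i = unlist(BI[seq_len(nb_)]),
                            j = unlist(BJ[seq_len(nb_)]),
                            x = unlist(BX[seq_len(nb_)]), dims = c(nP, nF))

  zero_forcing <- !any_inlet && all(ba == 0) && all(g == 0)
  if (zero_forcing) {
    uu <- numeric(nF); pp <- numeric(nP); hist <- 0
  } else {
    gamma <- gamma0 * mu
    Ag <- A + gamma * Matrix::crossprod(B)
    Ch <- Matrix::Cholesky(Matrix::forceSymmetric(Ag), LDL = FALSE,
                           super = TRUE)
    pp <- numeric(nP)
    Btg <- as.numeric(Matrix::crossprod(B, g))
    scale0 <- NULL; hist <- numeric(0); uu <- numeric(nF)
    for (it in seq_len(maxit)) {
      rhs <- ba + as.numeric(Matrix::crossprod(B, pp)) + gamma * Btg
      uu <- as.numeric(Matrix::solve(Ch, rhs))
      rdiv <- as.numeric(B %*% uu) - g
      pp <- pp - gamma * rdiv
      res <- sqrt(sum(rdiv^2))
      if (is.null(scale0))
        scale0 <- max(res, sqrt(sum(g^2)), sqrt(sum(ba^2)) * h / mu, 1e-300)
      hist <- c(hist, res / scale0)
      if (res / scale0 < tol * 1e-4 || res / scale0 < 1e-13) break
    }
    if (hist[length(hist)] > tol)
      stop(sprintf(paste0("flow solver did not converge: relative residual ",
                          "%.3e after %d iterations (tol %.1e); history: %s"),
                   hist[length(hist)], length(hist), tol,
                   paste(signif(hist, 3), collapse = " ")))
  }

  uarr <- array(0, dim(ustat)); uarr[ustat == 1L] <- uu[uid[ustat == 1L]]
  uarr[ustat == 2L] <- uval[ustat == 2L]
  varr <- array(0, dim(vstat)); varr[vstat == 1L] <- uu[vid[vstat == 1L]]
  warr <- array(0, dim(wstat)); warr[wstat == 1L] <- uu[wid[wstat == 1L]]
  parr <- array(NA_real_, d); parr[open] <- pp

  ## mass-balance audit over the x boundaries
  q_in <- (sum(pmax(uarr[1, , ], 0)) + sum(pmax(-uarr[nx + 1, , ], 0))) * h^2
  q_out <- (sum(pmax(-uarr[1, , ], 0)) + sum(pmax(uarr[nx + 1, , ], 0))) * h^2

  structure(list(u = uarr, v = varr, w = warr, p = parr, grid = grid,
                 fluid = fluid, sph = sph, bc = bc,
                 residual_history = hist, tol = tol,
                 converged = TRUE, q_in = q_in, q_out = q_out,
                 cross_pressure = p_off_left - bc$outlet_pressure),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat("Steady Stokes-Brinkman flow field\n")
  cat(sprintf("  grid: %s voxels at %.3g um\n",
              paste(x$grid$shape, collapse = " x "), x$grid$spacing * 1e6))
  cat(sprintf("  inflow %.4g / outflow %.4g m^3/s (imbalance %.2g%%)\n",
              x$q_in, x$q_out,
              100 * abs(x$q_in - x$q_out) / max(x$q_in, 1e-300)))
  cat(sprintf("  residual drop: %s\n",
              paste(signif(x$residual_history, 3), collapse = " -> ")))
  if (abs(x$cross_pressure) > 0)
    cat(sprintf("  cross-channel pressure offset: %.4g Pa\n",
                x$cross_pressure))
  invisible(x)
}

#' Cell-centered velocity components and speed
#'
#' Averages the staggered face velocities to voxel centers.
#'
#' @param flow a [solve_flow()] field.
#' @return List with arrays `ux`, `uy`, `uz` and `speed` (m/s), zero in solid.
#' @export
cell_velocity <- function(flow) {
  d <- flow$grid$shape; nx <- d[1]; ny <- d[2]; nz <- d[3]
  ux <- 0.5 * (flow$u[1:nx, , , drop = FALSE] +
                 flow$u[2:(nx + 1), , , drop = FALSE])
  uy <- 0.5 * (flow$v[, 1:ny, , drop = FALSE] +
                 flow$v[, 2:(ny + 1), , drop = FALSE])
  uz <- 0.5 * (flow$w[, , 1:nz, drop = FALSE] +
                 flow$w[, , 2:(nz + 1), drop = FALSE])
  dim(ux) <- d; dim(uy) <- d; dim(uz) <- d
  list(ux = ux, uy = uy, uz = uz, speed = sqrt(ux^2 + uy^2 + uz^2))
}

#' Shear-rate magnitude field
#'
#' gamma_dot = sqrt(2 D:D) with D the symmetric part of the cell-centered
#' velocity-gradient tensor, computed by central differences (one-sided at
#' domain boundaries). Solid cells report zero.
#'
#' @param flow a [solve_flow()] field (or any list with face arrays `u`,
#'   `v`, `w` and a `grid`).
#' @return Array of shear rates (1/s).
#' @export
shear_rate_field <- function(flow) {
  cv <- cell_velocity(flow)
  h <- flow$grid$spacing
  grad <- function(a, axis) {
    d <- dim(a); n <- d[axis]
    if (n == 1) return(array(0, d))
    fwd <- shift3(a, -(axis == 1), -(axis == 2), -(axis == 3), NA)
    bwd <- shift3(a, +(axis == 1), +(axis == 2), +(axis == 3), NA)
    g <- (fwd - bwd) / (2 * h)
    one_f <- (fwd - a) / h; one_b <- (a - bwd) / h
    g[is.na(g) & !is.na(fwd)] <- one_f[is.na(g) & !is.na(fwd)]
    g[is.na(g) & !is.na(bwd)] <- one_b[is.na(g) & !is.na(bwd)]
    g[is.na(g)] <- 0
    g
  }
  dxx <- grad(cv$ux, 1); dxy <- grad(cv$ux, 2); dxz <- grad(cv$ux, 3)
  dyx <- grad(cv$uy, 1); dyy <- grad(cv$uy, 2); dyz <- grad(cv$uy, 3)
  dzx <- grad(cv$uz, 1); dzy <- grad(cv$uz, 2); dzz <- grad(cv$uz, 3)
  sxy <- (dxy + dyx) / 2; sxz <- (dxz + dzx) / 2; syz <- (dyz + dzy) / 2
  gam <- sqrt(2 * (dxx^2 + dyy^2 + dzz^2 + 2 * (sxy^2 + sxz^2 + syz^2)))
  gam[flow$grid$labels == REGIONS[["SOLID"]]] <- 0
  gam
}

#' Maximum cell divergence of a flow field
#'
#' Discrete divergence of the face velocities in every open cell, as a
#' fraction of the characteristic inlet face velocity. Converged solves are
#' at solver tolerance or below.
#'
#' @param flow a [solve_flow()] field.
#' @return Maximum relative divergence (dimensionless).
#' @export
max_divergence <- function(flow) {
  d <- flow$grid$shape; nx <- d[1]; ny <- d[2]; nz <- d[3]
  h <- flow$grid$spacing
  div <- (flow$u[2:(nx + 1), , , drop = FALSE] -
            flow$u[1:nx, , , drop = FALSE] +
            flow$v[, 2:(ny + 1), , drop = FALSE] -
            flow$v[, 1:ny, , drop = FALSE] +
            flow$w[, , 2:(nz + 1), drop = FALSE] -
            flow$w[, , 1:nz, drop = FALSE]) / h
  dim(div) <- d
  uref <- max(abs(flow$u), abs(flow$v), abs(flow$w), 1e-300)
  max(abs(div[open_mask(flow$grid)])) * h / uref
}
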