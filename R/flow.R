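#' Boundary conditions and fluid properties for the channel flow
#'
#' The conventional permeametry set-up: a uniform streamwise velocity at the inlet, zero
#' (gauge) pressure at the outlet, and no-slip on the channel walls and on
#' every disc boundary. The inlet velocity is chosen so the Reynolds number
#' built on the mean axon diameter stays far below one (creeping flow), the
#' regime in which Darcy permeability is independent of the forcing.
#'
#' @param inlet_velocity Uniform inlet velocity, m/s.
#' @param outlet_pressure Outlet gauge pressure, Pa.
#' @param viscosity Dynamic viscosity, Pa s (interstitial fluid ~ 1e-3).
#' @param density Fluid density, kg/m^3 (used only for the Reynolds check).
#' @return A `flow_bc` object.
#' @export
flow_bc <- function(inlet_velocity = 0.0024, outlet_pressure = 0,
                    viscosity = 1e-3, density = 1000) {
  if (inlet_velocity <= 0) stop("flow_bc: inlet_velocity must be > 0", call. = FALSE)
  if (viscosity <= 0) stop("flow_bc: viscosity must be > 0", call. = FALSE)
  structure(list(inlet_velocity = inlet_velocity,
                 outlet_pressure = outlet_pressure,
                 viscosity = viscosity, density = density),
            class = "flow_bc")
}

#' Channel flow domain around a porous (disc) zone
#'
#' Embeds the disc geometry in a straight channel of the same height, with
#' empty entrance and exit segments so the flow is fully developed before
#' it meets the porous zone. The fluid region is the channel minus the disc
#' interiors.
#'
#' @param geom A [geometry()]; its domain becomes the porous zone.
#' @param entrance_length,exit_length Empty channel lengths (um) upstream /
#'   downstream; default one channel height each.
#' @param gap_tol Minimum admissible surface gap (um) between discs; a
#'   pinched geometry is rejected as unmeshable.
#' @return A `flow_domain`.
#' @export
build_flow_domain <- function(geom, entrance_length = NULL, exit_length = NULL,
                              gap_tol = geom$gap_tol) {
  stopifnot(inherits(geom, "geometry"))
  H <- geom$domain[2]
  if (is.null(entrance_length)) entrance_length <- H
  if (is.null(exit_length)) exit_length <- H
  if (entrance_length < 0 || exit_length < 0)
    stop("build_flow_domain: lengths must be >= 0", call. = FALSE)
  if (nrow(geom$discs) >= 2) {
    g <- min_surface_gap(geom)
    if (g < gap_tol * (1 - 1e-6))
      stop(sprintf("build_flow_domain: min surface gap %.3g um below gap_tol %.3g",
                   g, gap_tol), call. = FALSE)
  }
  structure(list(geometry = geom, entrance = entrance_length,
                 exit = exit_length, height = H,
                 porous_length = geom$domain[1],
                 total_length = entrance_length + geom$domain[1] + exit_length),
            class = "flow_domain")
}

#' @export
print.flow_domain <- function(x, ...) {
  cat(sprintf(paste0("Flow domain: %.3g um channel (%.3g entrance + %.3g ",
                     "porous + %.3g exit) x %.3g um high, %d discs\n"),
              x$total_length, x$entrance, x$porous_length, x$exit, x$height,
              nrow(x$geometry$discs)))
  invisible(x)
}

#' Solve steady incompressible creeping flow through the channel
#'
#' Discretises the Stokes equations (inertia dropped; the Reynolds number
#' is checked to be at most 0.01) on a marker-and-cell staggered grid of
#' square cells: velocities on cell faces, pressures at cell centres, discs
#' represented by stair-step blocked cells with no-slip imposed half a cell
#' inside the solid (mirror ghost values). Fluid pockets not connected to
#' the inlet are excluded. The saddle-point system is solved by an
#' augmented-Lagrangian (grad-div) iteration: the penalised momentum matrix
#' is factorised once with a sparse Cholesky decomposition and a handful of
#' multiplier updates drive the divergence to solver precision, so the
#' discrete solution is mass-conservative cell by cell.
#'
#' @param domain A [build_flow_domain()] result.
#' @param bc A [flow_bc()].
#' @param resolution Cell size in micrometres (square cells; snapped so an
#'   integer number of cells spans the channel height).
#' @param gamma_factor Grad-div penalty in units of the viscosity.
#' @param n_uzawa Maximum multiplier updates.
#' @param div_tol Convergence threshold on `max |div u| h / U`.
#' @param check_re If `TRUE`, enforce the creeping-flow Reynolds bound.
#' @param open_throats Sub-grid throat treatment: disc pairs whose surface
#'   gap is below `throat_gap` are unresolvable on the grid and would
#'   disconnect the two-dimensional fluid network (a 2-D artefact: tangent
#'   discs seal the plane, while a real extracellular space stays connected
#'   around contacts). When `TRUE` (default) a one-cell channel is kept
#'   open at each such throat, so the network percolates like the
#'   continuous ECS atmosphere it represents.
#' @param throat_gap Gap threshold (um) below which throats are carved;
#'   default twice the cell size.
#' @return A `flow_solution` with face velocities `u`, `v` (m/s), cell
#'   pressures `p` (Pa, `NA` in solid), the fluid mask, grid metadata and a
#'   `stats` list (cells, unknowns, residuals, mass-balance error).
#' @export
solve_creeping_flow <- function(domain, bc, resolution,
                                gamma_factor = 1e7, n_uzawa = 15L,
                                div_tol = 1e-10, check_re = TRUE,
                                open_throats = TRUE, throat_gap = NULL) {
  stopifnot(inherits(domain, "flow_domain"), inherits(bc, "flow_bc"))
  geom <- domain$geometry
  H <- domain$height
  ny <- max(4L, as.integer(round(H / resolution)))
  h <- H / ny                              # um
  nx <- max(4L, as.integer(round(domain$total_length / h)))
  h_m <- h * 1e-6
  mu <- bc$viscosity
  U <- bc$inlet_velocity

  if (check_re && nrow(geom$discs)) {
    d_char <- mean(2 * geom$discs$r) * 1e-6
    Re <- bc$density * U * d_char / mu
    if (Re > 0.01)
      stop(sprintf("solve_creeping_flow: Re = %.3g exceeds creeping-flow bound 0.01",
                   Re), call. = FALSE)
  }

  solid <- if (nrow(geom$discs))
    rasterize_discs_cpp(geom$discs$x + domain$entrance, geom$discs$y,
                        geom$discs$r, nx, ny, h)
  else matrix(FALSE, nx, ny)
  n_carved <- 0L
  if (open_throats && nrow(geom$discs) >= 2) {
    if (is.null(throat_gap)) throat_gap <- 2 * h
    d <- geom$discs
    cp <- close_pairs_cpp(d$x + domain$entrance, d$y, d$r, throat_gap)
    if (nrow(cp)) {
      i1 <- cp[, 1]; i2 <- cp[, 2]
      ux <- d$x[i2] - d$x[i1]; uy <- d$y[i2] - d$y[i1]
      nn <- sqrt(ux^2 + uy^2); ux <- ux / nn; uy <- uy / nn
      # mid-gap point between the two surfaces
      mx <- d$x[i1] + domain$entrance + (d$r[i1] + cp[, 3] / 2) * ux
      my <- d$y[i1] + (d$r[i1] + cp[, 3] / 2) * uy
      for (t in c(-1, 0, 1)) {
        # carve along the throat (perpendicular to the centre line)
        px <- mx - t * h * uy; py <- my + t * h * ux
        ci <- pmin(pmax(floor(px / h) + 1L, 1L), nx)
        cj <- pmin(pmax(floor(py / h) + 1L, 1L), ny)
        idx <- cbind(ci, cj)
        n_carved <- n_carved + sum(solid[idx])
        solid[idx] <- FALSE
      }
    }
  }
  # keep only fluid connected to the inlet column
  lab <- label_components_cpp(!solid, diag = FALSE)
  keep_labs <- setdiff(unique(lab[1, ]), 0L)
  if (!length(keep_labs))
    stop("solve_creeping_flow: inlet column fully blocked", call. = FALSE)
  fluid <- matrix(lab %in% keep_labs, nx, ny)
  n_trapped <- sum(!fluid & !solid)
  solidM <- !fluid
  ncell <- sum(fluid)
  cellid <- matrix(0L, nx, ny)
  cellid[fluid] <- seq_len(ncell)

  # --- face classification --------------------------------------------
  uval <- matrix(NA_real_, nx + 1, ny)     # physical face i = row - 1
  adj_u <- matrix(FALSE, nx + 1, ny)
  adj_u[2:nx, ] <- solidM[1:(nx - 1), ] | solidM[2:nx, ]
  adj_u[1, ] <- solidM[1, ]
  adj_u[nx + 1, ] <- solidM[nx, ]
  uval[adj_u] <- 0
  uval[1, !adj_u[1, ]] <- U                # uniform inflow

  vval <- matrix(NA_real_, nx, ny + 1)     # physical face j = col - 1
  adj_v <- matrix(FALSE, nx, ny + 1)
  if (ny > 1) adj_v[, 2:ny] <- solidM[, 1:(ny - 1)] | solidM[, 2:ny]
  vval[adj_v] <- 0
  vval[, 1] <- 0; vval[, ny + 1] <- 0      # channel walls

  uunk <- is.na(uval); vunk <- is.na(vval)
  nu <- sum(uunk); nv <- sum(vunk)
  nunk <- nu + nv
  uid <- matrix(0L, nx + 1, ny); uid[uunk] <- seq_len(nu)
  vid <- matrix(0L, nx, ny + 1); vid[vunk] <- nu + seq_len(nv)

  trip_i <- vector("list", 16); trip_j <- trip_i; trip_x <- trip_i; nt <- 0L
  push <- function(i, j, x) {
    nt <<- nt + 1L
    trip_i[[nt]] <<- i; trip_j[[nt]] <<- j; trip_x[[nt]] <<- x
  }
  b <- numeric(nunk)

  # momentum rows for one velocity component; dirs: list of c(dI, dJ, tang)
  assemble_component <- function(unk, valm, idm, idm_nrow, dirs, diagv) {
    pu <- which(unk, arr.ind = TRUE)
    my <- idm[unk]                         # column-major, matches which()
    for (d in dirs) {
      nI <- pu[, 1] + d[1]; nJ <- pu[, 2] + d[2]
      tang <- d[3] == 1
      out <- nI < 1 | nI > nrow(valm) | nJ < 1 | nJ > ncol(valm)
      # outside the face grid: tangential => wall at half spacing (mirror
      # ghost, +2 on the diagonal); longitudinal => outflow, do-nothing
      if (any(out) && tang) diagv[my[out]] <- diagv[my[out]] + 2
      inb <- which(!out)
      if (!length(inb)) next
      lin <- (nJ[inb] - 1L) * idm_nrow + nI[inb]
      isunk <- unk[lin]
      iu <- inb[isunk]
      if (length(iu)) {
        push(my[iu], idm[lin[isunk]], rep(-1, length(iu)))
        diagv[my[iu]] <- diagv[my[iu]] + 1
      }
      ik <- inb[!isunk]
      if (length(ik)) {
        if (tang) {
          # known tangential neighbours are always 0 on a solid surface or
          # wall half a cell away: mirror ghost
          diagv[my[ik]] <- diagv[my[ik]] + 2
        } else {
          diagv[my[ik]] <- diagv[my[ik]] + 1
          b[my[ik]] <<- b[my[ik]] + valm[lin[!isunk]]
        }
      }
    }
    diagv
  }

  diag_u <- numeric(nunk)
  diag_u <- assemble_component(uunk, uval, uid, nx + 1,
                               list(c(-1L, 0L, 0L), c(1L, 0L, 0L),
                                    c(0L, -1L, 1L), c(0L, 1L, 1L)), diag_u)
  diag_u <- assemble_component(vunk, vval, vid, nx,
                               list(c(0L, -1L, 0L), c(0L, 1L, 0L),
                                    c(-1L, 0L, 1L), c(1L, 0L, 1L)), diag_u)
  iu_all <- c(uid[uunk], vid[vunk])
  push(iu_all, iu_all, diag_u[iu_all])

  trips <- list(i = unlist(trip_i[seq_len(nt)]),
                j = unlist(trip_j[seq_len(nt)]),
                x = unlist(trip_x[seq_len(nt)]))
  A <- Matrix::sparseMatrix(i = trips$i, j = trips$j, x = trips$x * mu / h_m^2,
                            dims = c(nunk, nunk))
  b <- b * mu / h_m^2

  # --- discrete gradient G (momentum) and divergence D = -t(G) ---------
  pu <- which(uunk, arr.ind = TRUE)
  uW <- cellid[cbind(pu[, 1] - 1L, pu[, 2])]           # west cell, always fluid
  east_in <- pu[, 1] <= nx
  uE <- integer(nu)
  uE[east_in] <- cellid[cbind(pu[east_in, 1], pu[east_in, 2])]
  gi <- c(uid[uunk], uid[uunk][east_in])
  gj <- c(uW, uE[east_in])
  gx <- c(rep(-1, nu), rep(1, sum(east_in)))
  # outlet faces see the ghost outlet pressure
  if (any(!east_in) && bc$outlet_pressure != 0)
    b[uid[uunk][!east_in]] <- b[uid[uunk][!east_in]] -
      bc$outlet_pressure / h_m
  pv <- which(vunk, arr.ind = TRUE)
  vS <- cellid[cbind(pv[, 1], pv[, 2] - 1L)]
  vN <- cellid[cbind(pv[, 1], pv[, 2])]
  gi <- c(gi, vid[vunk], vid[vunk])
  gj <- c(gj, vS, vN)
  gx <- c(gx, rep(-1, nv), rep(1, nv))
  G <- Matrix::sparseMatrix(i = gi, j = gj, x = gx / h_m,
                            dims = c(nunk, ncell))
  D <- -Matrix::t(G)

  # continuity right-hand side from known faces (inlet inflow)
  ku <- uval; ku[is.na(ku)] <- 0
  kv <- vval; kv[is.na(kv)] <- 0
  divk <- (ku[2:(nx + 1), , drop = FALSE] - ku[1:nx, , drop = FALSE]) / h_m +
          (kv[, 2:(ny + 1), drop = FALSE] - kv[, 1:ny, drop = FALSE]) / h_m
  g <- -divk[fluid]

  # --- augmented-Lagrangian solve --------------------------------------
  gamma <- gamma_factor * mu
  Agam <- A + gamma * Matrix::crossprod(D)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Agam), LDL = FALSE, super = TRUE)
  Dt <- Matrix::t(D)
  lam <- numeric(ncell)
  Dtg <- as.numeric(Dt %*% g)
  resid <- Inf; iters <- 0L
  for (it in seq_len(n_uzawa)) {
    rhs <- b - as.numeric(Dt %*% lam) + gamma * Dtg
    uvec <- as.numeric(Matrix::solve(ch, rhs))
    r <- as.numeric(D %*% uvec) - g
    lam <- lam + gamma * r
    resid <- max(abs(r)) * h_m / U
    iters <- it
    if (resid < div_tol) break
  }
  p <- -lam

  Ufull <- uval; Ufull[uunk] <- uvec[uid[uunk]]
  Vfull <- vval; Vfull[vunk] <- uvec[vid[vunk]]
  Pmat <- matrix(NA_real_, nx, ny); Pmat[fluid] <- p

  flux <- rowSums(Ufull) * h_m             # volume flux per face column
  flux_in <- flux[1]
  mass_err <- max(abs(flux - flux_in)) / abs(flux_in)

  structure(list(
    u = Ufull, v = Vfull, p = Pmat, fluid = fluid,
    h = h, h_m = h_m, nx = nx, ny = ny,
    domain = domain, bc = bc,
    stats = list(n_cells = nx * ny, n_fluid = ncell, n_unknowns = nunk,
                 n_trapped = n_trapped, n_carved = n_carved, h_um = h,
                 mask_porosity = porous_mask_porosity(fluid, domain, h),
                 div_residual = resid, uzawa_iters = iters,
                 mass_balance_err = mass_err)),
    class = "flow_solution")
}

# ECS fraction of the rasterised porous zone (diagnostic)
porous_mask_porosity <- function(fluid, domain, h) {
  i0 <- floor(domain$entrance / h) + 1L
  i1 <- ceiling((domain$entrance + domain$porous_length) / h)
  i1 <- min(i1, nrow(fluid))
  if (i1 < i0) return(NA_real_)
  mean(fluid[i0:i1, ])
}

#' @export
print.flow_solution <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("Creeping-flow solution: %d x %d cells (h = %.4g um), ",
                     "%d unknowns\n"), x$nx, x$ny, x$h, s$n_unknowns))
  cat(sprintf("  div residual %.2e, mass balance error %.2e (%d updates)\n",
              s$div_residual, s$mass_balance_err, s$uzawa_iters))
  invisible(x)
}

#' Cell-centred streamwise velocity field (m/s)
#' @param sol A `flow_solution`.
#' @return `nx` x `ny` matrix; zero inside solid.
#' @export
cell_velocity <- function(sol) {
  (sol$u[1:sol$nx, , drop = FALSE] + sol$u[2:(sol$nx + 1), , drop = FALSE]) / 2
}

# column index range of the porous zone
porous_columns <- function(sol) {
  xc <- (seq_len(sol$nx) - 0.5) * sol$h
  which(xc >= sol$domain$entrance &
        xc <= sol$domain$entrance + sol$domain$porous_length)
}

#' Bilinear sample of the velocity field at arbitrary points
#'
#' @param sol A `flow_solution`.
#' @param x,y Coordinates in micrometres (channel frame: x from the inlet).
#' @return Data frame with `u` and `v` (m/s); `NA` outside the channel.
#' @export
sample_velocity <- function(sol, x, y) {
  uc <- cell_velocity(sol)
  vc <- (sol$v[, 1:sol$ny, drop = FALSE] + sol$v[, 2:(sol$ny + 1), drop = FALSE]) / 2
  gx <- (seq_len(sol$nx) - 0.5) * sol$h
  gy <- (seq_len(sol$ny) - 0.5) * sol$h
  bilin <- function(M, px, py) {
    i <- pmin(pmax(findInterval(px, gx), 1L), sol$nx - 1L)
    j <- pmin(pmax(findInterval(py, gy), 1L), sol$ny - 1L)
    tx <- pmin(pmax((px - gx[i]) / sol$h, 0), 1)
    ty <- pmin(pmax((py - gy[j]) / sol$h, 0), 1)
    M[cbind(i, j)] * (1 - tx) * (1 - ty) + M[cbind(i + 1L, j)] * tx * (1 - ty) +
      M[cbind(i, j + 1L)] * (1 - tx) * ty + M[cbind(i + 1L, j + 1L)] * tx * ty
  }
  ok <- x >= 0 & x <= sol$nx * sol$h & y >= 0 & y <= sol$ny * sol$h
  u <- v <- rep(NA_real_, length(x))
  u[ok] <- bilin(uc, x[ok], y[ok]); v[ok] <- bilin(vc, x[ok], y[ok])
  data.frame(u = u, v = v)
}

#' Grid-sensitivity study of the flow solution
#'
#' Solves the same domain on successively finer grids and tracks the
#' average interstitial velocity magnitude along fixed transversal lines in
#' the porous zone (the fluid-weighted mean speed; the superficial mean is
#' fixed by mass conservation and cannot discriminate between grids). The
#' solution is declared grid-independent at the first level whose line
#' averages change by less than `tol_pct` percent with respect to the next
#' finer level.
#'
#' @param domain A [build_flow_domain()] result.
#' @param bc A [flow_bc()].
#' @param levels Strictly decreasing cell sizes (um), at least 3.
#' @param station_frac Positions of the sampling lines as fractions of the
#'   porous-zone length.
#' @param tol_pct Convergence threshold in percent.
#' @param ... Passed to [solve_creeping_flow()].
#' @return Data frame with one row per level (`h_um`, `nodes`, one column
#'   per line, `pct_change`); attribute `converged_level` gives the first
#'   converged row index (`NA` if none).
#' @export
grid_sensitivity <- function(domain, bc, levels,
                             station_frac = c(0.25, 0.5, 0.75),
                             tol_pct = 0.5, ...) {
  if (length(levels) < 3 || any(diff(levels) >= 0))
    stop("grid_sensitivity: need >= 3 strictly refining levels", call. = FALSE)
  vals <- matrix(NA_real_, length(levels), length(station_frac))
  nodes <- integer(length(levels))
  for (l in seq_along(levels)) {
    sol <- solve_creeping_flow(domain, bc, resolution = levels[l], ...)
    uc <- cell_velocity(sol)
    vc <- (sol$v[, 1:sol$ny, drop = FALSE] +
             sol$v[, 2:(sol$ny + 1), drop = FALSE]) / 2
    speed <- sqrt(uc^2 + vc^2)
    xs <- domain$entrance + station_frac * domain$porous_length
    cols <- pmin(pmax(round(xs / sol$h + 0.5), 1L), sol$nx)
    vals[l, ] <- vapply(cols, function(i) {
      fl <- sol$fluid[i, ]
      mean(speed[i, fl])
    }, numeric(1))
    nodes[l] <- sol$stats$n_unknowns + sol$stats$n_fluid
  }
  pct <- rep(NA_real_, length(levels))
  for (l in seq_len(length(levels) - 1))
    pct[l] <- 100 * max(abs(vals[l, ] - vals[l + 1, ]) /
                          pmax(abs(vals[l + 1, ]), 1e-300))
  out <- data.frame(level = seq_along(levels), h_um = levels, nodes = nodes)
  for (s in seq_along(station_frac))
    out[[paste0("line", s)]] <- vals[, s]
  out$pct_change <- pct
  conv <- which(pct < tol_pct)
  attr(out, "converged_level") <- if (length(conv)) conv[1] else NA_integer_
  out
}

#' Transversal profile of the streamwise velocity
#'
#' Superficial streamwise velocity averaged over the porous-zone length as
#' a function of the transversal coordinate. Near the channel walls the
#' local porosity is structurally higher (discs cannot cross the wall), so
#' the profile rises there: the channelling effect. The first local minima
#' inward from each wall mark the start of the representative bulk region.
#'
#' @param sol A `flow_solution`.
#' @param smooth Half-width (um) of the moving-average smoother; default
#'   half the mean disc diameter. Set 0 to disable.
#' @return Data frame `y`, `u` (raw) and `u_smooth`; attribute `height`.
#' @export
channelling_profile <- function(sol, smooth = NULL) {
  cols <- porous_columns(sol)
  uc <- cell_velocity(sol)
  prof <- colMeans(uc[cols, , drop = FALSE])   # superficial: solid cells are 0
  y <- (seq_len(sol$ny) - 0.5) * sol$h
  if (is.null(smooth)) {
    d <- sol$domain$geometry$discs
    smooth <- if (nrow(d)) mean(d$r) else 0
  }
  us <- prof
  if (smooth > 0) {
    w <- max(1L, round(smooth / sol$h))
    kern <- rep(1 / (2 * w + 1), 2 * w + 1)
    us <- as.numeric(stats::filter(prof, kern, sides = 2))
    # shrink the window near the walls instead of dropping to NA
    for (j in which(is.na(us))) {
      lo <- max(1L, j - w); hi <- min(sol$ny, j + w)
      us[j] <- mean(prof[lo:hi])
    }
  }
  out <- data.frame(y = y, u = prof, u_smooth = us)
  attr(out, "height") <- sol$ny * sol$h
  class(out) <- c("channelling_profile", "data.frame")
  out
}
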