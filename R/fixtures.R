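#' Calibrated lognormal ADD emulating white-matter axon diameters
#'
#' The axon diameter distributions measured on electron micrographs of
#' primate white matter are right-skewed and are conventionally modelled as
#' lognormal. This constructor builds a truncated-lognormal ADD whose
#' volume-to-surface ratio reproduces a requested ECS width at a reference
#' ECS fraction through the atmosphere relation
#' `d = (V/S) alpha / (1 - alpha)` (see [ecs_width()]): the target
#' `V/S = width * (1 - alpha_max) / alpha_max` is inverted for the lognormal
#' location parameter at fixed coefficient of variation, accounting for the
#' truncation bounds.
#'
#' The default calibration (35 nm at `alpha = 0.30`, CV 0.35) yields
#' `V/S ~ 81.7 nm` and a mean external diameter of about 0.3 um, so that
#' the ECS width spans roughly 16-35 nm over ECS fractions 0.18-0.30.
#'
#' @param width_at_alpha_max Target ECS width in nanometres at `alpha_max`.
#' @param alpha_max Reference ECS fraction for the calibration.
#' @param cv Coefficient of variation of the external diameter.
#' @param d_min,d_max Truncation bounds (um).
#' @param alpha_range ECS-fraction range recorded in the calibration report.
#' @return An [add_spec()] with an attached `calibration` attribute
#'   (targets and achieved widths at the ends of `alpha_range`, in nm).
#' @examples
#' add <- calibrated_add()
#' attr(add, "calibration")
#' @export
calibrated_add <- function(width_at_alpha_max = 35, alpha_max = 0.30,
                           cv = 0.35, d_min = 0.1, d_max = 1.5,
                           alpha_range = c(0.18, 0.30)) {
  if (!is.finite(width_at_alpha_max) || width_at_alpha_max <= 0)
    stop("calibrated_add: width target must be positive", call. = FALSE)
  vs_target <- width_at_alpha_max * 1e-3 * (1 - alpha_max) / alpha_max  # um
  if (cv < 0) stop("calibrated_add: cv must be >= 0", call. = FALSE)
  sdlog <- sqrt(log(1 + cv^2))
  if (cv == 0) {
    diam <- 4 * vs_target                 # monodisperse: V/S = r/2 = D/4
    if (diam < d_min || diam > d_max)
      stop("calibrated_add: degenerate diameter outside bounds", call. = FALSE)
    add <- add_spec("lognormal", meanlog = log(diam), sdlog = 0,
                    d_min = d_min, d_max = d_max)
  } else {
    f <- function(m)
      vs_ratio(add_spec("lognormal", meanlog = m, sdlog = sdlog,
                        d_min = d_min, d_max = d_max)) - vs_target
    lo <- log(d_min * 0.2); hi <- log(d_max * 2)
    if (f(lo) * f(hi) > 0)
      stop("calibrated_add: width target infeasible for bounded diameters",
           call. = FALSE)
    m <- uniroot(f, c(lo, hi), tol = 1e-12)$root
    add <- add_spec("lognormal", meanlog = m, sdlog = sdlog,
                    d_min = d_min, d_max = d_max)
  }
  achieved <- ecs_width(add, alpha_range) * 1e3
  attr(add, "calibration") <- list(
    width_target_nm = width_at_alpha_max, alpha_max = alpha_max, cv = cv,
    alpha_range = alpha_range, width_achieved_nm = achieved,
    mean_diameter_um = add_moments(add)$m1)
  add
}

#' Ordered (lattice) disc geometry for analytic cross-checks
#'
#' Regular arrays of equal discs admit closed-form transverse permeabilities
#' (e.g. Gebart's lubrication formula), which makes them the natural oracle
#' for the creeping-flow solver. The pitch solves the porosity relation of
#' the arrangement: `1 - pi r^2 / a^2 = porosity` for a square lattice.
#'
#' @param arrangement `"square"` or `"hexagonal"`.
#' @param radius Disc radius (um).
#' @param porosity Target ECS fraction; must exceed the close-packing limit
#'   of the arrangement (`1 - pi/4` for square, `1 - pi/(2 sqrt(3))` for
#'   hexagonal).
#' @param n_cells Number of lattice cells per side.
#' @return A [geometry()]. Square lattices honour the porosity exactly;
#'   hexagonal lattices only up to finite-size boundary effects.
#' @export
ordered_array_geometry <- function(arrangement = c("square", "hexagonal"),
                                   radius = 1, porosity = 0.5, n_cells = 4) {
  arrangement <- match.arg(arrangement)
  stopifnot(radius > 0, n_cells >= 1)
  if (arrangement == "square") {
    limit <- 1 - pi / 4
    if (porosity <= limit)
      stop(sprintf(paste0("ordered_array_geometry: porosity %.4f is at or ",
                          "below the square-packing limit %.4f"),
                   porosity, limit), call. = FALSE)
    a <- radius * sqrt(pi / (1 - porosity))
    ij <- expand.grid(i = seq_len(n_cells), j = seq_len(n_cells))
    discs <- data.frame(x = (ij$i - 0.5) * a, y = (ij$j - 0.5) * a, r = radius)
    geometry(discs, c(n_cells * a, n_cells * a), provenance = "constructed",
             check = TRUE)
  } else {
    limit <- 1 - pi / (2 * sqrt(3))
    if (porosity <= limit)
      stop(sprintf(paste0("ordered_array_geometry: porosity %.4f is at or ",
                          "below the hexagonal-packing limit %.4f"),
                   porosity, limit), call. = FALSE)
    a <- radius * sqrt(2 * pi / (sqrt(3) * (1 - porosity)))
    rows <- lapply(seq_len(n_cells), function(j) {
      xoff <- if (j %% 2 == 0) a / 2 else 0
      data.frame(x = (seq_len(n_cells) - 0.5) * a + xoff,
                 y = (j - 0.5) * a * sqrt(3) / 2, r = radius)
    })
    discs <- do.call(rbind, rows)
    # natural bounding domain; realised porosity differs slightly from the
    # infinite-lattice request because of the boundary band
    W <- max(discs$x + radius) + (min(discs$x) - radius)
    H <- max(discs$y + radius) + (min(discs$y) - radius)
    geometry(discs, c(W, H), provenance = "constructed", check = TRUE)
  }
}

#' Reference point patterns for spatial-statistics tests
#'
#' `"poisson"` gives a homogeneous Poisson (binomial) pattern - complete
#' spatial randomness; `"lattice"` a regular grid (inhibition); and
#' `"clustered"` a parent-offspring process (aggregation).
#'
#' @param kind `"poisson"`, `"lattice"` or `"clustered"`.
#' @param n Number of points (`>= 2`).
#' @param window `c(width, height)`.
#' @param seed Integer seed.
#' @return A [point_pattern()].
#' @export
reference_patterns <- function(kind = c("poisson", "lattice", "clustered"),
                               n = 500, window = c(1, 1), seed = 1L) {
  kind <- match.arg(kind)
  if (n < 2) stop("reference_patterns: n must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  W <- window[1]; H <- window[2]
  pts <- switch(kind,
    poisson = cbind(runif(n) * W, runif(n) * H),
    lattice = {
      m <- ceiling(sqrt(n))
      g <- expand.grid(i = seq_len(m), j = seq_len(m))
      cbind((g$i - 0.5) * W / m, (g$j - 0.5) * H / m)[seq_len(n), , drop = FALSE]
    },
    clustered = {
      npar <- max(2L, round(n / 50))
      par <- cbind(runif(npar) * W, runif(npar) * H)
      idx <- rep(seq_len(npar), length.out = n)
      sd <- 0.02 * min(W, H)
      off <- cbind(rnorm(n, sd = sd), rnorm(n, sd = sd))
      p <- par[idx, , drop = FALSE] + off
      cbind(pmin(pmax(p[, 1], 0), W), pmin(pmax(p[, 2], 0), H))
    })
  point_pattern(pts, window)
}

#' Gebart's transverse permeability of a regular fibre array
#'
#' Closed-form lubrication estimate of the permeability for creeping flow
#' perpendicular to a regular array of parallel cylinders:
#' `k = C (sqrt(phi_max / phi) - 1)^(5/2) r^2`, with
#' `C = 16 / (9 pi sqrt(2))`, `phi_max = pi/4` for a square array and
#' `C = 16 / (9 pi sqrt(6))`, `phi_max = pi / (2 sqrt(3))` for a hexagonal
#' one (`phi` = solid fraction = 1 - porosity). Used as the independent
#' analytic oracle for the flow solver on [ordered_array_geometry()].
#'
#' @param radius Cylinder radius (um or m; the result carries the square of
#'   the unit used).
#' @param porosity Fluid volume fraction.
#' @param arrangement `"square"` or `"hexagonal"`.
#' @return Permeability in squared units of `radius`.
#' @export
gebart_permeability <- function(radius, porosity,
                                arrangement = c("square", "hexagonal")) {
  arrangement <- match.arg(arrangement)
  phi <- 1 - porosity
  if (arrangement == "square") {
    C <- 16 / (9 * pi * sqrt(2)); phimax <- pi / 4
  } else {
    C <- 16 / (9 * pi * sqrt(6)); phimax <- pi / (2 * sqrt(3))
  }
  if (phi <= 0 || phi >= phimax)
    stop("gebart_permeability: solid fraction outside (0, phi_max)", call. = FALSE)
  C * (sqrt(phimax / phi) - 1)^2.5 * radius^2
}
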