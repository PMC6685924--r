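#' Planar disc geometry
#'
#' A set of non-overlapping discs (axon cross-sections) fully contained in an
#' axis-aligned rectangular domain with its lower-left corner at the origin.
#' The ECS volume fraction `alpha` is always the exact vector value
#' `1 - sum(pi r^2) / (W * H)`.
#'
#' @param discs Data frame with columns `x`, `y`, `r` (micrometres).
#' @param domain Numeric `c(width, height)` in micrometres.
#' @param seed Integer seed that produced the geometry (or `NA`).
#' @param provenance Stage label: `"packed"`, `"filled"`, `"shrunk"` or
#'   `"constructed"`.
#' @param add Optional [add_spec()] the diameters were drawn from.
#' @param gap_tol Minimum surface gap (um) the construction aimed to keep
#'   between discs; recorded for downstream meshability checks.
#' @param check If `TRUE`, verify non-overlap and containment (O(n^2); skip
#'   for large trusted constructions).
#' @return An object of class `geometry`.
#' @export
geometry <- function(discs, domain, seed = NA_integer_,
                     provenance = "constructed", add = NULL,
                     gap_tol = 1e-4, check = TRUE) {
  stopifnot(is.data.frame(discs), all(c("x", "y", "r") %in% names(discs)))
  if (length(domain) != 2 || any(!is.finite(domain)) || any(domain <= 0))
    stop("geometry: domain must be positive c(width, height)", call. = FALSE)
  discs <- discs[, c("x", "y", "r")]
  if (nrow(discs) && any(discs$r <= 0))
    stop("geometry: disc radii must be positive", call. = FALSE)
  g <- structure(
    list(discs = discs, domain = as.numeric(domain),
         alpha = 1 - sum(pi * discs$r^2) / prod(domain),
         seed = seed, provenance = provenance, add = add, gap_tol = gap_tol),
    class = "geometry")
  if (check && nrow(discs)) validate_geometry(g)
  g
}

#' Check the geometry invariants
#'
#' Verifies pairwise non-overlap (centre distance >= r_i + r_j - overlap_tol),
#' full containment in the domain, and that the stored `alpha` matches the
#' vector recomputation.
#'
#' @param geom A [geometry()].
#' @param overlap_tol Allowed numerical overlap (um).
#' @return `geom`, invisibly; stops on violation.
#' @export
validate_geometry <- function(geom, overlap_tol = 1e-9) {
  stopifnot(inherits(geom, "geometry"))
  d <- geom$discs
  if (nrow(d) >= 2) {
    gap <- min_gap_cpp(d$x, d$y, d$r)
    if (gap < -overlap_tol)
      stop(sprintf("geometry: discs overlap (min gap %.3g um)", gap),
           call. = FALSE)
  }
  W <- geom$domain[1]; H <- geom$domain[2]
  inside <- d$x - d$r >= -overlap_tol & d$x + d$r <= W + overlap_tol &
            d$y - d$r >= -overlap_tol & d$y + d$r <= H + overlap_tol
  if (!all(inside))
    stop(sprintf("geometry: %d disc(s) cross the domain boundary",
                 sum(!inside)), call. = FALSE)
  a <- 1 - sum(pi * d$r^2) / prod(geom$domain)
  if (abs(a - geom$alpha) > 1e-12 * max(1, abs(a)))
    stop("geometry: stored alpha is stale", call. = FALSE)
  invisible(geom)
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("Disc geometry [%s]: %d discs in %.3g x %.3g um domain\n",
              x$provenance, nrow(x$discs), x$domain[1], x$domain[2]))
  cat(sprintf("  ECS volume fraction alpha = %.4f", x$alpha))
  if (!is.na(x$seed)) cat(sprintf("  (seed %d)", x$seed))
  cat("\n")
  invisible(x)
}

#' ECS volume fraction of a geometry
#'
#' Exact vector computation `1 - sum(pi r_i^2) / (W H)`. The void (fluid)
#' area between discs divided by the total domain area.
#'
#' @param geom A [geometry()].
#' @return ECS fraction in (0, 1] (1 for an empty geometry).
#' @export
ecs_volume_fraction <- function(geom) {
  stopifnot(inherits(geom, "geometry"))
  1 - sum(pi * geom$discs$r^2) / prod(geom$domain)
}

#' Smallest surface gap between any two discs (um)
#' @param geom A [geometry()].
#' @return Minimum over pairs of centre distance minus radii sum; `Inf` when
#'   fewer than two discs.
#' @export
min_surface_gap <- function(geom) {
  stopifnot(inherits(geom, "geometry"))
  d <- geom$discs
  if (nrow(d) < 2) return(Inf)
  min_gap_cpp(d$x, d$y, d$r)
}

#' Centres of a disc tangent to two given discs
#'
#' Given discs `(c1, r1)` and `(c2, r2)`, a disc of radius `r3` externally
#' tangent to both has its centre on the intersection of circles of radius
#' `r1 + r3` about `c1` and `r2 + r3` about `c2`. There are two, one or zero
#' solutions; insertion is geometrically possible only while the surface gap
#' between the parents is smaller than the new diameter.
#'
#' @param c1,c2 Numeric length-2 centres (um).
#' @param r1,r2,r3 Radii (um), all positive.
#' @return A matrix with 0, 1 or 2 rows of `(x, y)` candidate centres.
#' @examples
#' tangent_disc_centers(c(0, 0), 1, c(2, 0), 1, 1)  # (1, +-sqrt(3))
#' @export
tangent_disc_centers <- function(c1, r1, c2, r2, r3) {
  if (r3 <= 0) stop("tangent_disc_centers: r3 must be positive", call. = FALSE)
  dx <- c2[1] - c1[1]; dy <- c2[2] - c1[2]
  d <- sqrt(dx^2 + dy^2)
  if (d < 1e-12)
    stop("tangent_disc_centers: coincident centres", call. = FALSE)
  R1 <- r1 + r3; R2 <- r2 + r3
  none <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  if (d > R1 + R2 || d < abs(R1 - R2)) return(none)
  a <- (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R1^2 - a^2
  if (h2 < 0) {
    if (h2 > -1e-12 * R1^2) h2 <- 0 else return(none)
  }
  h <- sqrt(h2)
  px <- c1[1] + a * dx / d; py <- c1[2] + a * dy / d
  ox <- -dy / d; oy <- dx / d
  out <- rbind(c(px + h * ox, py + h * oy),
               c(px - h * ox, py - h * oy))
  colnames(out) <- c("x", "y")
  if (h == 0) out <- out[1, , drop = FALSE]
  out
}

#' Shrink all discs to reach a target ECS fraction
#'
#' Multiplies every radius by the single factor
#' `s = sqrt((1 - alpha_target) / (1 - alpha))` with centres unchanged, so
#' the resulting ECS fraction equals `alpha_target` exactly (to round-off).
#' Shrinking can only increase the ECS fraction; it opens every inter-disc
#' gap, which is what makes the fluid region meshable.
#'
#' @param geom A [geometry()].
#' @param alpha_target Target ECS fraction, `>= geom$alpha` and `< 1`.
#' @return The shrunk [geometry()] (`provenance = "shrunk"`), with the scale
#'   factor in attribute `"shrink_factor"`.
#' @export
shrink_to_porosity <- function(geom, alpha_target) {
  stopifnot(inherits(geom, "geometry"))
  if (!is.finite(alpha_target) || alpha_target >= 1)
    stop("shrink_to_porosity: alpha_target must be < 1", call. = FALSE)
  if (alpha_target < geom$alpha - 1e-12)
    stop("shrink_to_porosity: shrinking cannot densify (alpha_target < alpha)",
         call. = FALSE)
  s <- sqrt((1 - alpha_target) / (1 - geom$alpha))
  d <- geom$discs
  d$r <- d$r * s
  out <- geometry(d, geom$domain, seed = geom$seed, provenance = "shrunk",
                  add = geom$add, gap_tol = geom$gap_tol, check = FALSE)
  attr(out, "shrink_factor") <- s
  out
}

#' Compare realised disc diameters with a target ADD
#'
#' Reports the maximum CDF gap (Kolmogorov-Smirnov distance) between the
#' realised diameters and the target distribution, and the relative change
#' in mean diameter. Used to quantify how much the void-filling and
#' shrinking stages distort the diameter distribution.
#'
#' @param geom A [geometry()] with at least 30 discs.
#' @param add The target [add_spec()].
#' @return List with `ks_distance`, `mean_realised`, `mean_target`,
#'   `mean_rel_change` (signed), and `n`.
#' @export
compare_add <- function(geom, add) {
  stopifnot(inherits(geom, "geometry"), inherits(add, "add_spec"))
  dd <- sort(2 * geom$discs$r)
  if (length(dd) < 30)
    stop("compare_add: need at least 30 discs", call. = FALSE)
  n <- length(dd)
  cdf <- add_cdf(add, dd)
  # one-sample KS statistic against the target CDF
  ks <- max(pmax(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1) / n - cdf)))
  m_t <- add_moments(add)$m1
  m_r <- mean(dd)
  list(ks_distance = ks, mean_realised = m_r, mean_target = m_t,
       mean_rel_change = (m_r - m_t) / m_t, n = n)
}

# CDF of the (truncated) target ADD, evaluated at diameters q.
add_cdf <- function(add, q) {
  if (add$family == "empirical") {
    pool <- add$diameters[add$diameters >= add$d_min & add$diameters <= add$d_max]
    return(ecdf(pool)(q))
  }
  if (add$sdlog == 0) return(as.numeric(q >= exp(add$meanlog)))
  plo <- plnorm(add$d_min, add$meanlog, add$sdlog)
  phi <- plnorm(add$d_max, add$meanlog, add$sdlog)
  p <- (plnorm(q, add$meanlog, add$sdlog) - plo) / (phi - plo)
  pmin(pmax(p, 0), 1)
}
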