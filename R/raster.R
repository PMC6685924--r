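#' Rasterise the extracellular space of a geometry
#'
#' Converts the disc geometry to a binary image by the pixel-centre
#' inclusion test: a pixel is extracellular space (ECS, `TRUE`) unless its
#' centre lies inside a disc. Pixel `(i, j)` has its centre at
#' `((i - 0.5) res, (j - 0.5) res)` from the domain's lower-left corner.
#'
#' @param geom A [geometry()].
#' @param resolution Pixel size in micrometres; must not exceed a quarter of
#'   the smallest disc radius so every disc is resolved.
#' @return A `binary_mask`: list with `mask` (logical matrix, rows = x,
#'   columns = y, `TRUE` = ECS), `resolution`, `origin` and `domain`.
#' @export
rasterize_ecs <- function(geom, resolution) {
  stopifnot(inherits(geom, "geometry"))
  if (!is.finite(resolution) || resolution <= 0)
    stop("rasterize_ecs: resolution must be positive", call. = FALSE)
  if (nrow(geom$discs) && resolution > min(geom$discs$r) / 4 + 1e-15)
    stop("rasterize_ecs: resolution too coarse (must be <= min radius / 4)",
         call. = FALSE)
  nx <- max(1L, as.integer(round(geom$domain[1] / resolution)))
  ny <- max(1L, as.integer(round(geom$domain[2] / resolution)))
  solid <- if (nrow(geom$discs))
    rasterize_discs_cpp(geom$discs$x, geom$discs$y, geom$discs$r,
                        nx, ny, resolution)
  else matrix(FALSE, nx, ny)
  structure(list(mask = !solid, resolution = resolution,
                 origin = c(0, 0), domain = geom$domain),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("Binary ECS mask %d x %d px at %.4g um/px (ECS fraction %.4f)\n",
              nrow(x$mask), ncol(x$mask), x$resolution, mean(x$mask)))
  invisible(x)
}

#' Branch points of the thinned ECS skeleton
#'
#' Reduces the ECS mask to centre-lines by iterative morphological thinning
#' and returns the points where the skeleton branches (pixels with three or
#' more skeleton neighbours in the 8-neighbourhood). Branch points mark the
#' locations where the distance between close discs is maximised, i.e. the
#' best spots to insert a new disc. Adjacent branch pixels are merged to
#' their centroid.
#'
#' @param mask A `binary_mask` from [rasterize_ecs()].
#' @return A two-column matrix of branch-point coordinates (um) in the
#'   domain frame; zero rows when the skeleton has no branches.
#' @export
skeleton_branch_points <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  empty <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  if (!any(mask$mask)) return(empty)
  skel <- thin_mask_cpp(mask$mask)
  nb <- neighbour_count(skel)
  bp <- skel & nb >= 3L
  if (!any(bp)) return(empty)
  lab <- label_components_cpp(bp, diag = TRUE)
  idx <- which(bp, arr.ind = TRUE)
  l <- lab[bp]
  cx <- tapply((idx[, 1] - 0.5) * mask$resolution + mask$origin[1], l, mean)
  cy <- tapply((idx[, 2] - 0.5) * mask$resolution + mask$origin[2], l, mean)
  cbind(x = as.numeric(cx), y = as.numeric(cy))
}

# number of TRUE 8-neighbours for each pixel of a logical matrix
neighbour_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out + p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  out
}

#' Fill inter-disc voids at skeleton branch points
#'
#' Iteratively densifies a packed geometry: the ECS is rasterised and
#' thinned, and at each skeleton branch point a new disc is inserted whose
#' radius is the local clearance (distance to the nearest disc surface or
#' wall) minus `gap_tol`. An insertion is accepted only if its diameter lies
#' within the ADD truncation bounds `[d_min, d_max]`. Each pass processes
#' the branch points in decreasing clearance order, shrinking candidates
#' that a same-pass insertion has encroached on; passes repeat until the ECS
#' fraction reaches `alpha_stop` or no admissible branch point remains. The
#' ECS fraction never increases.
#'
#' @param geom A packed [geometry()].
#' @param add The [add_spec()] whose bounds gate insertions (defaults to the
#'   ADD stored in `geom`).
#' @param alpha_stop Target ECS fraction (`< geom$alpha`); the attainable
#'   minimum may be higher.
#' @param resolution Raster pixel size for skeletonisation (um); default one
#'   tenth of the smallest disc radius.
#' @param seed Integer seed (tie-breaking among equal clearances).
#' @param gap_tol Minimum surface gap kept around inserted discs (um).
#' @param max_passes Safety cap on skeletonisation passes.
#' @return A [geometry()] with `provenance = "filled"`; attributes
#'   `alpha_min` (the minimum ECS fraction achieved), `n_inserted` and
#'   `passes`.
#' @export
fill_voids <- function(geom, add = geom$add, alpha_stop,
                       resolution = NULL, seed = 1L, gap_tol = geom$gap_tol,
                       max_passes = 50L) {
  stopifnot(inherits(geom, "geometry"), inherits(add, "add_spec"))
  if (!is.finite(alpha_stop) || alpha_stop <= 0)
    stop("fill_voids: alpha_stop must be positive", call. = FALSE)
  if (alpha_stop > geom$alpha + 1e-12)
    stop("fill_voids: alpha_stop exceeds the current ECS fraction", call. = FALSE)
  if (abs(alpha_stop - geom$alpha) <= 1e-12) return(geom)
  if (is.null(resolution)) resolution <- min(geom$discs$r) / 10
  set.seed(as.integer(seed))
  W <- geom$domain[1]; H <- geom$domain[2]
  d <- geom$discs
  alpha <- geom$alpha
  r_lo <- add$d_min / 2; r_hi <- add$d_max / 2
  n0 <- nrow(d)
  passes <- 0L
  cur <- geom
  repeat {
    passes <- passes + 1L
    if (passes > max_passes) break
    mask <- rasterize_ecs(cur, resolution)
    bp <- skeleton_branch_points(mask)
    if (!nrow(bp)) break
    clear_disc <- point_clearance_cpp(bp[, 1], bp[, 2], d$x, d$y, d$r)
    clear_wall <- pmin(bp[, 1], W - bp[, 1], bp[, 2], H - bp[, 2])
    rc <- pmin(clear_disc, clear_wall) - gap_tol
    keep <- rc >= r_lo & rc > 0
    if (!any(keep)) break
    bp <- bp[keep, , drop = FALSE]; rc <- rc[keep]
    ord <- order(rc, sample.int(length(rc)), decreasing = TRUE)
    bp <- bp[ord, , drop = FALSE]; rc <- rc[ord]
    new_x <- new_y <- new_r <- numeric(0)
    reached <- FALSE
    for (q in seq_along(rc)) {
      r_eff <- rc[q]
      if (length(new_r)) {
        dq <- sqrt((new_x - bp[q, 1])^2 + (new_y - bp[q, 2])^2) - new_r
        r_eff <- min(r_eff, min(dq) - gap_tol)
      }
      if (r_eff < r_lo || r_eff > r_hi) next
      new_x <- c(new_x, bp[q, 1]); new_y <- c(new_y, bp[q, 2])
      new_r <- c(new_r, r_eff)
      alpha <- alpha - pi * r_eff^2 / (W * H)
      if (alpha <= alpha_stop) { reached <- TRUE; break }
    }
    if (!length(new_r)) break
    d <- rbind(d, data.frame(x = new_x, y = new_y, r = new_r))
    cur <- geometry(d, geom$domain, seed = geom$seed, provenance = "filled",
                    add = add, gap_tol = gap_tol, check = FALSE)
    if (reached) break
  }
  out <- geometry(d, geom$domain, seed = geom$seed, provenance = "filled",
                  add = add, gap_tol = gap_tol, check = TRUE)
  attr(out, "alpha_min") <- out$alpha
  attr(out, "n_inserted") <- nrow(d) - n0
  attr(out, "passes") <- passes
  out
}
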