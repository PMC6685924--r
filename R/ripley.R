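#' Planar point pattern in a rectangular window
#'
#' @param points Two-column matrix or data frame of coordinates.
#' @param window Numeric `c(width, height)`; the window is
#'   `[0, width] x [0, height]`.
#' @return A `point_pattern` with the points, window and intensity
#'   `lambda = N / area`.
#' @export
point_pattern <- function(points, window) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  colnames(pts) <- c("x", "y")
  if (length(window) != 2 || any(!is.finite(window)) || any(window <= 0))
    stop("point_pattern: window must be positive c(width, height)", call. = FALSE)
  if (nrow(pts) < 2)
    stop("point_pattern: need at least 2 points", call. = FALSE)
  if (any(pts[, 1] < 0 | pts[, 1] > window[1] |
          pts[, 2] < 0 | pts[, 2] > window[2]))
    stop("point_pattern: points outside the window", call. = FALSE)
  structure(list(points = pts, window = as.numeric(window),
                 n = nrow(pts), lambda = nrow(pts) / prod(window)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("Point pattern: %d points in %.3g x %.3g window (lambda %.4g)\n",
              x$n, x$window[1], x$window[2], x$lambda))
  invisible(x)
}

# Ripley's isotropic edge-correction weight: fraction of the circle of
# radius r centred at (px, py) that lies inside [0,W] x [0,H]. Closed form
# for rectangles; valid for r < min(W, H) / 2. Vectorised.
ripley_edge_weight <- function(px, py, r, W, H) {
  d1 <- px; d2 <- W - px; d3 <- py; d4 <- H - py
  arc <- function(d) {
    a <- numeric(length(r))
    cut <- d < r
    a[cut] <- 2 * acos(pmin(1, d[cut] / r[cut]))
    a
  }
  corner <- function(da, db) {
    a <- numeric(length(r))
    cut <- da * da + db * db < r * r
    a[cut] <- acos(pmin(1, da[cut] / r[cut])) +
      acos(pmin(1, db[cut] / r[cut])) - pi / 2
    a
  }
  exterior <- arc(d1) + arc(d2) + arc(d3) + arc(d4) -
    corner(d1, d3) - corner(d1, d4) - corner(d2, d3) - corner(d2, d4)
  1 - exterior / (2 * pi)
}

#' Ripley's R function of a point pattern
#'
#' Estimates `R(t) = lambda^-1 sum_i sum_{j != i} w(l_i, l_j)^-1
#' I(d_ij < t) / N`, where `w` is the isotropic edge correction: the
#' fraction of the circle of radius `d_ij` centred on point `i` that lies
#' inside the window. For complete spatial randomness `R(t) = pi t^2`. The
#' companion linearisation is `L(t) = sqrt(R(t) / pi)`, which grows as a
#' unit-slope line through the origin under CSR.
#'
#' @param pattern A [point_pattern()].
#' @param t_values Increasing distance grid; all values must stay below half
#'   the shorter window side. Default: 50 points up to a quarter of the
#'   longer side.
#' @param edge_correction Apply the isotropic correction (`TRUE`) or use
#'   `w = 1` (`FALSE`).
#' @param normalise If `TRUE`, rescale distances (and `L`) so that `t = 1`
#'   corresponds to 25% of the longer window side.
#' @return A `ripley_result` with `t`, `R`, `L` and metadata.
#' @export
ripley_R <- function(pattern, t_values = NULL, edge_correction = TRUE,
                     normalise = FALSE) {
  stopifnot(inherits(pattern, "point_pattern"))
  W <- pattern$window[1]; H <- pattern$window[2]
  if (is.null(t_values))
    t_values <- seq(0, 0.25 * max(W, H), length.out = 51)[-1]
  t_values <- sort(t_values)
  if (max(t_values) >= min(W, H) / 2)
    stop("ripley_R: max(t) must be below half the shorter window side",
         call. = FALSE)
  pts <- pattern$points
  N <- pattern$n
  D <- as.matrix(dist(pts))
  off <- !diag(N)
  dij <- D[off]
  if (edge_correction) {
    pxm <- matrix(pts[, 1], N, N)[off]   # x of the centre point i (rows)
    pym <- matrix(pts[, 2], N, N)[off]
    w <- ripley_edge_weight(pxm, pym, dij, W, H)
    w <- pmax(w, 1e-6)
  } else w <- rep(1, length(dij))
  ord <- order(dij)
  ds <- dij[ord]
  cw <- cumsum(1 / w[ord])
  counts <- findInterval(t_values * (1 - 1e-12), ds)
  Rt <- (prod(pattern$window) / N^2) * ifelse(counts > 0, cw[pmax(counts, 1)], 0)
  Rt[counts == 0] <- 0
  res <- list(t = t_values, R = Rt, L = sqrt(Rt / pi),
              window = pattern$window, n = N,
              edge_correction = edge_correction,
              normalised = normalise, t_ref = 0.25 * max(W, H))
  if (normalise) {
    res$t <- res$t / res$t_ref
    res$L <- res$L / res$t_ref
  }
  structure(res, class = "ripley_result")
}

#' Linearise an R function into the L function
#'
#' `L(t) = sqrt(R(t) / pi)`, recomputed from the stored `R` values.
#'
#' @param result A `ripley_result` from [ripley_R()].
#' @return The result with `L` (re)computed.
#' @export
l_function <- function(result) {
  stopifnot(inherits(result, "ripley_result"))
  scale <- if (result$normalised) result$t_ref else 1
  result$L <- sqrt(result$R / pi) / scale
  result
}

#' @export
print.ripley_result <- function(x, ...) {
  cat(sprintf("Ripley R/L result: %d points, %d distances up to %.4g%s\n",
              x$n, length(x$t), max(x$t),
              if (x$normalised) " (normalised)" else ""))
  invisible(x)
}

#' Classify a point pattern against complete spatial randomness
#'
#' Fits the through-origin least-squares slope of `L(t)` against `t` up to
#' `t_max`. Under CSR the slope is 1; clustering pulls it above 1 and
#' inhibition (regularity) below. The pattern is declared CSR when
#' `|slope - 1| <= csr_tol`.
#'
#' @param pattern A [point_pattern()].
#' @param t_max Largest distance used; at most 25% of the longer window
#'   side (the default).
#' @param n_t Number of grid points.
#' @param csr_tol Half-width of the CSR band on the slope.
#' @param edge_correction Passed to [ripley_R()].
#' @return List with `slope`, `classification` (`"CSR"`, `"clustered"` or
#'   `"inhibited"`), `n`, `t_max` and the underlying `ripley_result`.
#' @export
csr_classify <- function(pattern, t_max = NULL, n_t = 50, csr_tol = 0.05,
                         edge_correction = TRUE) {
  stopifnot(inherits(pattern, "point_pattern"))
  W <- pattern$window[1]; H <- pattern$window[2]
  lim <- 0.25 * max(W, H)
  if (is.null(t_max)) t_max <- lim
  if (t_max > lim + 1e-12)
    stop("csr_classify: t_max must not exceed 25% of the longer window side",
         call. = FALSE)
  tv <- seq(0, t_max, length.out = n_t + 1)[-1]
  res <- ripley_R(pattern, tv, edge_correction = edge_correction)
  slope <- sum(res$L * res$t) / sum(res$t^2)
  cls <- if (abs(slope - 1) <= csr_tol) "CSR"
         else if (slope > 1) "clustered" else "inhibited"
  list(slope = slope, classification = cls, n = pattern$n,
       t_max = t_max, result = res)
}
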