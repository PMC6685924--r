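#' Darcy permeability of a square window
#'
#' Homogenises the flow solution over a square window inside the porous
#' zone. The superficial (Darcy) velocity is the integral of the streamwise
#' velocity over the fluid part of the window divided by the *total* window
#' area; the driving gradient is the least-squares slope of the
#' fluid-averaged pressure versus the streamwise coordinate across the
#' window; and `k = mu * v_superficial / |grad p|`.
#'
#' @param sol A `flow_solution`.
#' @param size Window edge length (um).
#' @param center Window centre `c(x, y)` in channel coordinates (um);
#'   default the centre of the porous zone.
#' @param bc Boundary conditions (defaults to those of the solution; the
#'   viscosity enters `k`).
#' @return A `permeability_result`: list with `k` (m^2), `v_superficial`
#'   (m/s), `grad_p` (Pa/m), the window and cell counts.
#' @export
window_permeability <- function(sol, size, center = NULL, bc = sol$bc) {
  stopifnot(inherits(sol, "flow_solution"))
  dom <- sol$domain
  if (is.null(center))
    center <- c(dom$entrance + dom$porous_length / 2, dom$height / 2)
  if (size <= 0) stop("window_permeability: size must be > 0", call. = FALSE)
  xc <- (seq_len(sol$nx) - 0.5) * sol$h
  yc <- (seq_len(sol$ny) - 0.5) * sol$h
  ii <- which(xc >= center[1] - size / 2 & xc <= center[1] + size / 2)
  jj <- which(yc >= center[2] - size / 2 & yc <= center[2] + size / 2)
  if (length(ii) < 2 || length(jj) < 1)
    stop("window_permeability: window too small for the grid", call. = FALSE)
  uc <- cell_velocity(sol)[ii, jj, drop = FALSE]
  fl <- sol$fluid[ii, jj, drop = FALSE]
  if (!any(fl))
    stop("window_permeability: window contains no fluid", call. = FALSE)
  area <- length(ii) * length(jj) * sol$h_m^2
  v_sup <- sum(uc[fl]) * sol$h_m^2 / area
  pw <- sol$p[ii, jj, drop = FALSE]
  pbar <- rowMeans(pw, na.rm = TRUE)
  xs <- xc[ii] * 1e-6
  okc <- is.finite(pbar)
  if (sum(okc) < 2)
    stop("window_permeability: too few fluid columns for a pressure fit",
         call. = FALSE)
  slope <- unname(coef(lm(pbar[okc] ~ xs[okc]))[2])
  if (!is.finite(slope) || abs(slope) < 1e-300)
    stop("window_permeability: near-zero pressure gradient", call. = FALSE)
  structure(list(k = bc$viscosity * v_sup / abs(slope),
                 v_superficial = v_sup, grad_p = abs(slope),
                 window = list(size = size, center = center),
                 n_cells = length(ii) * length(jj), n_fluid = sum(fl)),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf(paste0("Window permeability: k = %.4g m^2 (%.3g um window, ",
                     "v = %.4g m/s, |grad p| = %.4g Pa/m)\n"),
              x$k, x$window$size, x$v_superficial, x$grad_p))
  invisible(x)
}

#' Mean and sample standard deviation of replicate permeabilities
#'
#' `k_bar = mean(k)`; `sigma = sqrt(sum((k_i - k_bar)^2) / (n - 1))` (the
#' sample standard deviation).
#'
#' @param k Numeric vector of per-replicate permeabilities.
#' @return List with `mean`, `sd` and `n`.
#' @export
permeability_stats <- function(k) {
  k <- k[is.finite(k)]
  if (length(k) < 1) stop("permeability_stats: no finite values", call. = FALSE)
  list(mean = mean(k), sd = if (length(k) > 1) sd(k) else 0, n = length(k))
}

#' Wall-exclusion band from the channelling effect
#'
#' Locates, on each smoothed channelling profile, the local minima nearest
#' the bottom and top walls, and averages their positions over the supplied
#' solutions. Windows reaching beyond these averaged positions sample the
#' wall-channelling zone and are excluded from homogenisation.
#'
#' @param solutions A list of `flow_solution` objects (or a single one).
#' @param smooth Passed to [channelling_profile()].
#' @return List with `lower` and `upper` (um), and the per-solution minima.
#'   With no near-wall minima (e.g. an empty channel) the band has zero
#'   width: `lower = 0`, `upper = H`.
#' @export
channelling_bounds <- function(solutions, smooth = NULL) {
  if (inherits(solutions, "flow_solution")) solutions <- list(solutions)
  stopifnot(length(solutions) >= 1)
  H <- solutions[[1]]$domain$height
  lo <- hi <- numeric(0)
  per <- data.frame(solution = integer(0), lower = numeric(0),
                    upper = numeric(0))
  for (s in seq_along(solutions)) {
    pr <- channelling_profile(solutions[[s]], smooth = smooth)
    u <- pr$u_smooth; y <- pr$y; m <- length(u)
    is_min <- c(FALSE, u[2:(m - 1)] < u[1:(m - 2)] &
                         u[2:(m - 1)] < u[3:m], FALSE)
    mins <- which(is_min)
    if (length(mins)) {
      l <- y[mins[1]]; h <- y[mins[length(mins)]]
    } else {
      l <- 0; h <- H
    }
    lo <- c(lo, l); hi <- c(hi, h)
    per <- rbind(per, data.frame(solution = s, lower = l, upper = h))
  }
  list(lower = mean(lo), upper = mean(hi), height = H, per_solution = per)
}

#' Permeability sweep over nested window sizes and replicate geometries
#'
#' The RVE-size study: each replicate geometry is solved once; nested
#' square windows, concentric with the porous zone and with edge lengths
#' `j * H / n_divisions` for `j = 1..n_used`, are homogenised with
#' [window_permeability()]; and the mean and sample standard deviation of
#' `k` across replicates are reported per window size. Only the first
#' `n_used` of the `n_divisions` sizes are considered, so the windows stay
#' clear of the wall channelling zone; windows that nevertheless protrude
#' beyond the measured channelling bounds are skipped with a warning.
#'
#' @param geometries List of replicate [geometry()] objects with identical
#'   nominal ECS fraction and ADD (at least 2).
#' @param bc A [flow_bc()].
#' @param resolution Flow-solver cell size (um).
#' @param n_divisions Number of divisions of the porous-zone height.
#' @param n_used Number of window sizes retained (counting from the
#'   smallest).
#' @param entrance_length,exit_length Channel margins (um); default one
#'   channel height.
#' @param solutions Optional list of pre-computed `flow_solution`s matching
#'   `geometries` (skips the solves).
#' @param ... Passed to [solve_creeping_flow()].
#' @return An `rve_sweep`: sizes (um), `k_mean`, `k_sd`, `n`, the full `k`
#'   matrix (replicates x sizes), and the channelling bounds.
#' @export
rve_sweep <- function(geometries, bc, resolution, n_divisions = 20,
                      n_used = 16, entrance_length = NULL, exit_length = NULL,
                      solutions = NULL, ...) {
  if (inherits(geometries, "geometry")) geometries <- list(geometries)
  n <- length(geometries)
  if (n < 2 && is.null(solutions))
    stop("rve_sweep: need at least 2 replicate geometries", call. = FALSE)
  alphas <- vapply(geometries, function(g) g$alpha, numeric(1))
  if (diff(range(alphas)) > 0.02)
    warning("rve_sweep: replicate ECS fractions differ by more than 0.02")
  if (is.null(solutions)) {
    solutions <- lapply(geometries, function(g) {
      dom <- build_flow_domain(g, entrance_length, exit_length)
      solve_creeping_flow(dom, bc, resolution = resolution, ...)
    })
  }
  n <- length(solutions)
  H <- solutions[[1]]$domain$height
  bounds <- channelling_bounds(solutions)
  sizes <- seq_len(n_used) * H / n_divisions
  K <- matrix(NA_real_, n, length(sizes))
  for (s in seq_along(solutions)) {
    for (q in seq_along(sizes)) {
      ylo <- H / 2 - sizes[q] / 2; yhi <- H / 2 + sizes[q] / 2
      if (ylo < bounds$lower - 1e-9 || yhi > bounds$upper + 1e-9) {
        warning(sprintf(paste0("rve_sweep: window %.3g um enters the ",
                               "channelling band; skipped"), sizes[q]))
        next
      }
      K[s, q] <- tryCatch(window_permeability(solutions[[s]], sizes[q])$k,
                          error = function(e) {
                            warning(sprintf(
                              "rve_sweep: window %.3g um unusable (%s)",
                              sizes[q], conditionMessage(e)), call. = FALSE)
                            NA_real_
                          })
    }
  }
  k_mean <- apply(K, 2, function(z) if (all(is.na(z))) NA_real_
                                    else mean(z, na.rm = TRUE))
  k_sd <- apply(K, 2, function(z) if (sum(is.finite(z)) < 2) NA_real_
                                  else sd(z, na.rm = TRUE))
  structure(list(sizes = sizes, k_mean = k_mean, k_sd = k_sd, n = n,
                 k_matrix = K, bounds = bounds, n_divisions = n_divisions,
                 n_used = n_used, height = H),
            class = "rve_sweep")
}

#' @export
print.rve_sweep <- function(x, ...) {
  cat(sprintf("RVE sweep: %d replicates, %d window sizes up to %.3g um\n",
              x$n, length(x$sizes), max(x$sizes)))
  df <- data.frame(size_um = signif(x$sizes, 4),
                   k_mean_m2 = signif(x$k_mean, 4),
                   k_sd_m2 = signif(x$k_sd, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Select the representative volume element size
#'
#' The RVE is the smallest window size at which (a) the mean permeability
#' has reached its plateau - it differs from the value at the largest
#' retained window by at most `plateau_tol` (relative) - and (b) the
#' replicate scatter is small: `sd / mean <= cv_tol`.
#'
#' @param sweep An `rve_sweep`.
#' @param plateau_tol Relative tolerance on the mean-permeability plateau.
#' @param cv_tol Tolerance on the coefficient of variation.
#' @return List with `found`, and when found `rve_um`, `k_m2`, `cv`, plus
#'   the criteria and the per-size table.
#' @export
select_rve <- function(sweep, plateau_tol = 0.05, cv_tol = 0.05) {
  stopifnot(inherits(sweep, "rve_sweep"))
  ok_idx <- which(is.finite(sweep$k_mean) & is.finite(sweep$k_sd))
  if (length(ok_idx) < 5)
    stop("select_rve: need at least 5 usable window sizes", call. = FALSE)
  ref <- sweep$k_mean[ok_idx[length(ok_idx)]]
  plateau <- abs(sweep$k_mean[ok_idx] - ref) / abs(ref) <= plateau_tol
  cv <- sweep$k_sd[ok_idx] / abs(sweep$k_mean[ok_idx])
  pass <- plateau & cv <= cv_tol
  tab <- data.frame(size_um = sweep$sizes[ok_idx],
                    k_mean_m2 = sweep$k_mean[ok_idx],
                    k_sd_m2 = sweep$k_sd[ok_idx], cv = cv,
                    plateau = plateau, pass = pass)
  criteria <- list(plateau_tol = plateau_tol, cv_tol = cv_tol)
  if (!any(pass))
    return(list(found = FALSE, criteria = criteria, table = tab))
  sel <- ok_idx[which(pass)[1]]
  list(found = TRUE, rve_um = sweep$sizes[sel], k_m2 = sweep$k_mean[sel],
       cv = sweep$k_sd[sel] / abs(sweep$k_mean[sel]),
       criteria = criteria, table = tab)
}
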