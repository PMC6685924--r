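#' Axon diameter distribution (ADD) specification
#'
#' Describes the distribution of *external* (myelin-inclusive) axon diameters
#' used to size the discs of the planar white-matter model. Two families are
#' supported: a truncated lognormal parameterised on the external diameter,
#' and an empirical list of diameters. When building an ADD from inner
#' (axolemma) diameters, `myelin_offset` is added once to convert them to
#' external diameters.
#'
#' @param family `"lognormal"` or `"empirical"`.
#' @param meanlog,sdlog Location and scale of the lognormal on the external
#'   diameter, in log-micrometre units (lognormal family only).
#' @param diameters Numeric vector of diameters in micrometres (empirical
#'   family only). Interpreted as inner diameters if `myelin_offset > 0`.
#' @param d_min,d_max Truncation bounds on the external diameter
#'   (micrometres). Samples always fall inside `[d_min, d_max]`.
#' @param myelin_offset Additive myelin sheath width (micrometres) applied
#'   when converting inner to external diameters.
#' @return An object of class `add_spec`.
#' @examples
#' add <- add_spec("lognormal", meanlog = log(0.3), sdlog = 0.34)
#' summary(sample_diameters(add, 100, seed = 1))
#' @export
add_spec <- function(family = c("lognormal", "empirical"),
                     meanlog = NULL, sdlog = NULL, diameters = NULL,
                     d_min = 0.1, d_max = 1.5, myelin_offset = 0) {
  family <- match.arg(family)
  if (!is.numeric(d_min) || !is.numeric(d_max) || d_min <= 0 || d_max <= d_min)
    stop("add_spec: need 0 < d_min < d_max", call. = FALSE)
  if (myelin_offset < 0) stop("add_spec: myelin_offset must be >= 0", call. = FALSE)
  if (family == "lognormal") {
    if (is.null(meanlog) || is.null(sdlog) || !is.finite(meanlog) ||
        !is.finite(sdlog) || sdlog < 0)
      stop("add_spec: lognormal family needs finite meanlog and sdlog >= 0",
           call. = FALSE)
    # truncation interval must carry probability mass
    if (sdlog > 0 && plnorm(d_max, meanlog, sdlog) - plnorm(d_min, meanlog, sdlog) <= 0)
      stop("add_spec: truncation interval has zero probability mass", call. = FALSE)
    if (sdlog == 0 && (exp(meanlog) < d_min || exp(meanlog) > d_max))
      stop("add_spec: degenerate diameter outside [d_min, d_max]", call. = FALSE)
    diameters <- NULL
  } else {
    if (is.null(diameters) || !length(diameters) || any(!is.finite(diameters)) ||
        any(diameters <= 0))
      stop("add_spec: empirical family needs positive finite diameters",
           call. = FALSE)
    diameters <- diameters + myelin_offset
    if (!any(diameters >= d_min & diameters <= d_max))
      stop("add_spec: no empirical diameters inside [d_min, d_max]", call. = FALSE)
    meanlog <- sdlog <- NULL
  }
  structure(
    list(family = family, meanlog = meanlog, sdlog = sdlog,
         diameters = diameters, d_min = d_min, d_max = d_max,
         myelin_offset = myelin_offset),
    class = "add_spec")
}

#' @export
print.add_spec <- function(x, ...) {
  cat("Axon diameter distribution (", x$family, ")\n", sep = "")
  if (x$family == "lognormal")
    cat(sprintf("  meanlog = %.4f, sdlog = %.4f (external diameter, um)\n",
                x$meanlog, x$sdlog))
  else
    cat(sprintf("  %d empirical diameters, mean %.3f um\n",
                length(x$diameters), mean(x$diameters)))
  cat(sprintf("  truncation [%.3g, %.3g] um, myelin offset %.3g um\n",
              x$d_min, x$d_max, x$myelin_offset))
  m <- add_moments(x)
  cat(sprintf("  E[D] = %.4f um, E[D^2] = %.5f um^2\n", m$m1, m$m2))
  invisible(x)
}

#' Sample external axon diameters from an ADD
#'
#' Truncated-lognormal sampling uses the inverse-CDF transform restricted to
#' the probability mass of `[d_min, d_max]`, so every draw respects the
#' bounds exactly. Empirical ADDs are resampled with replacement from the
#' in-bounds diameters.
#'
#' @param add An [add_spec()].
#' @param n Number of diameters to draw (`n >= 1`).
#' @param seed Integer seed; fixed seed gives reproducible draws.
#' @return Numeric vector of `n` diameters (micrometres), all in
#'   `[d_min, d_max]`.
#' @export
sample_diameters <- function(add, n, seed = 1L) {
  stopifnot(inherits(add, "add_spec"))
  if (!is.numeric(n) || n < 1) stop("sample_diameters: n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  if (add$family == "empirical") {
    pool <- add$diameters[add$diameters >= add$d_min & add$diameters <= add$d_max]
    return(pool[sample.int(length(pool), n, replace = TRUE)])
  }
  if (add$sdlog == 0) return(rep(exp(add$meanlog), n))
  plo <- plnorm(add$d_min, add$meanlog, add$sdlog)
  phi <- plnorm(add$d_max, add$meanlog, add$sdlog)
  d <- qlnorm(plo + runif(n) * (phi - plo), add$meanlog, add$sdlog)
  # guard against round-off at the bounds
  pmin(pmax(d, add$d_min), add$d_max)
}

#' First two truncated moments of the external diameter
#'
#' Closed-form truncated-lognormal moments, or plain sample moments of the
#' in-bounds empirical diameters.
#'
#' @param add An [add_spec()].
#' @return List with elements `m1` (`E[D]`, um) and `m2` (`E[D^2]`, um^2).
#' @export
add_moments <- function(add) {
  stopifnot(inherits(add, "add_spec"))
  if (add$family == "empirical") {
    pool <- add$diameters[add$diameters >= add$d_min & add$diameters <= add$d_max]
    return(list(m1 = mean(pool), m2 = mean(pool^2)))
  }
  if (add$sdlog == 0) {
    d <- exp(add$meanlog)
    return(list(m1 = d, m2 = d^2))
  }
  mu <- add$meanlog; s <- add$sdlog
  za <- (log(add$d_min) - mu) / s
  zb <- (log(add$d_max) - mu) / s
  mass <- pnorm(zb) - pnorm(za)
  mk <- function(k)
    exp(k * mu + k^2 * s^2 / 2) *
      (pnorm(zb - k * s) - pnorm(za - k * s)) / mass
  list(m1 = mk(1), m2 = mk(2))
}

#' Average ECS width around an axon
#'
#' The extracellular space forms an "atmosphere" of average thickness
#' `d = (V/S) * alpha / (1 - alpha)` around each axon, where `V/S` is the
#' volume-to-surface ratio of the average axon. For a unit-length slab of
#' circular axons of radii `r_i`, `V/S = sum(pi r^2) / sum(2 pi r)
#' = E[r^2] / (2 E[r])`, i.e. `E[D^2] / (4 E[D])` in diameter terms.
#'
#' @param x An [add_spec()] (moments of the distribution are used) or a
#'   [geometry()] (realised disc radii are used).
#' @param alpha ECS volume fraction, strictly inside (0, 1). Vectorised.
#' @return ECS width(s) in micrometres.
#' @examples
#' # radii 0.1 and 0.2 um at alpha = 0.3: V/S = 0.025/0.3 um, d ~ 35.7 nm
#' g <- geometry(data.frame(x = c(0, 1), y = c(0, 0), r = c(0.1, 0.2)),
#'               domain = c(2, 1))
#' ecs_width(g, 0.3) * 1e3
#' @export
ecs_width <- function(x, alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1))
    stop("ecs_width: alpha must lie strictly inside (0, 1)", call. = FALSE)
  vs <- vs_ratio(x)
  vs * alpha / (1 - alpha)
}

#' Volume-to-surface ratio of the average axon (um)
#' @param x An [add_spec()] or [geometry()].
#' @return `E[r^2] / (2 E[r])` in micrometres.
#' @export
vs_ratio <- function(x) {
  if (inherits(x, "add_spec")) {
    m <- add_moments(x)
    m$m2 / (4 * m$m1)
  } else if (inherits(x, "geometry")) {
    r <- x$discs$r
    mean(r^2) / (2 * mean(r))
  } else stop("vs_ratio: need an add_spec or geometry", call. = FALSE)
}

#' @importFrom stats pnorm
NULL
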