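#' Pack polydisperse discs by an advancing-front construction
#'
#' Builds a random, highly packed, non-overlapping disc assembly whose
#' diameters are drawn from an axon diameter distribution. The first three
#' discs form a mutually tangent triplet at the domain centre; every later
#' disc is placed tangent to the two discs of a front edge, on the exterior
#' side of the propagating front. The front is maintained as a closed
#' polygon of disc centres, traversed in a fixed cyclic order. The domain
#' rectangle starts from the area the discs would occupy at an ECS fraction
#' of `alpha_init` and its linear dimensions grow by `growth_factor` each
#' time a disc cannot be placed anywhere on the current front, until every
#' disc has found space.
#'
#' Every placement keeps a surface gap of at least `gap_tol` between discs
#' (tangency is realised at that clearance), so the extracellular fluid
#' region is never pinched to zero width.
#'
#' @param add An [add_spec()]; diameters are drawn up-front with
#'   [sample_diameters()] and inserted in draw order.
#' @param n_discs Total number of discs (`>= 3`).
#' @param aspect_ratio Domain width / height.
#' @param seed Integer seed driving diameter sampling and the construction.
#' @param alpha_init ECS fraction used to size the initial domain area.
#' @param growth_factor Linear growth per failed placement pass.
#' @param max_growth Maximum number of growth passes before giving up.
#' @param gap_tol Minimum surface gap between discs (um).
#' @return A [geometry()] with `provenance = "packed"` and exactly
#'   `n_discs` discs. The realised ECS fraction is in `$alpha`.
#' @export
advancing_front_pack <- function(add, n_discs, aspect_ratio = 1, seed = 1L,
                                 alpha_init = 0.22, growth_factor = 1.03,
                                 max_growth = 500L, gap_tol = 1e-4) {
  stopifnot(inherits(add, "add_spec"))
  if (n_discs < 3) stop("advancing_front_pack: n_discs must be >= 3", call. = FALSE)
  if (aspect_ratio <= 0) stop("advancing_front_pack: bad aspect_ratio", call. = FALSE)
  n <- as.integer(n_discs)
  rr <- sample_diameters(add, n, seed = seed) / 2
  pad <- gap_tol / 2                      # padding so tangency leaves gap_tol

  # domain centred at the origin; translated to the first quadrant on exit
  area0 <- sum(pi * rr^2) / (1 - alpha_init)
  W <- sqrt(area0 * aspect_ratio)
  H <- area0 / W

  x <- numeric(n); y <- numeric(n)
  # initial mutually tangent triplet (with gap_tol clearance)
  x[1] <- 0; y[1] <- 0
  x[2] <- rr[1] + rr[2] + 2 * pad; y[2] <- 0
  cand <- tangent_disc_centers(c(x[1], y[1]), rr[1] + pad,
                               c(x[2], y[2]), rr[2] + pad, rr[3] + pad)
  k3 <- which.max(cand[, 2])
  x[3] <- cand[k3, 1]; y[3] <- cand[k3, 2]
  ctr <- c(mean(x[1:3]), mean(y[1:3]))
  x[1:3] <- x[1:3] - ctr[1]; y[1:3] <- y[1:3] - ctr[2]

  if (n > 3) {
    # --- neighbour cell list -------------------------------------------
    cs <- 2 * max(rr) + 2 * gap_tol        # search radius fits in 3x3 cells
    cells <- new.env(hash = TRUE, parent = emptyenv())
    cell_key <- function(cx, cy)
      paste(floor(cx / cs), floor(cy / cs), sep = ",")
    cell_add <- function(k) {
      key <- cell_key(x[k], y[k])
      cells[[key]] <- c(cells[[key]], k)
    }
    neighbours <- function(cx, cy) {
      ix <- floor(cx / cs); iy <- floor(cy / cs)
      out <- integer(0)
      for (dx in -1:1) for (dy in -1:1) {
        v <- cells[[paste(ix + dx, iy + dy, sep = ",")]]
        if (!is.null(v)) out <- c(out, v)
      }
      out
    }
    for (k in 1:3) cell_add(k)

    overlapping <- function(cx, cy, cr) {
      # disc ids whose clearance to the candidate is below gap_tol
      nb <- neighbours(cx, cy)
      if (!length(nb)) return(integer(0))
      nb[(x[nb] - cx)^2 + (y[nb] - cy)^2 <
           (cr + rr[nb] + gap_tol * (1 - 1e-6))^2]
    }
    ok_inside <- function(cx, cy, cr)
      cx - cr >= -W / 2 && cx + cr <= W / 2 &&
      cy - cr >= -H / 2 && cy + cr <= H / 2

    # --- front: closed polygon as a doubly linked list over disc ids ----
    nxt <- integer(n); prv <- integer(n)
    # orientation 1 -> 2 -> 3 is counter-clockwise (disc 3 lies above the
    # 1-2 edge), so the exterior is to the right of each directed edge
    nxt[1] <- 2L; nxt[2] <- 3L; nxt[3] <- 1L
    prv[2] <- 1L; prv[3] <- 2L; prv[1] <- 3L
    # live-edge list: vertices whose outgoing edge may still host a disc
    lnx <- integer(n); lpv <- integer(n); islive <- logical(n)
    lnx[1] <- 2L; lnx[2] <- 3L; lnx[3] <- 1L
    lpv[2] <- 1L; lpv[3] <- 2L; lpv[1] <- 3L
    islive[1:3] <- TRUE
    nlive <- 3L
    nfront <- 3L                           # vertices currently on the polygon
    kill_edge <- function(v) {
      # remove v from the live list (its outgoing edge is saturated)
      if (!islive[v] || nlive <= 1L) return(invisible())
      islive[v] <<- FALSE
      lnx[lpv[v]] <<- lnx[v]; lpv[lnx[v]] <<- lpv[v]
      nlive <<- nlive - 1L
    }
    revive_edge <- function(v, after) {
      # v's outgoing edge changed: put it back on the live list
      if (islive[v]) return(invisible())
      while (!islive[after]) after <- lnx[after]
      islive[v] <<- TRUE
      lnx[v] <<- lnx[after]; lpv[lnx[after]] <<- v
      lnx[after] <<- v; lpv[v] <<- after
      nlive <<- nlive + 1L
    }
    splice_out <- function(v) {
      # drop a buried vertex from the front polygon entirely
      kill_edge(v)
      p <- prv[v]; q <- nxt[v]
      nxt[p] <<- q; prv[q] <<- p
      nfront <<- nfront - 1L
      p                                    # edge (p, q) replaces (p, v), (v, q)
    }
    r_floor <- add$d_min / 2               # smallest radius the ADD allows

    # exterior-side tangent candidate for edge (a, b) and radius rc
    edge_candidate <- function(a, b, rc) {
      cc <- tangent_disc_centers(c(x[a], y[a]), rr[a] + pad,
                                 c(x[b], y[b]), rr[b] + pad, rc + pad)
      if (!nrow(cc)) return(NULL)
      if (nrow(cc) == 1L) return(cc[1, ])
      cr <- (x[b] - x[a]) * (cc[, 2] - y[a]) - (y[b] - y[a]) * (cc[, 1] - x[a])
      if (abs(cr[1]) < 1e-12 && abs(cr[2]) < 1e-12) {
        # degenerate: tie-break by distance from the domain centroid
        return(cc[which.max(cc[, 1]^2 + cc[, 2]^2), ])
      }
      cc[which.min(cr), ]                  # most negative cross = right side
    }

    # attempt one edge: may absorb buried front vertices (classic front
    # cleanup: a candidate overlapping the previous / next front vertex
    # means that vertex is covered and leaves the polygon)
    try_edge <- function(e, rk) {
      a <- e
      for (guard in 1:64) {
        b <- nxt[a]
        cc <- edge_candidate(a, b, rk)
        if (is.null(cc)) return(list(status = "fail"))
        if (!ok_inside(cc[1], cc[2], rk)) return(list(status = "wall"))
        bad <- overlapping(cc[1], cc[2], rk)
        if (!length(bad)) return(list(status = "ok", xy = cc, a = a, b = b))
        if (nfront > 3L && prv[a] %in% bad) { a <- splice_out(a); next }
        if (nfront > 3L && nxt[b] %in% bad) { splice_out(b); next }
        # blocked by a non-adjacent disc: if not even the smallest
        # admissible disc fits here, the edge is saturated for good
        if (rk > r_floor) {
          cf <- edge_candidate(a, b, r_floor)
          if (!is.null(cf) && ok_inside(cf[1], cf[2], r_floor) &&
              length(overlapping(cf[1], cf[2], r_floor)))
            return(list(status = "dead", a = a))
        }
        return(list(status = "fail"))
      }
      list(status = "fail")
    }

    pos <- 3L                              # traversal pointer (live vertex)
    for (k in 4:n) {
      rk <- rr[k]
      ngrow <- 0L
      placed <- FALSE
      while (!placed) {
        while (!islive[pos]) pos <- lnx[pos]  # pointer may have been killed
        e <- pos
        tried <- 0L
        budget <- nlive
        while (tried < budget && nlive > 0L) {
          while (!islive[e]) e <- lnx[e]
          nxt_e <- lnx[e]                  # read before kills / splices
          res <- try_edge(e, rk)
          if (res$status == "ok") {
            a <- res$a; b <- res$b
            x[k] <- res$xy[1]; y[k] <- res$xy[2]
            nxt[a] <- k; prv[k] <- a; nxt[k] <- b; prv[b] <- k
            nfront <- nfront + 1L
            islive[k] <- TRUE              # splice k into the live list
            anchor <- a
            while (!islive[anchor]) anchor <- lnx[anchor]
            lnx[k] <- lnx[anchor]; lpv[lnx[anchor]] <- k
            lnx[anchor] <- k; lpv[k] <- anchor
            nlive <- nlive + 1L
            if (!islive[a]) revive_edge(a, k)  # its edge is now (a, k)
            cell_add(k)
            pos <- k
            placed <- TRUE
            break
          }
          if (res$status == "dead") kill_edge(res$a)
          e <- nxt_e
          tried <- tried + 1L
        }
        if (placed) break
        ngrow <- ngrow + 1L
        if (ngrow > max_growth || nlive == 0L)
          stop(sprintf(paste0("advancing_front_pack: failed to place disc ",
                              "%d of %d after %d domain growth passes"),
                       k, n, ngrow - 1L), call. = FALSE)
        W <- W * growth_factor; H <- H * growth_factor
      }
    }
  } else {
    # only the triplet: make sure the initial domain contains it
    while (any(abs(x[1:3]) + rr[1:3] > W / 2) ||
           any(abs(y[1:3]) + rr[1:3] > H / 2)) {
      W <- W * growth_factor; H <- H * growth_factor
    }
  }

  discs <- data.frame(x = x + W / 2, y = y + H / 2, r = rr)
  geometry(discs, c(W, H), seed = as.integer(seed), provenance = "packed",
           add = add, gap_tol = gap_tol, check = TRUE)
}
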