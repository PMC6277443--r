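#' Sample one random fiber spanning a square
#'
#' Draws a straight fiber whose endpoints lie on two opposing sides of the
#' \code{[0, L] x [0, L]} square. The side pair (left-right versus top-bottom)
#' is chosen with probability 1/2 each, and each endpoint is uniform along its
#' side, so the resulting web is statistically isotropic. Every fiber is a
#' chord between opposing sides and therefore has length at least \code{L}.
#'
#' Uses the current R random number stream; call \code{set.seed()} first for
#' reproducibility (\code{\link{generate_web}} does this for you).
#'
#' @param L side length of the square (distance units; 1 unit corresponds to
#'   1 micrometre for physical samples).
#' @return A named list with elements \code{x0, y0, x1, y1} (endpoints) and
#'   \code{length}.
#' @examples
#' set.seed(1)
#' f <- sample_fiber(1000)
#' f$length >= 1000
#' @export
sample_fiber <- function(L) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  horizontal <- stats::runif(1) < 0.5
  a <- stats::runif(1, 0, L)
  b <- stats::runif(1, 0, L)
  if (horizontal) {
    f <- list(x0 = 0, y0 = a, x1 = L, y1 = b)
  } else {
    f <- list(x0 = a, y0 = 0, x1 = b, y1 = L)
  }
  f$length <- sqrt((f$x1 - f$x0)^2 + (f$y1 - f$y0)^2)
  f
}

#' Intersection point of two open segments
#'
#' Returns the crossing point of the centerlines of two fibers, or \code{NULL}
#' when the open segments do not cross. Parallel and near-parallel pairs
#' (crossing angle below \code{1e-9} rad) are treated as non-crossing, as are
#' collinear overlaps: such contacts produce no electrical junction in the
#' web model.
#'
#' @param a,b fibers as returned by \code{\link{sample_fiber}} (lists with
#'   \code{x0, y0, x1, y1}).
#' @return Numeric vector \code{c(x, y)} or \code{NULL}.
#' @examples
#' a <- list(x0 = 0, y0 = 0, x1 = 10, y1 = 10)
#' b <- list(x0 = 0, y0 = 10, x1 = 10, y1 = 0)
#' intersect_segments(a, b)  # (5, 5)
#' @export
intersect_segments <- function(a, b) {
  hit <- .cross_many(a$x0, a$y0, a$x1, a$y1,
                     b$x0, b$y0, b$x1, b$y1)
  if (!hit$crosses[1]) return(NULL)
  c(hit$x[1], hit$y[1])
}

# Vectorized segment crossing: one segment (p) against many (q*).
# Returns crossing flags, intersection coordinates, parameters along both
# segments and sin of the crossing angle. Open-segment semantics; pairs with
# sin(theta) < 1e-9 are reported as non-crossing.
.cross_many <- function(px0, py0, px1, py1, qx0, qy0, qx1, qy1) {
  dx1 <- px1 - px0; dy1 <- py1 - py0
  dx2 <- qx1 - qx0; dy2 <- qy1 - qy0
  denom <- dx1 * dy2 - dy1 * dx2
  len1 <- sqrt(dx1^2 + dy1^2)
  len2 <- sqrt(dx2^2 + dy2^2)
  sin_theta <- abs(denom) / (len1 * len2)
  ok <- sin_theta >= 1e-9
  t <- u <- x <- y <- rep(NA_real_, length(qx0))
  if (any(ok)) {
    rx <- qx0[ok] - px0; ry <- qy0[ok] - py0
    d <- denom[ok]
    t[ok] <- (rx * dy2[ok] - ry * dx2[ok]) / d
    u[ok] <- (rx * dy1 - ry * dx1) / d
  }
  crosses <- ok & t > 0 & t < 1 & u > 0 & u < 1
  crosses[is.na(crosses)] <- FALSE
  x[crosses] <- px0 + t[crosses] * dx1
  y[crosses] <- py0 + t[crosses] * dy1
  list(crosses = crosses, x = x, y = y, t = t, u = u, sin_theta = sin_theta)
}

#' Overlap area of two crossing fiber strips
#'
#' Two straight strips of width \code{w} crossing at acute angle \code{theta}
#' share a parallelogram of area \code{w^2 / sin(theta)}. For near-parallel
#' crossings this blows up, so the value is capped at
#' \code{w * min(length_a, length_b)} (one strip lying fully inside the
#' other). Used by \code{\link{generate_web}} to correct the covered-area
#' bookkeeping once per crossing pair.
#'
#' @param a,b crossing fibers (lists with endpoints and \code{length}).
#' @param w strip width.
#' @return Overlap area (same units squared).
#' @examples
#' a <- list(x0 = 0, y0 = 5, x1 = 10, y1 = 5, length = 10)
#' b <- list(x0 = 5, y0 = 0, x1 = 5, y1 = 10, length = 10)
#' pair_overlap_area(a, b, w = 1)  # 1: perpendicular crossing
#' @export
pair_overlap_area <- function(a, b, w) {
  stopifnot(w > 0)
  dx1 <- a$x1 - a$x0; dy1 <- a$y1 - a$y0
  dx2 <- b$x1 - b$x0; dy2 <- b$y1 - b$y0
  la <- sqrt(dx1^2 + dy1^2); lb <- sqrt(dx2^2 + dy2^2)
  sin_theta <- abs(dx1 * dy2 - dy1 * dx2) / (la * lb)
  if (sin_theta < 1e-9)
    stop("pair_overlap_area() requires crossing (non-parallel) fibers")
  min(w^2 / sin_theta, w * min(la, lb))
}

#' Generate a random fiber web at a target transmittance
#'
#' Builds a web of straight fibers of width \code{w} on an \code{L x L}
#' square. Fibers are appended one at a time (\code{\link{sample_fiber}});
#' after each addition the fiber's area \code{length * w} is added to the
#' covered-area tally, every crossing with an earlier fiber is recorded as a
#' junction, and each pairwise overlap parallelogram is subtracted exactly
#' once. Generation stops at the first fiber for which the covered area
#' reaches \code{(1 - target_T) * L^2}, so the bookkept transmittance
#' \code{1 - covered_area / L^2} lands within one fiber's area below
#' \code{target_T}.
#'
#' Overlaps are corrected pairwise only (truncated inclusion-exclusion);
#' regions where three or more fibers stack are over-subtracted. At the
#' operating transmittances of interest (>= 0.85) the resulting bias is below
#' 0.005, as checked against the rasterization oracle
#' \code{\link{measured_transmittance}}. The same truncation bounds the
#' reachable density: the covered-area tally peaks around 45\% coverage and
#' then declines, so very low transmittance targets (roughly below 0.55)
#' are unreachable and abort with a stall diagnostic.
#'
#' @param L side length of the square.
#' @param w fiber width (the reference configuration uses \code{w = 1}).
#' @param target_T target geometric transmittance in \code{[0, 1)}: the
#'   fraction of the square not covered by fibers.
#' @param seed integer seed; recorded in the result for provenance.
#' @param thickness fiber thickness, carried as metadata only (resistance is
#'   per unit length, so thickness enters no computation). Default 0.2.
#' @param max_fibers guard against non-termination for degenerate
#'   configurations; generation aborts with an error beyond this count.
#' @return An object of class \code{fiber_web}: a list with \code{L}, \code{w},
#'   \code{thickness}, \code{target_T}, \code{seed}, \code{covered_area},
#'   \code{fibers} (data.frame \code{id, x0, y0, x1, y1, length}) and
#'   \code{junctions} (data.frame \code{x, y, fiber_a, fiber_b, t_a, t_b}
#'   where \code{t_a}/\code{t_b} are the positions of the junction along each
#'   parent fiber as a fraction of its length).
#' @examples
#' web <- generate_web(L = 200, w = 1, target_T = 0.9, seed = 42)
#' web
#' bookkept_transmittance(web)
#' @seealso \code{\link{measured_transmittance}}, \code{\link{build_graph}}
#' @export
generate_web <- function(L, w, target_T, seed, thickness = 0.2,
                         max_fibers = 1e6) {
  stopifnot(L > 0, w > 0, target_T >= 0, target_T < 1)
  set.seed(as.integer(seed))
  required <- (1 - target_T) * L^2

  cap <- 4096L
  x0 <- y0 <- x1 <- y1 <- len <- numeric(cap)
  jx <- jy <- jta <- jtb <- numeric(0)
  ja <- jb <- integer(0)
  covered <- 0
  n <- 0L
  best_covered <- 0
  best_n <- 0L

  while (covered < required) {
    if (n >= max_fibers)
      stop("generate_web(): fiber count exceeded max_fibers = ", max_fibers,
           " before reaching the target coverage")
    # The pairwise-truncated bookkeeping over-subtracts triple overlaps, so
    # the covered-area tally peaks (around 45% coverage) and then declines:
    # dense targets are unreachable and the loop would spin to max_fibers.
    if (n - best_n > 500L)
      stop("generate_web(): covered area stalled at ",
           sprintf("%.3f", best_covered / L^2), " of the square (target ",
           sprintf("%.3f", required / L^2), "); transmittances this low are ",
           "unreachable under pairwise overlap bookkeeping")
    f <- sample_fiber(L)
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(x0) <- cap; length(y0) <- cap
      length(x1) <- cap; length(y1) <- cap; length(len) <- cap
    }
    x0[n] <- f$x0; y0[n] <- f$y0; x1[n] <- f$x1; y1[n] <- f$y1
    len[n] <- f$length
    covered <- covered + f$length * w

    if (n > 1L) {
      prev <- seq_len(n - 1L)
      hit <- .cross_many(f$x0, f$y0, f$x1, f$y1,
                         x0[prev], y0[prev], x1[prev], y1[prev])
      cr <- hit$crosses
      if (any(cr)) {
        overlap <- pmin(w^2 / hit$sin_theta[cr],
                        w * pmin(len[prev][cr], f$length))
        covered <- covered - sum(overlap)
        jx <- c(jx, hit$x[cr]); jy <- c(jy, hit$y[cr])
        ja <- c(ja, prev[cr]);  jb <- c(jb, rep.int(n, sum(cr)))
        jta <- c(jta, hit$u[cr]); jtb <- c(jtb, hit$t[cr])
      }
    }
    if (covered > best_covered) {
      best_covered <- covered
      best_n <- n
    }
  }

  web <- list(
    L = L, w = w, thickness = thickness, target_T = target_T,
    seed = as.integer(seed), covered_area = covered,
    fibers = data.frame(id = seq_len(n), x0 = x0[seq_len(n)],
                        y0 = y0[seq_len(n)], x1 = x1[seq_len(n)],
                        y1 = y1[seq_len(n)], length = len[seq_len(n)]),
    junctions = data.frame(x = jx, y = jy, fiber_a = ja, fiber_b = jb,
                           t_a = jta, t_b = jtb)
  )
  class(web) <- "fiber_web"
  web
}

#' Bookkept transmittance of a fiber web
#'
#' The geometric transmittance implied by the web's running covered-area
#' tally: \code{1 - covered_area / L^2}. In the shadow-loss model this is the
#' fraction of the sample that transmits light.
#'
#' @param web a \code{fiber_web}.
#' @return Transmittance fraction in \code{[0, 1]}.
#' @export
bookkept_transmittance <- function(web) {
  stopifnot(inherits(web, "fiber_web"))
  1 - web$covered_area / web$L^2
}

#' Rasterized (oracle) transmittance of a fiber web
#'
#' Rasterizes every width-\code{w} fiber strip onto a square grid of the
#' given cell size and returns the fraction of cells whose center is not
#' covered. This is the exact-coverage oracle used to validate the pairwise
#' overlap-area bookkeeping of \code{\link{generate_web}}: the two measures
#' agree within 0.005 for webs with transmittance >= 0.85 at
#' \code{cell = w/4}.
#'
#' Each fiber strip is modelled as the parallelogram of area
#' \code{length * w} around its centerline (vertical or horizontal extent
#' \code{w / cos(theta)} depending on orientation), clipped to the square.
#'
#' @param web a \code{fiber_web}.
#' @param cell raster cell size; must satisfy \code{cell <= w/2} so the strip
#'   is resolved.
#' @return Uncovered-cell fraction in \code{[0, 1]}.
#' @export
measured_transmittance <- function(web, cell) {
  stopifnot(inherits(web, "fiber_web"), cell > 0)
  if (cell > web$w / 2)
    stop("measured_transmittance(): cell must be <= w/2 to resolve fibers")
  L <- web$L; w <- web$w
  ncell <- max(1L, as.integer(round(L / cell)))
  cell <- L / ncell                      # snap so the grid tiles the square
  covered <- matrix(FALSE, nrow = ncell, ncol = ncell)  # [row = y, col = x]
  centers <- (seq_len(ncell) - 0.5) * cell
  fb <- web$fibers
  for (i in seq_len(nrow(fb))) {
    dx <- fb$x1[i] - fb$x0[i]; dy <- fb$y1[i] - fb$y0[i]
    if (abs(dx) >= abs(dy)) {
      # sweep columns: vertical half-extent of the strip at fixed x
      m <- dy / dx
      half <- (w / 2) * sqrt(1 + m^2)
      xr <- range(fb$x0[i], fb$x1[i])
      ix <- which(centers >= xr[1] & centers <= xr[2])
      if (!length(ix)) next
      yc <- fb$y0[i] + m * (centers[ix] - fb$x0[i])
      lo <- pmax(1L, ceiling((yc - half) / cell + 0.5))
      hi <- pmin(ncell, floor((yc + half) / cell + 0.5))
      keep <- hi >= lo
      if (!any(keep)) next
      ix <- ix[keep]; lo <- lo[keep]; hi <- hi[keep]
      nrun <- hi - lo + 1L
      rows <- sequence(nrun) + rep.int(lo - 1L, nrun)
      cols <- rep.int(ix, nrun)
      covered[cbind(rows, cols)] <- TRUE
    } else {
      m <- dx / dy
      half <- (w / 2) * sqrt(1 + m^2)
      yr <- range(fb$y0[i], fb$y1[i])
      iy <- which(centers >= yr[1] & centers <= yr[2])
      if (!length(iy)) next
      xc <- fb$x0[i] + m * (centers[iy] - fb$y0[i])
      lo <- pmax(1L, ceiling((xc - half) / cell + 0.5))
      hi <- pmin(ncell, floor((xc + half) / cell + 0.5))
      keep <- hi >= lo
      if (!any(keep)) next
      iy <- iy[keep]; lo <- lo[keep]; hi <- hi[keep]
      nrun <- hi - lo + 1L
      cols <- sequence(nrun) + rep.int(lo - 1L, nrun)
      rows <- rep.int(iy, nrun)
      covered[cbind(rows, cols)] <- TRUE
    }
  }
  1 - sum(covered) / length(covered)
}

#' @export
print.fiber_web <- function(x, ...) {
  cat("Random fiber web\n")
  cat(sprintf("  square:        %g x %g (fiber width %g, thickness %g)\n",
              x$L, x$L, x$w, x$thickness))
  cat(sprintf("  fibers:        %d\n", nrow(x$fibers)))
  cat(sprintf("  junctions:     %d\n", nrow(x$junctions)))
  cat(sprintf("  transmittance: %.4f (target %.4f), seed %d\n",
              bookkept_transmittance(x), x$target_T, x$seed))
  invisible(x)
}
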