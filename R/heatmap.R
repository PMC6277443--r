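#' Rasterize Joule power onto a spatial grid
#'
#' Distributes each fiber edge's dissipated power uniformly along its
#' segment into the grid cells the segment traverses (length-weighted
#' deposition by exact segment-cell clipping, so long edges do not alias
#' onto their endpoints' cells). Contact edges are excluded: they are an
#' electrode-model artifact, not part of the heater. The cell values sum to
#' the total fiber-edge power, at any cell size.
#'
#' Uniform linear power density along an edge is exact for a homogeneous
#' resistive segment at DC. The map reports dissipated power per cell, not
#' temperature; thermal transport is outside the model.
#'
#' @param solution a \code{circuit_solution} from \code{\link{solve_dc}}.
#' @param graph the \code{web_graph} that was solved (node coordinates).
#' @param cell grid cell size; must be at most \code{L/10} for a meaningful
#'   map.
#' @return An object of class \code{power_map}: list with \code{grid}
#'   (matrix, rows = y from bottom, cols = x from left), \code{cell},
#'   \code{origin}, \code{applied_voltage}.
#' @examples
#' # maps at 1, 3, 5, 8 V differ only by the factor V^2 (static regime)
#' @export
rasterize_power <- function(solution, graph, cell) {
  stopifnot(inherits(solution, "circuit_solution"),
            inherits(graph, "web_graph"), cell > 0)
  L <- graph$L
  if (cell > L / 10)
    stop("rasterize_power(): cell must be <= L/10")
  ncell <- max(1L, as.integer(round(L / cell)))
  cell <- L / ncell
  grid <- matrix(0, nrow = ncell, ncol = ncell)

  fiber <- graph$edges$kind == "fiber"
  P <- solution$edge_powers[fiber]
  use <- which(P > 0)
  if (length(use)) {
    ef <- graph$edges$from[fiber][use]
    et <- graph$edges$to[fiber][use]
    x0 <- graph$nodes$x[ef]; y0 <- graph$nodes$y[ef]
    x1 <- graph$nodes$x[et]; y1 <- graph$nodes$y[et]
    P <- P[use]
    ne <- length(use)

    # breakpoints where each segment crosses a grid line, as fractions t
    cross_t <- function(a0, a1) {
      klo <- floor(pmin(a0, a1) / cell) + 1L
      khi <- ceiling(pmax(a0, a1) / cell) - 1L
      nk <- pmax(0L, khi - klo + 1L)
      eid <- rep.int(seq_len(ne), nk)
      k <- sequence(nk) + rep.int(klo - 1L, nk)
      list(eid = eid, t = (k * cell - a0[eid]) / (a1[eid] - a0[eid]))
    }
    cx <- cross_t(x0, x1)
    cy <- cross_t(y0, y1)
    eid <- c(seq_len(ne), seq_len(ne), cx$eid, cy$eid)
    t <- c(rep(0, ne), rep(1, ne), cx$t, cy$t)
    o <- order(eid, t)
    eid <- eid[o]; t <- t[o]
    n <- length(t)
    same <- eid[-1L] == eid[-n]
    dt <- (t[-1L] - t[-n])[same]
    e <- eid[-n][same]
    tm <- ((t[-1L] + t[-n]) / 2)[same]
    xm <- x0[e] + tm * (x1[e] - x0[e])
    ym <- y0[e] + tm * (y1[e] - y0[e])
    ix <- pmin(ncell, pmax(1L, floor(xm / cell) + 1L))
    iy <- pmin(ncell, pmax(1L, floor(ym / cell) + 1L))
    dep <- P[e] * dt
    lin <- (ix - 1L) * ncell + iy
    acc <- rowsum(dep, lin)
    grid[as.integer(rownames(acc))] <- grid[as.integer(rownames(acc))] + acc[, 1]
  }

  out <- list(grid = grid, cell = cell, origin = c(0, 0),
              applied_voltage = solution$applied_voltage)
  class(out) <- "power_map"
  out
}

#' Summary statistics of a power map
#'
#' Quantifies how unevenly a fiber-web heater dissipates power: the total
#' and maximum cell power, the Gini coefficient over traversed (positive)
#' cells, and — when the underlying solution is supplied — the fraction of
#' edges that together carry at least 99% of the total power. In sparse webs
#' current concentrates in a small number of fibers that directly connect
#' the electrodes, so this fraction is well below 1.
#'
#' @param map a \code{power_map}.
#' @param solution optional \code{circuit_solution} for the edge-level
#'   concentration statistic.
#' @param q power quantile for the concentration statistic (default 0.99).
#' @return List with \code{total_power}, \code{max_cell}, \code{gini},
#'   \code{edge_fraction_99} (NA without \code{solution}), and
#'   \code{degenerate} flag for all-zero maps (where concentration is
#'   undefined).
#' @export
map_summary <- function(map, solution = NULL, q = 0.99) {
  stopifnot(inherits(map, "power_map"))
  v <- as.numeric(map$grid)
  total <- sum(v)
  if (total <= 0) {
    return(list(total_power = 0, max_cell = 0, gini = NA_real_,
                edge_fraction_99 = NA_real_, degenerate = TRUE))
  }
  pos <- sort(v[v > 0])
  n <- length(pos)
  gini <- sum((2 * seq_len(n) - n - 1) * pos) / (n * sum(pos))
  ef <- NA_real_
  if (!is.null(solution)) {
    p <- solution$edge_powers[solution$edges$kind == "fiber"]
    n_edges <- length(p)
    p <- sort(p[p > 0], decreasing = TRUE)
    ef <- min(which(cumsum(p) >= q * sum(p))) / n_edges
  }
  list(total_power = total, max_cell = max(v), gini = gini,
       edge_fraction_99 = ef, degenerate = FALSE)
}

#' @export
print.power_map <- function(x, ...) {
  cat(sprintf("Power map: %d x %d cells of size %g at %g V, total %.6g W\n",
              nrow(x$grid), ncol(x$grid), x$cell, x$applied_voltage,
              sum(x$grid)))
  invisible(x)
}
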