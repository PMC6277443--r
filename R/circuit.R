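#' Resistance of a fiber segment
#'
#' The model assumes uniform cross-section and conductivity along every
#' fiber, so an inter-junction segment is characterized by its length alone:
#' \code{R = rho_lin * length}, with \code{rho_lin} the linear resistivity in
#' ohm per unit length. The reference value \code{rho_lin = 0.04} ohm/unit
#' corresponds to sputtered gold films thicker than 100 nm when one distance
#' unit is one micrometre.
#'
#' @param length segment length (> 0).
#' @param rho_lin linear resistivity in ohm per unit length (> 0).
#' @return Resistance in ohm.
#' @examples
#' edge_resistance(1000, 0.04)  # 40 ohm
#' @export
edge_resistance <- function(length, rho_lin = 0.04) {
  stopifnot(all(length > 0), rho_lin > 0)
  rho_lin * length
}

# per-edge resistance vector for a graph (fiber edges by length, contact
# edges by the stored contact resistance)
.edge_resistances <- function(graph, rho_lin) {
  r <- numeric(nrow(graph$edges))
  fiber <- graph$edges$kind == "fiber"
  r[fiber] <- edge_resistance(graph$edges$length[fiber], rho_lin)
  r[!fiber] <- graph$contact_resistance
  r
}

#' Solve the DC operating point of a web graph
#'
#' Performs nodal analysis of the resistor network: assembles the sparse
#' weighted-Laplacian (node-conductance) matrix, imposes Dirichlet values
#' \code{V} at the source and \code{0} at the sink, and solves the reduced
#' symmetric positive-definite system restricted to the connected component
#' containing both terminals. Components touching at most one terminal are
#' floating: they carry no current and their nodes are reported at potential
#' 0 with an explicit marker, never mixed silently with driven nodes.
#'
#' A graph whose terminals are not connected by any path is non-percolating:
#' the solution is returned with \code{percolating = FALSE}, infinite
#' equivalent resistance and all-zero currents (this is a valid outcome for
#' sparse webs, not an error).
#'
#' @param graph a \code{web_graph} with electrodes attached.
#' @param V applied source-sink voltage in volt.
#' @param rho_lin linear resistivity in ohm per unit length.
#' @return An object of class \code{circuit_solution}: list with
#'   \code{applied_voltage}, \code{node_potentials} (volt, one per node),
#'   \code{floating} (logical per node), \code{edge_currents},
#'   \code{edge_powers}, \code{total_current}, \code{equivalent_resistance},
#'   \code{percolating}, and a copy of the edge table with per-edge
#'   resistance.
#' @examples
#' # a single spanning fiber of length 1000 at rho 0.04 gives R = 40 ohm
#' @seealso \code{\link{sheet_resistance}}, \code{\link{rasterize_power}}
#' @export
solve_dc <- function(graph, V = 1, rho_lin = 0.04) {
  stopifnot(inherits(graph, "web_graph"))
  if (is.na(graph$source))
    stop("solve_dc(): attach electrodes first (see attach_electrodes)")
  nn <- nrow(graph$nodes)
  ne <- nrow(graph$edges)
  src <- graph$source; snk <- graph$sink
  res <- .edge_resistances(graph, rho_lin)

  empty <- function(percolating = FALSE) {
    out <- list(
      applied_voltage = V,
      node_potentials = numeric(nn),
      floating = rep(TRUE, nn),
      edges = cbind(graph$edges, resistance = res),
      edge_currents = numeric(ne),
      edge_powers = numeric(ne),
      total_current = 0,
      equivalent_resistance = Inf,
      percolating = percolating
    )
    class(out) <- "circuit_solution"
    out
  }
  if (ne == 0L) return(empty())

  ig <- igraph::graph_from_edgelist(
    cbind(graph$edges$from, graph$edges$to), directed = FALSE)
  if (igraph::vcount(ig) < nn)
    ig <- igraph::add_vertices(ig, nn - igraph::vcount(ig))
  comp <- igraph::components(ig)$membership
  if (comp[src] != comp[snk]) return(empty())
  live <- comp == comp[src]

  g <- 1 / res
  # Laplacian over live nodes only
  keep_e <- live[graph$edges$from]     # both ends live iff one end is
  ef <- graph$edges$from[keep_e]; et <- graph$edges$to[keep_e]
  ge <- g[keep_e]
  idx <- which(live)
  map <- integer(nn); map[idx] <- seq_along(idx)
  ef <- map[ef]; et <- map[et]
  nl <- length(idx)
  Lap <- Matrix::sparseMatrix(
    i = c(ef, et, ef, et), j = c(et, ef, ef, et),
    x = c(-ge, -ge, ge, ge), dims = c(nl, nl))

  bset <- c(map[src], map[snk])
  vb <- c(V, 0)
  int <- setdiff(seq_len(nl), bset)
  phi_l <- numeric(nl)
  phi_l[bset] <- vb
  if (length(int)) {
    rhs <- -Lap[int, bset, drop = FALSE] %*% vb
    A <- Matrix::forceSymmetric(Lap[int, int])   # SPD: sparse Cholesky path
    ch <- Matrix::Cholesky(A)
    x <- Matrix::solve(ch, rhs)
    for (it in 1:2) {                            # iterative refinement
      r <- rhs - A %*% x
      x <- x + Matrix::solve(ch, r)
    }
    phi_l[int] <- as.numeric(x)
  }

  phi <- numeric(nn)
  phi[idx] <- phi_l
  dv <- phi[graph$edges$from] - phi[graph$edges$to]
  dv[!keep_e] <- 0
  cur <- dv / res
  pow <- dv * cur

  # Edges whose resistance sits many orders below their neighbours' pair a
  # potential drop near the rounding floor of phi with a huge conductance,
  # so dv/R there is numerically meaningless; their current is recovered by
  # Kirchhoff closure from well-conditioned neighbouring currents instead.
  # Two such families exist: near-coincident-junction fiber stubs (shorter
  # than 1e-6 * L) and the 1e-9 ohm contact edges.
  terminal_flag <- graph$nodes$type == "terminal"
  short <- which(graph$edges$kind == "fiber" &
                 graph$edges$length < 1e-6 * graph$L & keep_e)
  if (length(short)) {
    # clusters of nearly coincident junctions form connected subgraphs of
    # short edges (chains, or cycles when three fibers cross within the
    # tolerance). Re-solve each cluster locally: boundary currents from the
    # well-conditioned long edges enter as Neumann injections, and the
    # cluster's internal Laplacian (scale-free among its own conductances)
    # yields currents satisfying Kirchhoff at every cluster node.
    is_short <- logical(ne)
    is_short[short] <- TRUE
    sub <- igraph::graph_from_edgelist(
      cbind(graph$edges$from[short], graph$edges$to[short]),
      directed = FALSE)
    memb <- igraph::components(sub)$membership
    vs <- which(memb > 0 & igraph::degree(sub) > 0)
    for (cid in unique(memb[vs])) {
      vc <- vs[memb[vs] == cid]
      if (any(terminal_flag[vc])) next
      inc <- which(graph$edges$from %in% vc | graph$edges$to %in% vc)
      internal <- graph$edges$from[inc] %in% vc &
                  graph$edges$to[inc] %in% vc
      ec <- inc[internal]
      bnd <- inc[!internal]
      if (any(graph$edges$kind[bnd] == "contact") || !length(bnd)) next
      # Dirichlet data: far-endpoint potentials, taken relative to one of
      # them so that tiny in-cluster drops survive double precision
      bf <- graph$edges$from[bnd]; bt <- graph$edges$to[bnd]
      far <- ifelse(bf %in% vc, bt, bf)
      own <- ifelse(bf %in% vc, bf, bt)
      ref <- phi[far[1]]
      d_far <- phi[far] - ref
      k <- length(vc)
      li <- match(graph$edges$from[ec], vc)
      lj <- match(graph$edges$to[ec], vc)
      gl <- 1 / res[ec]
      gb <- 1 / res[bnd]
      vo <- match(own, vc)
      A <- matrix(0, k, k)
      rhs <- numeric(k)
      for (m in seq_along(ec)) {
        A[li[m], lj[m]] <- A[li[m], lj[m]] - gl[m]
        A[lj[m], li[m]] <- A[lj[m], li[m]] - gl[m]
        A[li[m], li[m]] <- A[li[m], li[m]] + gl[m]
        A[lj[m], lj[m]] <- A[lj[m], lj[m]] + gl[m]
      }
      for (m in seq_along(bnd)) {
        A[vo[m], vo[m]] <- A[vo[m], vo[m]] + gb[m]
        rhs[vo[m]] <- rhs[vo[m]] + gb[m] * d_far[m]
      }
      y <- solve(A, rhs)
      cur[ec] <- gl * (y[li] - y[lj])
      pow[ec] <- cur[ec]^2 * res[ec]
      # boundary currents from the corrected cluster potentials
      dvb <- ifelse(bf %in% vc, y[vo] - d_far, d_far - y[vo])
      cur[bnd] <- dvb * gb
      pow[bnd] <- cur[bnd]^2 * res[bnd]
      phi[vc] <- ref + y
    }
  }
  contact <- which(graph$edges$kind == "contact")
  if (length(contact)) {
    terminal <- graph$nodes$type == "terminal"
    cnode <- ifelse(terminal[graph$edges$from[contact]],
                    graph$edges$to[contact], graph$edges$from[contact])
    single <- contact[cnode %in%
      as.integer(names(which(table(cnode) == 1L))) & !terminal[cnode]]
    if (length(single)) {
      v <- ifelse(terminal[graph$edges$from[single]],
                  graph$edges$to[single], graph$edges$from[single])
      net <- rowsum(c(cur, -cur),
                    c(graph$edges$to, graph$edges$from))
      net_v <- numeric(nn)
      net_v[as.integer(rownames(net))] <- net[, 1]
      contrib <- ifelse(graph$edges$to[single] == v, cur[single],
                        -cur[single])
      inflow <- net_v[v] - contrib
      cur[single] <- ifelse(graph$edges$from[single] == v, inflow, -inflow)
    }
    pow[contact] <- cur[contact]^2 * res[contact]
  }

  # current injected at the source terminal
  at_src <- graph$edges$from == src | graph$edges$to == src
  sgn <- ifelse(graph$edges$from[at_src] == src, 1, -1)
  I <- sum(sgn * cur[at_src])

  out <- list(
    applied_voltage = V,
    node_potentials = phi,
    floating = !live,
    edges = cbind(graph$edges, resistance = res),
    edge_currents = cur,
    edge_powers = pow,
    total_current = I,
    equivalent_resistance = if (I > 0) V / I else Inf,
    percolating = TRUE
  )
  class(out) <- "circuit_solution"
  out
}

#' Sheet resistance of a square web
#'
#' Applies 1 V across the bus bars of a square sample and divides by the
#' current through the source, yielding the sheet resistance in ohm per
#' square. For a square geometry this equals the equivalent resistance.
#' Non-percolating webs give \code{Inf}.
#'
#' @inheritParams solve_dc
#' @return Sheet resistance in ohm per square.
#' @export
sheet_resistance <- function(graph, rho_lin = 0.04) {
  sol <- solve_dc(graph, V = 1, rho_lin = rho_lin)
  sol$equivalent_resistance
}

#' Per-edge Joule power of a solved network
#'
#' For every edge the dissipated power is \code{P = (dV)^2 / R}, with
#' \code{dV} the potential drop across the edge; the per-edge current
#' \code{I = dV / R} is available as \code{solution$edge_currents}. The sum
#' over all edges equals \code{V * I_total} (energy conservation).
#'
#' @param solution a \code{circuit_solution}.
#' @return Numeric vector of edge powers in watt.
#' @export
edge_power <- function(solution) {
  stopifnot(inherits(solution, "circuit_solution"))
  solution$edge_powers
}

#' @export
print.circuit_solution <- function(x, ...) {
  cat("DC operating point\n")
  cat(sprintf("  applied voltage: %g V\n", x$applied_voltage))
  if (x$percolating) {
    cat(sprintf("  total current:   %.6g A\n", x$total_current))
    cat(sprintf("  equivalent R:    %.6g ohm\n", x$equivalent_resistance))
    cat(sprintf("  dissipated P:    %.6g W over %d edges\n",
                sum(x$edge_powers), length(x$edge_powers)))
  } else {
    cat("  non-percolating: no conductive path between electrodes\n")
  }
  invisible(x)
}
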