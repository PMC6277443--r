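# Fixture builders and independent oracles, constructed in code.

# fiber_web from explicit fiber endpoints; junctions and covered area are
# recomputed here with the exported geometric primitives so build_graph()
# tests do not depend on generate_web()'s internals.
make_web <- function(coords, L, w = 1) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 4, byrow = TRUE)
  n <- nrow(coords)
  fibers <- data.frame(
    id = seq_len(n), x0 = coords[, 1], y0 = coords[, 2],
    x1 = coords[, 3], y1 = coords[, 4])
  fibers$length <- sqrt((fibers$x1 - fibers$x0)^2 + (fibers$y1 - fibers$y0)^2)
  jx <- jy <- jta <- jtb <- numeric(0)
  ja <- jb <- integer(0)
  covered <- sum(fibers$length * w)
  tpar <- function(f, p) {
    dx <- f$x1 - f$x0; dy <- f$y1 - f$y0
    ((p[1] - f$x0) * dx + (p[2] - f$y0) * dy) / (dx^2 + dy^2)
  }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- fibers[i, ]; b <- fibers[j, ]
      p <- intersect_segments(a, b)
      if (!is.null(p)) {
        covered <- covered - pair_overlap_area(a, b, w)
        jx <- c(jx, p[1]); jy <- c(jy, p[2])
        ja <- c(ja, i); jb <- c(jb, j)
        jta <- c(jta, tpar(a, p)); jtb <- c(jtb, tpar(b, p))
      }
    }
  }
  web <- list(L = L, w = w, thickness = 0.2,
              target_T = NA_real_, seed = 0L, covered_area = covered,
              fibers = fibers,
              junctions = data.frame(x = jx, y = jy, fiber_a = ja,
                                     fiber_b = jb, t_a = jta, t_b = jtb))
  class(web) <- "fiber_web"
  web
}

empty_web <- function(L, w = 1) {
  make_web(matrix(numeric(0), ncol = 4), L, w)
}

# web_graph from explicit node/edge tables (closed-form circuit fixtures)
make_graph <- function(x, y, type, from, to, length, kind,
                       source, sink, contact_R = 1e-9, L = 100) {
  g <- list(
    nodes = data.frame(id = seq_along(x), x = x, y = y, type = type,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = from, to = to, length = length, kind = kind,
                       stringsAsFactors = FALSE),
    L = L, w = 1, fibers = NULL, occupancy = NULL,
    source = source, sink = sink, contact_resistance = contact_R,
    contacted = c(TRUE, TRUE))
  class(g) <- "web_graph"
  g
}

# random connected resistor graph with two terminals, for the dense oracle
random_test_graph <- function(n, seed, extra_edges = n) {
  set.seed(seed)
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  from <- to <- integer(0)
  for (i in 2:n) { from <- c(from, sample(i - 1L, 1)); to <- c(to, i) }
  for (k in seq_len(extra_edges)) {
    p <- sample(n, 2)
    from <- c(from, p[1]); to <- c(to, p[2])
  }
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  len <- sqrt((x[from] - x[to])^2 + (y[from] - y[to])^2)
  len[len == 0] <- 1
  src <- n + 1L; snk <- n + 2L
  nsrc <- sample(n, 2); nsnk <- sample(setdiff(seq_len(n), nsrc), 2)
  make_graph(
    x = c(x, -5, 105), y = c(y, 50, 50),
    type = c(rep("junction", n), "terminal", "terminal"),
    from = c(from, nsrc, nsnk),
    to = c(to, rep(src, 2), rep(snk, 2)),
    length = c(len, rep(NA, 4)),
    kind = c(rep("fiber", length(from)), rep("contact", 4)),
    source = src, sink = snk)
}

# brute-force dense nodal solve, independent of the package's sparse path
dense_solve <- function(graph, V = 1, rho_lin = 0.04) {
  nn <- nrow(graph$nodes)
  r <- ifelse(graph$edges$kind == "fiber",
              rho_lin * graph$edges$length, graph$contact_resistance)
  g <- 1 / r
  Lap <- matrix(0, nn, nn)
  for (k in seq_along(g)) {
    i <- graph$edges$from[k]; j <- graph$edges$to[k]
    Lap[i, j] <- Lap[i, j] - g[k]; Lap[j, i] <- Lap[j, i] - g[k]
    Lap[i, i] <- Lap[i, i] + g[k]; Lap[j, j] <- Lap[j, j] + g[k]
  }
  b <- c(graph$source, graph$sink)
  int <- setdiff(seq_len(nn), b)
  phi <- numeric(nn)
  phi[b] <- c(V, 0)
  A <- Lap[int, int]
  rhs <- -Lap[int, b] %*% c(V, 0)
  x <- solve(A, rhs)
  x <- x + solve(A, rhs - A %*% x)               # one refinement step
  phi[int] <- x
  # terminal current via Kirchhoff closure at single-contact nodes (the
  # dv/R product across a 1e-9 ohm contact edge is numerically void)
  cur <- (phi[graph$edges$from] - phi[graph$edges$to]) / r
  contact <- which(graph$edges$kind == "contact")
  terminal <- graph$nodes$type == "terminal"
  cnode <- ifelse(terminal[graph$edges$from[contact]],
                  graph$edges$to[contact], graph$edges$from[contact])
  for (k in seq_along(contact)) {
    if (sum(cnode == cnode[k]) > 1L) next
    e <- contact[k]; v <- cnode[k]
    others <- setdiff(which(graph$edges$from == v | graph$edges$to == v), e)
    inflow <- sum(ifelse(graph$edges$to[others] == v, cur[others],
                         -cur[others]))
    cur[e] <- if (graph$edges$from[e] == v) inflow else -inflow
  }
  at_src <- which(graph$edges$from == graph$source |
                  graph$edges$to == graph$source)
  I <- sum(ifelse(graph$edges$from[at_src] == graph$source, 1, -1) *
           cur[at_src])
  list(potentials = phi, R_eq = V / I)
}

# maximum Kirchhoff current residual over internal (non-terminal) nodes,
# relative to the largest edge current
kcl_residual <- function(graph, solution) {
  nn <- nrow(graph$nodes)
  net <- numeric(nn)
  cur <- solution$edge_currents
  net <- net +
    tabulate(graph$edges$from, nbins = nn) * 0   # allocate
  for (k in seq_along(cur)) {
    net[graph$edges$from[k]] <- net[graph$edges$from[k]] - cur[k]
    net[graph$edges$to[k]] <- net[graph$edges$to[k]] + cur[k]
  }
  internal <- graph$nodes$type != "terminal"
  mx <- max(abs(cur))
  if (mx == 0) return(0)
  max(abs(net[internal])) / mx
}

# vectorized KCL residual for large graphs
kcl_residual_fast <- function(graph, solution) {
  nn <- nrow(graph$nodes)
  cur <- solution$edge_currents
  out <- rowsum(c(-cur, cur), c(graph$edges$from, graph$edges$to))
  net <- numeric(nn)
  net[as.integer(rownames(out))] <- out[, 1]
  internal <- graph$nodes$type != "terminal"
  mx <- max(abs(cur))
  if (mx == 0) return(0)
  max(abs(net[internal])) / mx
}
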