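#' Build the junction graph of a fiber web
#'
#' Converts a fiber web into an electrical graph: every fiber-fiber junction
#' becomes a node, and for each fiber the junctions lying on it are sorted by
#' position along the fiber and consecutive ones are connected by an edge
#' weighted with their Euclidean distance. Segments of a fiber beyond its
#' first/last junction are dangling stubs and produce no edge (they are later
#' reachable only through electrode contacts, see
#' \code{\link{attach_electrodes}}). Junctions closer than \code{1e-9 * L}
#' are merged into a single node.
#'
#' @param web a \code{fiber_web} from \code{\link{generate_web}}.
#' @return An object of class \code{web_graph}: list with \code{nodes}
#'   (data.frame \code{id, x, y, type}), \code{edges} (data.frame
#'   \code{from, to, length, kind}), \code{L}, \code{w}, bookkeeping columns
#'   used by electrode attachment, and placeholders \code{source}/\code{sink}
#'   (NA until electrodes are attached).
#' @seealso \code{\link{attach_electrodes}}, \code{\link{prune_dangling}}
#' @export
build_graph <- function(web) {
  stopifnot(inherits(web, "fiber_web"))
  jn <- web$junctions
  L <- web$L
  tol <- 1e-9 * L
  nj <- nrow(jn)

  # merge coincident junctions on a tolerance grid
  if (nj > 0L) {
    key <- paste(round(jn$x / tol), round(jn$y / tol))
    node_of_junction <- match(key, unique(key))
    nn <- max(node_of_junction)
    nx <- ny <- numeric(nn)
    first <- !duplicated(node_of_junction)
    nx[node_of_junction[first]] <- jn$x[first]
    ny[node_of_junction[first]] <- jn$y[first]
  } else {
    node_of_junction <- integer(0)
    nn <- 0L
    nx <- ny <- numeric(0)
  }

  nodes <- data.frame(id = seq_len(nn), x = nx, y = ny,
                      type = rep("junction", nn),
                      stringsAsFactors = FALSE)

  # one row per (fiber, junction-on-it): sort along each fiber, link runs
  if (nj > 0L) {
    occ <- data.frame(
      fiber = c(jn$fiber_a, jn$fiber_b),
      node  = c(node_of_junction, node_of_junction),
      t     = c(jn$t_a, jn$t_b)
    )
    occ <- occ[order(occ$fiber, occ$t), ]
    same_fiber <- occ$fiber[-1L] == occ$fiber[-nrow(occ)]
    from <- occ$node[-nrow(occ)][same_fiber]
    to   <- occ$node[-1L][same_fiber]
    keep <- from != to                     # merged coincident junctions
    from <- from[keep]; to <- to[keep]
    elen <- sqrt((nx[from] - nx[to])^2 + (ny[from] - ny[to])^2)
    edges <- data.frame(from = from, to = to, length = elen,
                        kind = rep("fiber", length(from)),
                        stringsAsFactors = FALSE)
    occ_keep <- occ
  } else {
    edges <- data.frame(from = integer(0), to = integer(0),
                        length = numeric(0), kind = character(0),
                        stringsAsFactors = FALSE)
    occ_keep <- data.frame(fiber = integer(0), node = integer(0),
                           t = numeric(0))
  }

  g <- list(nodes = nodes, edges = edges, L = L, w = web$w,
            fibers = web$fibers, occupancy = occ_keep,
            source = NA_integer_, sink = NA_integer_,
            contact_resistance = NA_real_, contacted = c(FALSE, FALSE))
  class(g) <- "web_graph"
  g
}

#' Attach electrode terminals to a web graph
#'
#' Adds a source and a sink terminal node and wires them to the web. In
#' \code{"busbar"} mode (the sheet-resistance configuration: electrodes along
#' the full left and right sides) every fiber endpoint lying on the left
#' (respectively right) boundary becomes a contact node, joined to its
#' fiber's nearest junction by an ordinary resistive fiber edge and to the
#' terminal by a contact edge of resistance \code{contact_R}. A fiber that
#' spans left to right without any junction is wired straight through.
#' Fibers running top to bottom touch neither bus bar and contribute no
#' contact. With \code{margin > 0}, junction nodes within a strip of that
#' width along each side are additionally connected to the terminal. In
#' \code{"regions"} mode all nodes inside each of two user rectangles are
#' joined to the corresponding terminal.
#'
#' The contact resistance is kept small but non-zero (default \code{1e-9}
#' ohm, many orders below any fiber edge) so the nodal system stays
#' well-posed.
#'
#' @param graph a \code{web_graph} from \code{\link{build_graph}}.
#' @param mode \code{"busbar"} or \code{"regions"}.
#' @param regions for \code{"regions"} mode: list of two rectangles, each
#'   \code{c(xmin, xmax, ymin, ymax)}, for source and sink.
#' @param margin bus-bar strip width; 0 (default) uses boundary fiber
#'   endpoints only.
#' @param contact_R contact edge resistance in ohm.
#' @return The graph with terminals attached; \code{$contacted} flags whether
#'   each side found at least one connection point. A web whose two flags are
#'   not both \code{TRUE} cannot percolate.
#' @export
attach_electrodes <- function(graph, mode = c("busbar", "regions"),
                              regions = NULL, margin = 0, contact_R = 1e-9) {
  stopifnot(inherits(graph, "web_graph"), margin >= 0, contact_R > 0)
  mode <- match.arg(mode)
  L <- graph$L
  nodes <- graph$nodes
  edges <- graph$edges
  nn <- nrow(nodes)
  src <- nn + 1L
  snk <- nn + 2L
  nodes <- rbind(nodes,
                 data.frame(id = c(src, snk), x = c(-0.02 * L, 1.02 * L),
                            y = c(L / 2, L / 2),
                            type = c("terminal", "terminal"),
                            stringsAsFactors = FALSE))
  e_from <- integer(0); e_to <- integer(0)
  e_len <- numeric(0); e_kind <- character(0)
  tolb <- 1e-9 * L

  if (mode == "busbar") {
    fb <- graph$fibers
    occ <- graph$occupancy
    # first/last junction node along each fiber (occupancy is t-sorted)
    if (nrow(occ) > 0L) {
      first_node <- occ$node[!duplicated(occ$fiber)]
      last_node  <- occ$node[!duplicated(occ$fiber, fromLast = TRUE)]
      names(first_node) <- occ$fiber[!duplicated(occ$fiber)]
      names(last_node)  <- occ$fiber[!duplicated(occ$fiber, fromLast = TRUE)]
    } else {
      first_node <- last_node <- integer(0)
    }
    # endpoint table: one row per fiber endpoint lying on the left/right side
    ex <- c(fb$x0, fb$x1); ey <- c(fb$y0, fb$y1)
    efib <- rep.int(fb$id, 2L)
    eend <- rep(c(0L, 1L), each = nrow(fb))     # 0 = start (t=0), 1 = end
    side <- ifelse(abs(ex) < tolb, "left",
                   ifelse(abs(ex - L) < tolb, "right", NA))
    sel <- which(!is.na(side))
    if (length(sel)) {
      cid <- nrow(nodes) + seq_along(sel)
      nodes <- rbind(nodes,
                     data.frame(id = cid, x = ex[sel], y = ey[sel],
                                type = "contact", stringsAsFactors = FALSE))
      term <- ifelse(side[sel] == "left", src, snk)
      e_from <- c(e_from, cid); e_to <- c(e_to, term)
      e_len <- c(e_len, rep(NA_real_, length(sel)))
      e_kind <- c(e_kind, rep("contact", length(sel)))
      # stub edge from each contact to its fiber's nearest junction
      fkey <- as.character(efib[sel])
      near <- ifelse(eend[sel] == 0L,
                     first_node[fkey], last_node[fkey])
      has_j <- !is.na(near)
      if (any(has_j)) {
        d <- sqrt((nodes$x[near[has_j]] - ex[sel][has_j])^2 +
                  (nodes$y[near[has_j]] - ey[sel][has_j])^2)
        e_from <- c(e_from, cid[has_j]); e_to <- c(e_to, near[has_j])
        e_len <- c(e_len, d)
        e_kind <- c(e_kind, rep("fiber", sum(has_j)))
      }
      # junction-free fibers contacting both sides: wire straight through
      bare <- efib[sel][!has_j]
      bare_span <- unique(bare[duplicated(bare)])
      for (f in bare_span) {
        cids <- cid[!has_j][efib[sel][!has_j] == f]
        e_from <- c(e_from, cids[1]); e_to <- c(e_to, cids[2])
        e_len <- c(e_len, fb$length[f])
        e_kind <- c(e_kind, "fiber")
      }
    }
    if (margin > 0) {
      jn <- nodes$type == "junction"
      lj <- which(jn & nodes$x <= margin)
      rj <- which(jn & nodes$x >= L - margin)
      e_from <- c(e_from, lj, rj)
      e_to <- c(e_to, rep(src, length(lj)), rep(snk, length(rj)))
      e_len <- c(e_len, rep(NA_real_, length(lj) + length(rj)))
      e_kind <- c(e_kind, rep("contact", length(lj) + length(rj)))
    }
  } else {
    if (is.null(regions) || length(regions) != 2L)
      stop("regions mode needs a list of two rectangles c(xmin,xmax,ymin,ymax)")
    for (k in 1:2) {
      r <- regions[[k]]
      inside <- which(nodes$type == "junction" &
                      nodes$x >= r[1] & nodes$x <= r[2] &
                      nodes$y >= r[3] & nodes$y <= r[4])
      term <- if (k == 1L) src else snk
      e_from <- c(e_from, inside)
      e_to <- c(e_to, rep(term, length(inside)))
      e_len <- c(e_len, rep(NA_real_, length(inside)))
      e_kind <- c(e_kind, rep("contact", length(inside)))
    }
  }

  if (length(e_from))
    edges <- rbind(edges,
                   data.frame(from = e_from, to = e_to, length = e_len,
                              kind = e_kind, stringsAsFactors = FALSE))
  graph$nodes <- nodes
  graph$edges <- edges
  graph$source <- src
  graph$sink <- snk
  graph$contact_resistance <- contact_R
  graph$contacted <- c(any(edges$kind == "contact" & (edges$to == src | edges$from == src)),
                       any(edges$kind == "contact" & (edges$to == snk | edges$from == snk)))
  graph
}

#' Prune dangling branches from a web graph
#'
#' Repeatedly removes non-electrode nodes of degree <= 1 (and their incident
#' edges) until a fixed point. Dangling branches carry no current in a DC
#' solution, so pruning leaves the equivalent resistance unchanged while
#' shrinking the linear system. Terminal nodes are never removed.
#'
#' @param graph a \code{web_graph} with electrodes attached.
#' @return The pruned graph; the number of removed nodes is available as
#'   \code{attr(, "pruned")}.
#' @export
prune_dangling <- function(graph) {
  stopifnot(inherits(graph, "web_graph"))
  nodes <- graph$nodes
  edges <- graph$edges
  keep_always <- nodes$type == "terminal"
  alive_nodes <- rep(TRUE, nrow(nodes))
  alive_edges <- rep(TRUE, nrow(edges))
  removed <- 0L
  repeat {
    deg <- tabulate(c(edges$from[alive_edges], edges$to[alive_edges]),
                    nbins = nrow(nodes))
    drop <- alive_nodes & !keep_always & deg <= 1L
    if (!any(drop)) break
    removed <- removed + sum(drop)
    alive_nodes[drop] <- FALSE
    alive_edges <- alive_edges & !(drop[edges$from] | drop[edges$to])
  }
  new_id <- cumsum(alive_nodes)
  nodes <- nodes[alive_nodes, , drop = FALSE]
  nodes$id <- seq_len(nrow(nodes))
  edges <- edges[alive_edges, , drop = FALSE]
  edges$from <- new_id[edges$from]
  edges$to <- new_id[edges$to]
  rownames(nodes) <- rownames(edges) <- NULL
  graph$nodes <- nodes
  graph$edges <- edges
  graph$source <- new_id[graph$source]
  graph$sink <- new_id[graph$sink]
  graph$occupancy <- NULL               # node ids re-based; occupancy stale
  attr(graph, "pruned") <- removed
  graph
}

#' @export
print.web_graph <- function(x, ...) {
  cat("Fiber web graph\n")
  cat(sprintf("  nodes: %d (%d junction, %d contact, %d terminal)\n",
              nrow(x$nodes), sum(x$nodes$type == "junction"),
              sum(x$nodes$type == "contact"), sum(x$nodes$type == "terminal")))
  cat(sprintf("  edges: %d (%d fiber, %d contact)\n", nrow(x$edges),
              sum(x$edges$kind == "fiber"), sum(x$edges$kind == "contact")))
  if (!is.na(x$source))
    cat(sprintf("  electrodes attached (contact R = %g ohm); sides contacted: %s/%s\n",
                x$contact_resistance, x$contacted[1], x$contacted[2]))
  invisible(x)
}
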