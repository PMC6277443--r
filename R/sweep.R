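# replicate seed derivation: every (transmittance index, replicate index)
# pair gets its own reproducible stream, so any single replicate can be
# regenerated in isolation. Kept below 2^31 - 1.
.derived_seed <- function(base_seed, t_index, rep_index) {
  as.integer((as.numeric(base_seed) + 100003 * (t_index - 1) + rep_index) %%
               .Machine$integer.max)
}

#' Sheet-resistance sweep over transmittance
#'
#' The ensemble experiment relating optical transmittance to electrical
#' sheet resistance: for each target transmittance, \code{n_reps}
#' independent webs are generated (derived seeds, recorded per replicate),
#' each is solved at 1 V in bus-bar configuration, and sheet resistance is
#' aggregated over the percolating replicates. The reference design uses 100
#' replicates of 1000 x 1000 squares per transmittance value.
#'
#' Non-percolating replicates have infinite sheet resistance; they are
#' excluded from the mean/sd and reported through the percolating fraction
#' instead, so a single disconnected web cannot destroy the statistics.
#'
#' @param T_list transmittance values in \code{[0, 1)}; default grid
#'   \code{c(0.80, 0.85, 0.90, 0.95)}.
#' @param n_reps replicates per transmittance (reference design: 100).
#' @param L,w web geometry (reference: 1000 x 1000, width 1).
#' @param rho_lin linear resistivity in ohm per unit length.
#' @param seed base seed for the derived replicate streams.
#' @return An object of class \code{sweep_result}: list with \code{summary}
#'   (data.frame \code{T, n, n_percolating, mean_Rs, sd_Rs}),
#'   \code{replicates} (per-replicate records incl. derived seed) and the
#'   input parameters.
#' @export
sweep_transmission <- function(T_list = c(0.80, 0.85, 0.90, 0.95),
                               n_reps = 100, L = 1000, w = 1,
                               rho_lin = 0.04, seed = 1) {
  stopifnot(all(T_list >= 0), all(T_list < 1), n_reps >= 1)
  reps <- vector("list", length(T_list) * n_reps)
  k <- 0L
  for (ti in seq_along(T_list)) {
    for (ri in seq_len(n_reps)) {
      s <- .derived_seed(seed, ti, ri)
      web <- generate_web(L, w, T_list[ti], seed = s)
      g <- prune_dangling(attach_electrodes(build_graph(web)))
      Rs <- sheet_resistance(g, rho_lin)
      k <- k + 1L
      reps[[k]] <- data.frame(
        T = T_list[ti], rep = ri, seed = s,
        n_fibers = nrow(web$fibers), n_junctions = nrow(web$junctions),
        percolating = is.finite(Rs), Rs = Rs)
    }
  }
  replicates <- do.call(rbind, reps)
  agg <- lapply(split(replicates, replicates$T), function(d) {
    perc <- d$Rs[is.finite(d$Rs)]
    data.frame(T = d$T[1], n = nrow(d), n_percolating = length(perc),
               mean_Rs = if (length(perc)) mean(perc) else NA_real_,
               sd_Rs = if (length(perc) > 1) stats::sd(perc) else NA_real_)
  })
  summary <- do.call(rbind, agg)
  summary <- summary[order(summary$T), ]
  rownames(summary) <- NULL
  out <- list(summary = summary, replicates = replicates,
              L = L, w = w, rho_lin = rho_lin, n_reps = n_reps,
              base_seed = as.integer(seed))
  class(out) <- "sweep_result"
  out
}

#' Fraction of replicate webs that percolate
#'
#' Generates \code{n_reps} webs at the given transmittance and reports the
#' fraction whose junction graph connects the two bus-bar electrodes. Sparse
#' webs (high transmittance) may fail to span; this fraction is the
#' percolation probability estimate that complements the sheet-resistance
#' sweep.
#'
#' @inheritParams sweep_transmission
#' @param T single transmittance value in \code{[0, 1)}.
#' @return Fraction in \code{[0, 1]}.
#' @export
percolation_fraction <- function(T, n_reps, L = 1000, w = 1, seed = 1) {
  stopifnot(T >= 0, T < 1, n_reps >= 1)
  perc <- logical(n_reps)
  for (ri in seq_len(n_reps)) {
    s <- .derived_seed(seed, 1L, ri)
    web <- generate_web(L, w, T, seed = s)
    g <- attach_electrodes(build_graph(web))
    perc[ri] <- .percolates(g)
  }
  mean(perc)
}

# connectivity check without solving the linear system
.percolates <- function(graph) {
  if (!all(graph$contacted)) return(FALSE)
  if (nrow(graph$edges) == 0L) return(FALSE)
  ig <- igraph::graph_from_edgelist(
    cbind(graph$edges$from, graph$edges$to), directed = FALSE)
  if (igraph::vcount(ig) < nrow(graph$nodes))
    ig <- igraph::add_vertices(ig, nrow(graph$nodes) - igraph::vcount(ig))
  comp <- igraph::components(ig)$membership
  comp[graph$source] == comp[graph$sink]
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Transmittance sweep: %d x %d webs (%g x %g, w = %g, rho = %g)\n",
              nrow(x$summary), x$n_reps, x$L, x$L, x$w, x$rho_lin))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
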