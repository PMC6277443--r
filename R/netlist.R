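#' Export a web graph as a SPICE netlist
#'
#' Writes one resistor card per edge (\code{R<id> n<from> n<to> <ohm>}), a
#' single DC voltage source between the terminals and an operating-point
#' directive, so the network can be cross-checked in any SPICE-compatible
#' simulator (the native solver in \code{\link{solve_dc}} is the primary
#' path). \code{\link{parse_netlist}} round-trips the format.
#'
#' @param graph a \code{web_graph} with electrodes attached.
#' @param V source voltage in volt.
#' @param rho_lin linear resistivity in ohm per unit length.
#' @param file optional path; when \code{NULL} the netlist is returned as a
#'   character vector of lines.
#' @return The netlist lines, invisibly when written to \code{file}.
#' @export
export_netlist <- function(graph, V = 1, rho_lin = 0.04, file = NULL) {
  stopifnot(inherits(graph, "web_graph"))
  if (is.na(graph$source))
    stop("export_netlist(): attach electrodes first")
  if (nrow(graph$edges) == 0L)
    stop("export_netlist(): graph has no edges")
  res <- .edge_resistances(graph, rho_lin)
  lines <- c(
    "* fiberheat resistor network",
    sprintf("R%d n%d n%d %.17g", seq_len(nrow(graph$edges)),
            graph$edges$from, graph$edges$to, res),
    sprintf("V1 n%d n%d DC %.17g", graph$source, graph$sink, V),
    ".op",
    ".end"
  )
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Parse a SPICE netlist written by \code{export_netlist}
#'
#' @param lines character vector of netlist lines, or a file path.
#' @return List with \code{edges} (data.frame \code{from, to, resistance}),
#'   \code{source}, \code{sink} and \code{V}.
#' @export
parse_netlist <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  rl <- grep("^R", lines, value = TRUE)
  parts <- strsplit(trimws(rl), "\\s+")
  num <- function(p, i) as.numeric(sub("^n", "", vapply(p, `[`, "", i)))
  edges <- data.frame(
    from = as.integer(num(parts, 2L)),
    to = as.integer(num(parts, 3L)),
    resistance = as.numeric(vapply(parts, `[`, "", 4L))
  )
  vl <- grep("^V", lines, value = TRUE)
  if (length(vl) != 1L) stop("parse_netlist(): expected exactly one source")
  vp <- strsplit(trimws(vl), "\\s+")[[1]]
  list(edges = edges,
       source = as.integer(sub("^n", "", vp[2])),
       sink = as.integer(sub("^n", "", vp[3])),
       V = as.numeric(vp[5]))
}
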