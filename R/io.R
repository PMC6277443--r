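# Plain-text serialization. A web is stored as two delimited files:
#   <prefix>_fibers.tsv    id x0 y0 x1 y1 length   (+ header comments)
#   <prefix>_junctions.tsv x y fiber_a fiber_b t_a t_b
# Header comment lines carry L, w, thickness, target_T, seed, covered_area
# so the web round-trips exactly.

#' Write a fiber web to delimited text files
#'
#' @param web a \code{fiber_web}.
#' @param prefix output path prefix; writes \code{<prefix>_fibers.tsv} and
#'   \code{<prefix>_junctions.tsv}.
#' @return The two file paths, invisibly.
#' @export
write_web <- function(web, prefix) {
  stopifnot(inherits(web, "fiber_web"))
  ffile <- paste0(prefix, "_fibers.tsv")
  jfile <- paste0(prefix, "_junctions.tsv")
  hdr <- sprintf("# L=%.17g w=%.17g thickness=%.17g target_T=%.17g seed=%d covered_area=%.17g",
                 web$L, web$w, web$thickness, web$target_T, web$seed,
                 web$covered_area)
  writeLines(c(hdr, paste(names(web$fibers), collapse = "\t")), ffile)
  utils::write.table(web$fibers, ffile, append = TRUE, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste(names(web$junctions), collapse = "\t"), jfile)
  utils::write.table(web$junctions, jfile, append = TRUE, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(ffile, jfile))
}

#' Read a fiber web written by \code{write_web}
#'
#' @param prefix path prefix used at write time.
#' @return A \code{fiber_web}.
#' @export
read_web <- function(prefix) {
  ffile <- paste0(prefix, "_fibers.tsv")
  jfile <- paste0(prefix, "_junctions.tsv")
  hdr <- readLines(ffile, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-zA-Z_]+=[-0-9.e+]+", hdr))[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  fibers <- utils::read.table(ffile, header = TRUE, sep = "\t", skip = 1L)
  junctions <- utils::read.table(jfile, header = TRUE, sep = "\t")
  web <- list(L = meta[["L"]], w = meta[["w"]],
              thickness = meta[["thickness"]],
              target_T = meta[["target_T"]],
              seed = as.integer(meta[["seed"]]),
              covered_area = meta[["covered_area"]],
              fibers = fibers, junctions = junctions)
  class(web) <- "fiber_web"
  web
}

#' Write a solved network and summary to text files
#'
#' Writes \code{<prefix>_solution.tsv} (edge id, from, to, kind, resistance,
#' current, power) and \code{<prefix>_summary.json} (applied voltage, total
#' current, equivalent resistance, percolation flag).
#'
#' @param solution a \code{circuit_solution}.
#' @param prefix output path prefix.
#' @return File paths, invisibly.
#' @export
write_solution <- function(solution, prefix) {
  stopifnot(inherits(solution, "circuit_solution"))
  sfile <- paste0(prefix, "_solution.tsv")
  jfile <- paste0(prefix, "_summary.json")
  d <- data.frame(edge = seq_len(nrow(solution$edges)),
                  from = solution$edges$from, to = solution$edges$to,
                  kind = solution$edges$kind,
                  resistance = solution$edges$resistance,
                  current = solution$edge_currents,
                  power = solution$edge_powers)
  utils::write.table(d, sfile, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(applied_voltage = solution$applied_voltage,
         total_current = solution$total_current,
         equivalent_resistance =
           if (is.finite(solution$equivalent_resistance))
             solution$equivalent_resistance else "Inf",
         percolating = solution$percolating),
    jfile, auto_unbox = TRUE, digits = NA)
  invisible(c(sfile, jfile))
}

#' Write a power map as a delimited-text matrix
#'
#' Row i, column j holds the power in the cell centred at
#' \code{((j - 0.5) * cell, (i - 0.5) * cell)}.
#'
#' @param map a \code{power_map}.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_power_map <- function(map, file) {
  stopifnot(inherits(map, "power_map"))
  writeLines(sprintf("# cell=%.17g voltage=%.17g", map$cell,
                     map$applied_voltage), file)
  utils::write.table(map$grid, file, append = TRUE, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a release series as delimited text with a JSON sidecar
#'
#' @param series a \code{release_series}.
#' @param file output path for the two-column table (time_min, current_uA);
#'   the sidecar is written to \code{<file>.json}.
#' @return File paths, invisibly.
#' @export
write_release_series <- function(series, file) {
  stopifnot(inherits(series, "release_series"))
  d <- data.frame(time_min = series$times, current_uA = series$peak_currents)
  utils::write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- paste0(file, ".json")
  jsonlite::write_json(list(condition = series$condition,
                            volume_L = series$volume,
                            molar_mass = series$molar_mass),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(file, side))
}

#' Read a release series written by \code{write_release_series}
#'
#' @param file table path; the \code{<file>.json} sidecar is read when
#'   present.
#' @return A \code{release_series}.
#' @export
read_release_series <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t")
  side <- paste0(file, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side)
          else list(condition = "unknown", volume_L = 1e-3,
                    molar_mass = 319.85)
  release_series(d$time_min, d$current_uA, condition = meta$condition,
                 volume = meta$volume_L, molar_mass = meta$molar_mass)
}
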