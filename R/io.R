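#' Write and read simulation snapshots
#'
#' A snapshot stores u, v, the phase field and the time in a single
#' container file (RDS), consumable by \code{\link{integrate_medium}}
#' after \code{read_snapshot}.
#'
#' @param state A \code{medium_state}.
#' @param domain A \code{phase_field_domain}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_snapshot <- function(state, domain, path) {
  saveRDS(list(u = state$u, v = state$v, phi = domain$phi, t = state$t),
          path)
  invisible(path)
}

#' @rdname write_snapshot
#' @return \code{read_snapshot}: list with a \code{medium_state}
#'   (\code{state}) and the stored phase field (\code{phi}).
#' @export
read_snapshot <- function(path) {
  x <- readRDS(path)
  list(state = medium_state(x$u, x$v, t = x$t), phi = x$phi)
}

#' Export a state as a legacy-VTK structured-points file
#'
#' ASCII legacy VTK with point scalars u, v and phi, loadable in
#' ParaView for 3D visualization.
#'
#' @param state A \code{medium_state}.
#' @param domain A \code{phase_field_domain}.
#' @param params A \code{model_params} object.
#' @param path Output .vtk file path.
#' @return \code{path}, invisibly.
#' @export
write_vtk <- function(state, domain, params, path) {
  d <- params$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("excitable medium state t=%g", state$t),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", params$dx, params$dx, params$dx),
               sprintf("POINT_DATA %d", prod(d))), con)
  for (nm in c("u", "v", "phi")) {
    vals <- if (nm == "phi") domain$phi else state[[nm]]
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(formatC(as.vector(vals), format = "g", digits = 6), con)
  }
  invisible(path)
}
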