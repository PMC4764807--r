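#' Read a simulation configuration file
#'
#' YAML with sections \code{model} (a, b, epsilon, dx, dt, grid),
#' \code{obstacle} (radius, center, interface_width), \code{field}
#' (kind, E0, omega_e, pulse_duration) and \code{run} (t_end,
#' snapshot_every, probe_positions).  Any omitted entry falls back to the
#' package default.
#'
#' @param path Path to a YAML config file.
#' @return List with \code{params} (\code{model_params}), \code{domain}
#'   (\code{phase_field_domain}), \code{field} (\code{field_spec}) and
#'   \code{run} (plain list).
#' @examples
#' cfg <- read_sim_config(system.file("extdata", "example_config.yaml",
#'                                    package = "scrollwave"))
#' cfg$params
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  m <- raw$model %||% list()
  params <- model_params(a = m$a %||% 0.9, b = m$b %||% 0.08,
                         epsilon = m$epsilon %||% 0.02,
                         dx = m$dx %||% 0.25, dt = m$dt,
                         grid = unlist(m$grid %||% c(60, 60, 60)))
  o <- raw$obstacle %||% list()
  domain <- if (isTRUE(o$none)) {
    no_obstacle_domain(params)
  } else {
    build_phase_field(params,
                      center = if (!is.null(o$center)) unlist(o$center),
                      radius = o$radius %||% 2.5,
                      interface_width = o$interface_width %||%
                        (2 * params$dx))
  }
  f <- raw$field %||% list()
  field <- field_spec(kind = f$kind %||% "NONE", E0 = f$E0 %||% 0,
                      omega_e = f$omega_e,
                      pulse_duration = f$pulse_duration)
  run <- raw$run %||% list()
  run$t_end <- run$t_end %||% 40
  run$snapshot_every <- run$snapshot_every %||% 10
  if (!is.null(run$probe_positions)) {
    run$probe_positions <- matrix(unlist(run$probe_positions),
                                  ncol = 3, byrow = TRUE)
  }
  list(params = params, domain = domain, field = field, run = run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
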