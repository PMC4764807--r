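#' Medium state container
#'
#' Holds the two 3D scalar fields of the Barkley medium: \code{u}
#' (fast, membrane-potential-like) and \code{v} (slow recovery), plus the
#' current simulation time.
#'
#' @param u,v 3D numeric arrays of identical shape.
#' @param t Current time (time units).
#' @return An object of class \code{"medium_state"}.
#' @export
medium_state <- function(u, v, t = 0) {
  stopifnot(is.array(u), is.array(v), identical(dim(u), dim(v)),
            length(dim(u)) == 3)
  structure(list(u = u, v = v, t = t), class = "medium_state")
}

#' @export
print.medium_state <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("Medium state %d x %d x %d at t = %g; u in [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$t, min(x$u), max(x$u)))
  invisible(x)
}

#' Quiescent (rest) state
#'
#' u = v = 0 everywhere, t = 0.  This is a fixed point of the dynamics:
#' without an external field the medium stays at rest indefinitely.
#'
#' @param params A \code{model_params} object.
#' @return A \code{medium_state}.
#' @export
quiescent_state <- function(params) {
  z <- array(0, dim = params$grid)
  medium_state(z, z, t = 0)
}

# Zero out u and v at phase-field points below the floor (held at rest).
enforce_rest_in_obstacle <- function(state, domain) {
  off <- domain$active == 0L
  if (any(off)) {
    state$u[off] <- 0
    state$v[off] <- 0
  }
  state
}

#' Diffusion and electric-field forcing rate field
#'
#' Evaluates the spatial part of the u-equation,
#' \deqn{\frac{1}{\varphi}\nabla\cdot(\varphi\nabla u)
#'       + \frac{1}{\varphi}\,\nabla\varphi\cdot E,}
#' the phase-field form of the Laplacian whose sharp-interface limit
#' imposes the Neumann condition \eqn{n\cdot\nabla u = n\cdot E} on the
#' obstacle surface.  Conservative 7-point central differences with
#' 2-point face averages of \eqn{\varphi}; mirrored ghost layers give
#' no-flux outer boundaries.  Points below the phase-field floor get
#' rate 0.
#'
#' @param u 3D array.
#' @param domain A \code{phase_field_domain}.
#' @param E Length-3 numeric vector, the spatially uniform field value.
#' @param params A \code{model_params} object.
#' @return 3D array of rates.
#' @export
diffusion_and_forcing <- function(u, domain, E, params) {
  stopifnot(length(E) == 3, identical(dim(u), dim(domain$phi)))
  out <- rate_field_cpp(u, domain$phi, domain$invphi, domain$gx, domain$gy,
                        domain$gz, domain$active, params$grid, params$dx,
                        E[1], E[2], E[3])
  array(out, dim = dim(u))
}

# Low-level chunk advance: nsteps explicit Euler steps in C++.
# probe_idx: 0-based linear indices; probe_every in steps (0 = no probes).
advance_chunk <- function(state, domain, field, params, nsteps,
                          probe_idx = integer(0), probe_every = 0L) {
  res <- advance_cpp(state$u, state$v, domain$phi, domain$invphi,
                     domain$gx, domain$gy, domain$gz, domain$active,
                     params$grid, params$a, params$b, params$epsilon,
                     params$dx, params$dt, field_kind_code(field),
                     field$E0, field$omega_e, field$pulse_duration,
                     field$phase, state$t, as.integer(nsteps),
                     as.integer(probe_idx), as.integer(probe_every))
  u <- array(res$u, dim = params$grid)
  v <- array(res$v, dim = params$grid)
  st <- medium_state(u, v, t = state$t + nsteps * params$dt)
  list(state = st, probe_t = res$probe_t, probe_u = res$probe_u,
       max_abs_u = res$max_abs_u)
}

#' Advance the medium by one explicit Euler step
#'
#' \code{u <- u + dt * (reaction + diffusion + forcing)};
#' \code{v <- v + dt * (u - v)} using the pre-step u.  Deterministic.
#' Raises an error naming the first offending grid index and time if the
#' step produces non-finite values.
#'
#' @param state A \code{medium_state}.
#' @param domain A \code{phase_field_domain}.
#' @param field A \code{field_spec}.
#' @param params A \code{model_params} object.
#' @return The updated \code{medium_state}.
#' @export
euler_step <- function(state, domain, field, params) {
  advance_chunk(state, domain, field, params, 1L)$state
}

#' Integrate the medium to a target time
#'
#' Repeatedly applies explicit Euler steps until \code{t >= t_end},
#' optionally recording probe time series of u, sampling the scroll-wave
#' filament, and invoking a snapshot callback.  Integration proceeds in
#' chunks of \code{chunk} time units inside compiled code; all observer
#' cadences are rounded to whole steps.
#'
#' @param state Initial \code{medium_state}.
#' @param domain A \code{phase_field_domain}.
#' @param field A \code{field_spec}.
#' @param params A \code{model_params} object.
#' @param t_end Target time; must be >= \code{state$t}.
#' @param probes Optional n x 3 matrix of probe positions (space units).
#' @param probe_dt Probe sampling interval (time units), default 0.01.
#' @param filament_every Optional interval (time units) at which to detect
#'   the filament; results are returned as a \code{filament_trace}.
#' @param snapshot_fun Optional callback \code{function(state)} invoked
#'   every \code{snapshot_every} time units.
#' @param snapshot_every Snapshot interval (time units).
#' @param chunk Chunk length in time units handed to compiled code.
#' @param log_every Optional interval (time units) at which to emit a
#'   progress line (step count, time, running max |u|, wall time).
#' @return List with \code{state}, optional \code{probes}
#'   (a \code{probe_series}), optional \code{trace}
#'   (a \code{filament_trace}), and \code{max_abs_u}.
#' @export
integrate_medium <- function(state, domain, field, params, t_end,
                             probes = NULL, probe_dt = 0.01,
                             filament_every = NULL,
                             snapshot_fun = NULL, snapshot_every = 10,
                             chunk = 1, log_every = NULL) {
  stopifnot(t_end >= state$t - 1e-12)
  state <- enforce_rest_in_obstacle(state, domain)
  probe_idx <- integer(0)
  probe_every <- 0L
  if (!is.null(probes)) {
    probes <- rbind(probes)
    probe_idx <- apply(probes, 1, position_to_linear0, params = params)
    probe_every <- max(1L, as.integer(round(probe_dt / params$dt)))
  }
  steps_per_chunk <- max(1L, as.integer(round(chunk / params$dt)))
  all_t <- numeric(0)
  all_u <- NULL
  tr_times <- numeric(0)
  tr_points <- list()
  max_abs <- 0
  snap_counter <- 0
  fil_counter <- 0
  log_counter <- 0
  steps_done <- 0
  wall0 <- proc.time()[3]

  record_filament <- function(st) {
    pts <- detect_filament(st, domain = domain, params = params)
    tr_times[[length(tr_times) + 1]] <<- st$t
    tr_points[[length(tr_points) + 1]] <<- pts
  }
  if (!is.null(filament_every)) record_filament(state)

  while (state$t < t_end - 1e-9) {
    n <- min(steps_per_chunk,
             max(1L, as.integer(round((t_end - state$t) / params$dt))))
    res <- advance_chunk(state, domain, field, params, n, probe_idx,
                         probe_every)
    state <- res$state
    max_abs <- max(max_abs, res$max_abs_u)
    steps_done <- steps_done + n
    if (!is.null(log_every)) {
      log_counter <- log_counter + n * params$dt
      if (log_counter >= log_every - 1e-9) {
        log_counter <- 0
        message(sprintf("step %d  t = %.2f  max|u| = %.3f  wall %.1fs",
                        steps_done, state$t, max_abs,
                        proc.time()[3] - wall0))
      }
    }
    if (probe_every > 0L && length(res$probe_t)) {
      all_t <- c(all_t, res$probe_t)
      all_u <- rbind(all_u, res$probe_u)
    }
    if (!is.null(filament_every)) {
      fil_counter <- fil_counter + n * params$dt
      if (fil_counter >= filament_every - 1e-9) {
        fil_counter <- 0
        record_filament(state)
      }
    }
    if (!is.null(snapshot_fun)) {
      snap_counter <- snap_counter + n * params$dt
      if (snap_counter >= snapshot_every - 1e-9) {
        snap_counter <- 0
        snapshot_fun(state)
      }
    }
  }
  out <- list(state = state, max_abs_u = max_abs)
  if (!is.null(probes)) {
    out$probes <- probe_series(positions = probes, times = all_t,
                               u = all_u)
  }
  if (!is.null(filament_every)) {
    out$trace <- filament_trace(tr_times, tr_points, domain, params)
  }
  out
}
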