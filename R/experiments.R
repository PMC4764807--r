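#' Rotation frequency of a pinned scroll wave
#'
#' Integrates the state with the field off, recording probes just outside
#' the obstacle at two perpendicular azimuths, and reports the mean
#' activation frequency (the two probes must agree within a few percent
#' for a rigidly rotating pinned scroll).
#'
#' @param state A pinned-scroll \code{medium_state}.
#' @param domain A \code{phase_field_domain}.
#' @param params A \code{model_params} object.
#' @param t_measure Measurement window (time units).
#' @return List with \code{omega} (mean over probes), \code{per_probe},
#'   \code{cv} (max over probes) and the \code{probe_series}.
#' @export
scroll_frequency <- function(state, domain, params, t_measure = 30) {
  probes <- axis_probes(domain, params, axes = "xy")
  res <- integrate_medium(state, domain, field_spec("NONE"), params,
                          t_end = state$t + t_measure, probes = probes)
  f <- lapply(1:2, function(i) activation_frequency(res$probes, column = i))
  list(omega = mean(vapply(f, `[[`, numeric(1), "omega")),
       per_probe = vapply(f, `[[`, numeric(1), "omega"),
       cv = max(vapply(f, `[[`, numeric(1), "cv")),
       probes = res$probes)
}

#' Wave emission from the obstacle in a quiescent medium
#'
#' Applies an external field to the initially quiescent medium with the
#' obstacle and classifies wave emission from probes placed on all six
#' axis directions at equal distance outside the surface.  Emission
#' requires at least 3 activations at some probe; the wave train is
#' "sound" (a regular, unbroken spherical wave) when every probe shows a
#' regular train: per-probe inter-activation coefficient of variation
#' below 10% and activation counts across the six probes differing by at
#' most one cycle.
#'
#' @param field A \code{field_spec}.
#' @param params A \code{model_params} object.
#' @param domain A \code{phase_field_domain}.
#' @param t_end Integration time (time units), default 70.  Emission
#'   settles through a long transient (the first waves leave a broad
#'   refractory tail), so frequencies are measured on the second half of
#'   the run.
#' @param threshold Activation threshold on u.
#' @param window Measurement window (time units); default
#'   \code{c(t_end/2, t_end)}.
#' @return List with \code{emitted}, \code{sound}, \code{omega_wave}
#'   (mean over the +x and +y probes; NA when not measurable),
#'   \code{per_probe_omega}, \code{cv} (max over probes),
#'   \code{counts} (tail-window activations per probe) and the
#'   \code{probe_series}.
#' @export
run_weh_quiescent <- function(field, params, domain, t_end = 70,
                              threshold = 0.5, window = NULL) {
  if (is.null(window)) window <- c(t_end / 2, t_end)
  state <- quiescent_state(params)
  probes <- axis_probes(domain, params, axes = "all")
  res <- integrate_medium(state, domain, field, params, t_end = t_end,
                          probes = probes)
  np <- nrow(probes)
  cross <- lapply(seq_len(np), function(i)
    upward_crossings(res$probes$times, res$probes$u[, i], threshold))
  emitted <- max(lengths(cross)) >= 3
  tailc <- lapply(cross, function(cr) cr[cr >= window[1] & cr <= window[2]])
  counts <- lengths(tailc)
  omegas <- vapply(tailc, function(cr) {
    if (length(cr) >= 4) 2 * pi / mean(diff(cr)) else NA_real_
  }, numeric(1))
  cvs <- vapply(tailc, function(cr) {
    if (length(cr) >= 4) stats::sd(diff(cr)) / mean(diff(cr)) else NA_real_
  }, numeric(1))
  # a sound (well-formed, unbroken) spherical wave train: every axis
  # probe sees the same number of cycles in the window (within one) and
  # regular intervals
  sound <- emitted && all(is.finite(omegas)) && all(cvs < 0.10) &&
    (max(counts) - min(counts) <= 1)
  omega_wave <- if (all(is.finite(omegas[c(1, 3)]))) {
    mean(omegas[c(1, 3)])          # +x and +y probes
  } else if (any(is.finite(omegas))) {
    mean(omegas[is.finite(omegas)])
  } else {
    NA_real_
  }
  list(emitted = emitted, sound = sound, omega_wave = omega_wave,
       per_probe_omega = omegas,
       cv = if (any(is.finite(cvs))) max(cvs, na.rm = TRUE) else NA_real_,
       counts = counts, window = window, probes = res$probes)
}

#' Frequency-response scan of wave emission
#'
#' For each field frequency, measures the induced spherical-wave
#' frequency in the quiescent medium and compares it with the pinned
#' scroll frequency.
#'
#' @param kind Field kind ("PDCEF", "ACEF" or "CPEF").
#' @param E0 Field amplitude.
#' @param omega_list Field angular frequencies to scan.
#' @param d Pulse duration (PDCEF only).
#' @param params,domain Model parameters and obstacle domain.
#' @param omega_scroll Reference pinned-scroll frequency (same grid).
#' @param t_end Integration time per cell.
#' @return A data.frame with one row per frequency: \code{omega_e},
#'   \code{emitted}, \code{sound}, \code{omega_wave}, \code{cv} and
#'   \code{exceeds_scroll}, carrying the scan setup as attributes.
#' @export
run_frequency_scan <- function(kind, E0, omega_list, d = NULL, params,
                               domain, omega_scroll = NA_real_,
                               t_end = 70) {
  rows <- lapply(omega_list, function(om) {
    f <- field_spec(kind, E0 = E0, omega_e = om, pulse_duration = d)
    r <- run_weh_quiescent(f, params, domain, t_end = t_end)
    data.frame(omega_e = om, emitted = r$emitted, sound = r$sound,
               omega_wave = r$omega_wave, cv = r$cv,
               exceeds_scroll = !is.na(r$omega_wave) &
                 r$omega_wave > omega_scroll)
  })
  out <- do.call(rbind, rows)
  attr(out, "setup") <- list(kind = kind, E0 = E0, d = d,
                             omega_scroll = omega_scroll,
                             grid = params$grid, dx = params$dx,
                             dt = params$dt, R = domain$radius)
  out
}

#' Removal of a pinned scroll wave by an external field
#'
#' Integrates a pinned-scroll state with the field on, sampling the
#' filament once per time unit, until the filament has left the
#' obstacle-centered success box (or \code{t_limit} is reached); then
#' switches the field off and integrates on until the medium is
#' quiescent or \code{post_limit} more time units have elapsed.
#'
#' @param field A \code{field_spec}.
#' @param params,domain Model parameters and obstacle domain.
#' @param state A pinned-scroll \code{medium_state}
#'   (from \code{\link{pinned_scroll_init}}).
#' @param t_limit Success deadline (time units), default 500.
#' @param box_half_width Success-box half width, default 2 R.
#' @param sample_every Filament sampling cadence (time units).
#' @param post_limit Maximum field-off follow-up time.
#' @param post_check Follow the run with the field off (default TRUE).
#' @return List with the \code{classify_removal} outcome
#'   (\code{success}, \code{t_detach}, \code{t_removed}), the
#'   \code{filament_trace}, \code{quiescent_after} and the final state.
#' @export
run_removal <- function(field, params, domain, state, t_limit = 500,
                        box_half_width = 2 * domain$radius,
                        sample_every = 1, post_limit = 120,
                        post_check = TRUE) {
  state$t <- 0
  state <- enforce_rest_in_obstacle(state, domain)
  times <- numeric(0)
  pts <- list()
  record <- function(st) {
    times[[length(times) + 1]] <<- st$t
    pts[[length(pts) + 1]] <<- detect_filament(st, domain = domain,
                                               params = params)
  }
  record(state)
  outside_for <- 0
  while (state$t < t_limit - 1e-9) {
    state <- advance_chunk(state, domain, field, params,
                           max(1L, as.integer(round(sample_every /
                                                      params$dt))))$state
    record(state)
    p <- pts[[length(pts)]]
    gone <- nrow(p) == 0
    if (!gone) {
      comp <- filament_components(p, 3 * params$dx)
      zext <- (params$grid[3] - 1) * params$dx
      flags <- reentrant_flags(p, comp, zext, 0.6, 4 * params$dx)
      gone <- TRUE
      for (ki in seq_along(unique(comp))) {
        if (!flags[ki]) next
        q <- p[comp == unique(comp)[ki], , drop = FALSE]
        if (any(apply(abs(sweep(q, 2, domain$center)), 1, max) <
                  box_half_width)) {
          gone <- FALSE
          break
        }
      }
    }
    outside_for <- if (gone) outside_for + 1 else 0
    if (outside_for >= 2) break  # success classified; stop early
  }
  trace <- filament_trace(times, pts, domain, params,
                          box_half_width = box_half_width)
  outcome <- classify_removal(trace, box_half_width = box_half_width,
                              t_limit = t_limit, dx = params$dx)
  quiet <- NA
  if (post_check && outcome$success) {
    res <- integrate_medium(state, domain, field_spec("NONE"), params,
                            t_end = state$t + post_limit, chunk = 5)
    quiet <- is_quiescent(res$state, domain)
    state <- res$state
  }
  c(outcome, list(trace = trace, quiescent_after = quiet,
                  final_state = state))
}

#' Success region of scroll-wave removal in the (E0, omega_e) plane
#'
#' Runs \code{\link{run_removal}} on a grid of circularly-polarized-field
#' amplitudes and frequencies, reusing one pinned reference state, and
#' tabulates success; also reports per amplitude the number of successful
#' frequency cells (the measure of the successful interval).
#'
#' @param E0_list Amplitudes to scan.
#' @param omega_list Frequencies to scan.
#' @param params,domain Model parameters and obstacle domain.
#' @param state Pinned-scroll reference state (reused across cells).
#' @param kind Field kind, default "CPEF".
#' @param t_limit Per-cell success deadline.
#' @param ... Passed to \code{run_removal}.
#' @return A data.frame grid with columns \code{E0}, \code{omega_e},
#'   \code{success}, \code{t_detach}, \code{t_removed}; attribute
#'   \code{interval_width} holds successful-cell counts per E0.
#' @export
run_phase_diagram <- function(E0_list, omega_list, params, domain, state,
                              kind = "CPEF", t_limit = 500, ...) {
  rows <- list()
  for (E0 in E0_list) {
    for (om in omega_list) {
      out <- if (E0 <= 0) {
        list(success = FALSE, t_detach = NA, t_removed = NA)
      } else {
        f <- field_spec(kind, E0 = E0, omega_e = om)
        r <- tryCatch(
          run_removal(f, params, domain, state, t_limit = t_limit,
                      post_check = FALSE, ...),
          error = function(e) list(success = NA, t_detach = NA,
                                   t_removed = NA, error = conditionMessage(e)))
        r
      }
      rows[[length(rows) + 1]] <-
        data.frame(E0 = E0, omega_e = om,
                   success = isTRUE(out$success),
                   t_detach = if (is.null(out$t_detach)) NA else out$t_detach,
                   t_removed = if (is.null(out$t_removed)) NA
                   else out$t_removed)
    }
  }
  grid <- do.call(rbind, rows)
  width <- tapply(grid$success, grid$E0, sum)
  attr(grid, "interval_width") <-
    data.frame(E0 = as.numeric(names(width)), n_success = as.integer(width))
  attr(grid, "setup") <- list(kind = kind, t_limit = t_limit,
                              grid = params$grid, dx = params$dx,
                              dt = params$dt, R = domain$radius)
  grid
}
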