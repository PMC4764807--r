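#' External electric field specification
#'
#' Three waveforms are supported, all spatially uniform:
#' \describe{
#'   \item{PDCEF}{pulsed DC field along x: amplitude \code{E0} during the
#'     first \code{pulse_duration} time units of each period
#'     \eqn{2\pi/\omega_e}, zero otherwise.  \code{omega_e} is the pulse
#'     repetition angular frequency, so frequency axes are comparable
#'     across waveforms.}
#'   \item{ACEF}{alternating field along x:
#'     \eqn{E_0 \cos(\omega_e t)\,\hat x}.}
#'   \item{CPEF}{circularly polarized field rotating in the xy-plane:
#'     \eqn{E_0 (\cos\omega_e t, \sin\omega_e t, 0)}; its magnitude is
#'     \eqn{E_0} at all times.}
#' }
#' The linear waveforms point along x (any horizontal axis would do); the
#' circularly polarized field rotates about the z-axis.
#'
#' @param kind One of "NONE", "PDCEF", "ACEF", "CPEF".
#' @param E0 Field amplitude (model units per space unit), >= 0.
#' @param omega_e Angular frequency (radians per time unit); > 0 for
#'   ACEF/CPEF and pulsed PDCEF.
#' @param pulse_duration Pulse duration d (time units, PDCEF only);
#'   must satisfy 0 < d < 2 pi / omega_e.
#' @param phase Initial phase (radians for ACEF/CPEF, time offset for
#'   PDCEF); default 0.
#' @return An object of class \code{"field_spec"}.
#' @examples
#' field_spec("CPEF", E0 = 1.8, omega_e = 3.0)
#' @export
field_spec <- function(kind = c("NONE", "PDCEF", "ACEF", "CPEF"),
                       E0 = 0, omega_e = NULL, pulse_duration = NULL,
                       phase = 0) {
  kind <- match.arg(toupper(kind[1]), c("NONE", "PDCEF", "ACEF", "CPEF"))
  stopifnot(is.numeric(E0), length(E0) == 1, E0 >= 0)
  if (kind %in% c("PDCEF", "ACEF", "CPEF")) {
    stopifnot(is.numeric(omega_e), length(omega_e) == 1, omega_e > 0)
  } else {
    omega_e <- 0
  }
  if (kind == "PDCEF") {
    stopifnot(is.numeric(pulse_duration), pulse_duration > 0,
              pulse_duration < 2 * pi / omega_e)
  } else {
    pulse_duration <- 0
  }
  structure(list(kind = kind, E0 = E0, omega_e = omega_e,
                 pulse_duration = pulse_duration, phase = phase),
            class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  if (x$kind == "NONE") {
    cat("Electric field: none\n")
  } else {
    cat(sprintf("Electric field: %s, E0 = %g, omega_e = %g%s\n", x$kind,
                x$E0, x$omega_e,
                if (x$kind == "PDCEF")
                  sprintf(", pulse duration = %g", x$pulse_duration)
                else ""))
  }
  invisible(x)
}

field_kind_code <- function(spec) {
  match(spec$kind, c("NONE", "PDCEF", "ACEF", "CPEF")) - 1L
}

#' Evaluate the field vector at given times
#'
#' @param spec A \code{field_spec}.
#' @param t Numeric vector of times.
#' @return An n x 3 matrix of field vectors (columns x, y, z).
#' @examples
#' field_vector(field_spec("CPEF", E0 = 1.8, omega_e = 2), 0)  # (1.8, 0, 0)
#' @export
field_vector <- function(spec, t) {
  stopifnot(inherits(spec, "field_spec"))
  out <- field_vector_cpp(field_kind_code(spec), spec$E0, spec$omega_e,
                          spec$pulse_duration, spec$phase, as.numeric(t))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Instantaneous surface forcing n . E on the spherical obstacle
#'
#' With outward unit normal
#' \eqn{n = (\sin\theta\cos\varphi, \sin\theta\sin\varphi, \cos\theta)}
#' in spherical coordinates, the field enters the medium through the
#' Neumann condition \eqn{n\cdot\nabla u = n\cdot E}, so \eqn{n\cdot E}
#' controls how strongly each surface point is (de/hyper)polarized.
#' For the x-directed waveforms \eqn{n\cdot E = A(t)\sin\theta\cos\varphi};
#' for the circularly polarized field
#' \eqn{n\cdot E = E_0 \sin\theta\cos(\varphi - \omega_e t)}.
#'
#' @param spec A \code{field_spec}.
#' @param theta Polar angle in [0, pi] (0 = +z pole).
#' @param phi_az Azimuth in [0, 2 pi).
#' @param t Time.
#' @return Scalar (vectorized over arguments of equal length).
#' @export
surface_forcing <- function(spec, theta, phi_az, t) {
  stopifnot(inherits(spec, "field_spec"))
  E <- field_vector(spec, t)
  nvec <- cbind(sin(theta) * cos(phi_az), sin(theta) * sin(phi_az),
                cos(theta))
  if (nrow(E) == 1 && nrow(nvec) > 1) E <- E[rep(1, nrow(nvec)), , drop = FALSE]
  if (nrow(nvec) == 1 && nrow(E) > 1) {
    nvec <- nvec[rep(1, nrow(E)), , drop = FALSE]
  }
  rowSums(nvec * E)
}

#' Temporal extremum of the surface forcing
#'
#' Maximum over time of |n . E| at a surface point.  For the x-directed
#' waveforms this is \eqn{E_0 \sin\theta\,|\cos\varphi|}, which depends on
#' both angles; for the circularly polarized field the rotation wipes out
#' the azimuth dependence and the extremum is \eqn{E_0 \sin\theta}, at
#' least as large as the linear-field extremum everywhere on the sphere.
#' This is the geometric reason the rotating field drives the obstacle
#' boundary harder than a linear field of equal amplitude.
#'
#' @inheritParams surface_forcing
#' @return Scalar extremum (vectorized over angles).
#' @examples
#' surface_forcing_extremum(field_spec("CPEF", 2, 3), pi / 2, 0)  # 2
#' @export
surface_forcing_extremum <- function(spec, theta, phi_az) {
  stopifnot(inherits(spec, "field_spec"))
  switch(spec$kind,
         NONE = 0 * theta * phi_az,
         PDCEF = spec$E0 * sin(theta) * abs(cos(phi_az)),
         ACEF = spec$E0 * sin(theta) * abs(cos(phi_az)),
         CPEF = spec$E0 * sin(theta) + 0 * phi_az)
}
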