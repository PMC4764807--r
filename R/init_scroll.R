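#' Scroll wave pinned to the spherical obstacle
#'
#' Constructs a scroll wave anchored to the obstacle by the cross-field
#' protocol: a half-plane excited slab in u abutting the obstacle center
#' is crossed with a half-plane refractory block in v, the resulting free
#' wavefront end curls into a spiral around the obstacle, and the 2D
#' pattern is extruded uniformly along z so the filament spans the box
#' height.  The state is then relaxed with the field off until the
#' rotation is stationary, and pinning is verified via the filament
#' detector (at least one filament point within 2 dx of the obstacle
#' surface, filament spanning most of the z-extent).
#'
#' The generator is seed-free and bitwise reproducible: identical
#' parameters give identical states.
#'
#' @param params A \code{model_params} object.
#' @param domain A \code{phase_field_domain} with the obstacle.
#' @param relaxation_time Time units of field-free integration before the
#'   state counts as pinned; should cover at least 5 rotation periods.
#' @param v_block Recovery value of the refractory block.
#' @param verify Check the pinning postcondition (default TRUE).
#' @return A \code{medium_state} with attributes \code{filament} (point
#'   matrix), \code{omega_scroll} (rotation frequency estimated from the
#'   relaxation probes; NA when too few activations were recorded) and
#'   \code{probes} (the relaxation \code{probe_series}).
#' @export
pinned_scroll_init <- function(params, domain, relaxation_time = 30,
                               v_block = 0.6, verify = TRUE) {
  stopifnot(inherits(domain, "phase_field_domain"), domain$radius > 0)
  cx <- domain$center[1]
  cy <- domain$center[2]
  X <- array(rep(grid_coords(params, 1), times = prod(params$grid[2:3])),
             dim = params$grid)
  Y <- array(rep(rep(grid_coords(params, 2), each = params$grid[1]),
                 times = params$grid[3]), dim = params$grid)
  u <- array(0, dim = params$grid)
  v <- array(0, dim = params$grid)
  # single excited half space: one front at x = cx whose free end
  # terminates on the obstacle; the refractory block below y = cy keeps
  # it from closing, so the end curls and pins
  u[X >= cx] <- 1
  v[Y <= cy] <- v_block
  state <- enforce_rest_in_obstacle(medium_state(u, v, t = 0), domain)

  probes <- axis_probes(domain, params, axes = "xy")
  res <- integrate_medium(state, domain, field_spec("NONE"), params,
                          t_end = relaxation_time, probes = probes)
  state <- res$state
  state$t <- 0

  fil <- detect_filament(state, domain = domain, params = params)
  if (verify) {
    if (nrow(fil) == 0) stop("pinning failed: no filament after relaxation; ",
                             "try a larger obstacle radius")
    dists <- sqrt(rowSums(sweep(fil, 2, domain$center)^2)) - domain$radius
    if (min(dists) >= 2 * params$dx) {
      stop("pinning failed: filament detached from the obstacle ",
           "(min surface distance ", signif(min(dists), 3), ")")
    }
    zspan <- diff(range(fil[, 3]))
    if (zspan < 0.6 * (params$grid[3] - 1) * params$dx) {
      stop("pinning failed: filament does not span the z-extent")
    }
  }
  omega <- tryCatch(activation_frequency(res$probes)$omega,
                    error = function(e) NA_real_)
  if (is.finite(omega) && relaxation_time < 5 * (2 * pi / omega)) {
    warning("relaxation_time covers fewer than 5 rotation periods")
  }
  attr(state, "filament") <- fil
  attr(state, "omega_scroll") <- omega
  attr(state, "probes") <- res$probes
  state
}

#' Free scroll ring (closed filament loop)
#'
#' Builds an axisymmetric scroll ring with no obstacle: a hemispherical
#' excited shell of radius \code{ring_radius} (upper half space) with a
#' refractory block behind it and below the equatorial plane.  The free
#' circular rim of the shell curls into a rotating scroll ring whose
#' filament is a closed loop of roughly the requested radius.  Because
#' the kinetic parameters sit in the positive-filament-tension regime,
#' the ring subsequently shrinks ("collapsing scroll ring").
#'
#' @param params A \code{model_params} object.
#' @param ring_radius Target filament loop radius (space units).
#' @param settle_time Field-free integration time before the filament is
#'   detected and returned (time units).
#' @param shell_width Thickness of the initiating shell (space units).
#' @param curl_offset Radial distance by which the curling rim overshoots
#'   the excited shell (space units); the shell is placed this far inside
#'   the target radius.  Calibrated once for the default kinetics.
#' @param v_block Recovery value of the refractory block.
#' @return A \code{medium_state} (no obstacle) with attribute
#'   \code{filament}.  The detected loop radius oscillates with rotation
#'   phase by about two grid spacings around the target.
#' @export
scroll_ring_init <- function(params, ring_radius, settle_time = 2,
                             shell_width = 1.5, curl_offset = 1.8,
                             v_block = 0.6) {
  dom <- no_obstacle_domain(params)
  ctr <- grid_center(params)
  ext <- (params$grid - 1) * params$dx
  if (ring_radius + shell_width > min(ctr, ext - ctr)) {
    stop("ring does not fit inside the grid with margin")
  }
  if (ring_radius - curl_offset < shell_width) {
    stop("ring radius below the core size: the loop would collapse ",
         "immediately")
  }
  xs <- grid_coords(params, 1) - ctr[1]
  ys <- grid_coords(params, 2) - ctr[2]
  zs <- grid_coords(params, 3) - ctr[3]
  r <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
  dim(r) <- params$grid
  Z <- array(rep(zs, each = prod(params$grid[1:2])), dim = params$grid)
  u <- array(0, dim = params$grid)
  v <- array(0, dim = params$grid)
  r0 <- ring_radius - curl_offset
  u[r >= r0 - shell_width & r <= r0 & Z >= 0] <- 1
  v[r < r0 - shell_width | Z < 0] <- v_block
  state <- medium_state(u, v, t = 0)
  if (settle_time > 0) {
    state <- integrate_medium(state, dom, field_spec("NONE"), params,
                              t_end = settle_time)$state
  }
  fil <- detect_filament(state, domain = dom, params = params)
  attr(state, "filament") <- fil
  state
}
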