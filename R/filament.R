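# Min and max over the 8 corners of every grid cell of a 3D array.
cell_corner_range <- function(A) {
  d <- dim(A)
  i1 <- 1:(d[1] - 1); i2 <- 2:d[1]
  j1 <- 1:(d[2] - 1); j2 <- 2:d[2]
  k1 <- 1:(d[3] - 1); k2 <- 2:d[3]
  lo <- hi <- A[i1, j1, k1]
  for (ii in list(i1, i2)) for (jj in list(j1, j2)) for (kk in list(k1, k2)) {
    if (identical(ii, i1) && identical(jj, j1) && identical(kk, k1)) next
    B <- A[ii, jj, kk]
    lo <- pmin(lo, B)
    hi <- pmax(hi, B)
  }
  list(lo = lo, hi = hi)
}

#' Detect the scroll-wave filament
#'
#' The filament (the rotation center line of a scroll wave) is located as
#' the intersection of the isosurfaces \code{u = u_iso} and
#' \code{v = v_iso}.  Every grid cell whose corners straddle both
#' isovalues is a candidate; within each candidate the two fields are
#' linearized from the corner values and the point on the intersection
#' line of the two local isoplanes closest to the cell center is
#' returned.  Cells whose phase field drops below 0.5 (inside the
#' obstacle interface) are excluded.
#'
#' @param state A \code{medium_state}.
#' @param domain A \code{phase_field_domain} (or NULL for no obstacle).
#' @param params A \code{model_params} object.
#' @param u_iso Isovalue for u, default 0.5.
#' @param v_iso Isovalue for v; default \code{a/2 - b}, the mid-range of v
#'   on a rigidly rotating spiral.
#' @return An n x 3 matrix of filament points in space units (0 rows when
#'   no scroll wave is present).
#' @export
detect_filament <- function(state, domain = NULL, params,
                            u_iso = 0.5, v_iso = params$a / 2 - params$b) {
  u <- state$u
  v <- state$v
  d <- dim(u)
  dx <- params$dx
  ru <- cell_corner_range(u)
  rv <- cell_corner_range(v)
  cand <- ru$lo < u_iso & ru$hi > u_iso & rv$lo < v_iso & rv$hi > v_iso
  if (!is.null(domain) && domain$radius > 0) {
    rp <- cell_corner_range(domain$phi)
    cand <- cand & rp$lo >= 0.5
  }
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 3))
  pts <- matrix(NA_real_, nrow(idx), 3)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    cu <- u[i:(i + 1), j:(j + 1), k:(k + 1)]
    cv <- v[i:(i + 1), j:(j + 1), k:(k + 1)]
    gu <- c(mean(cu[2, , ] - cu[1, , ]), mean(cu[, 2, ] - cu[, 1, ]),
            mean(cu[, , 2] - cu[, , 1])) / dx
    gv <- c(mean(cv[2, , ] - cv[1, , ]), mean(cv[, 2, ] - cv[, 1, ]),
            mean(cv[, , 2] - cv[, , 1])) / dx
    G <- rbind(gu, gv)
    rhs <- c(u_iso - mean(cu), v_iso - mean(cv))
    M <- G %*% t(G)
    if (abs(det(M)) < 1e-12) next
    p <- as.numeric(t(G) %*% solve(M, rhs))
    p <- pmin(pmax(p, -0.75 * dx), 0.75 * dx)  # keep inside the cell
    pts[r, ] <- c(i - 0.5, j - 0.5, k - 0.5) * dx + p
  }
  pts[stats::complete.cases(pts), , drop = FALSE]
}

#' Connected components of a filament point set
#'
#' Single-linkage clustering: two points belong to the same component
#' when a chain of steps no longer than \code{link} connects them.
#' Used to tell reentrant scroll filaments (components spanning the box
#' height) from the short seams that strongly driven wave surfaces
#' carry.
#'
#' @param points n x 3 matrix of filament points.
#' @param link Linkage distance (space units).
#' @return Integer vector of component labels (length n).
#' @export
filament_components <- function(points, link) {
  n <- nrow(points)
  if (n == 0) return(integer(0))
  adj <- as.matrix(stats::dist(points)) <= link
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    front <- i
    comp[i] <- cur
    while (length(front)) {
      nb <- which(adj[front[1], ] & is.na(comp))
      comp[nb] <- cur
      front <- c(front[-1], nb)
    }
  }
  comp
}

# Which components of a filament point set are reentrant (scroll-like)?
# A scroll filament is transmural: it reaches the no-flux z-walls (the
# obstacle may hide its equatorial section, so wall contact rather than
# total span is the robust signature) or spans most of the box height.
# The isosurface seams riding on strongly driven wave trains are short
# arcs away from the walls.
reentrant_flags <- function(points, comp, zext, span_frac, wall_tol) {
  vapply(unique(comp), function(k) {
    z <- points[comp == k, 3]
    min(z) < wall_tol || max(z) > zext - wall_tol ||
      diff(range(z)) >= span_frac * zext
  }, logical(1))
}

#' Filament trace container
#'
#' Time-indexed filament point sets with derived distances to the
#' obstacle surface and to the outer domain box.  Each sample is also
#' decomposed into connected components, and components that reach the
#' z-walls (within \code{wall_tol}) or span at least \code{span_frac}
#' of the box height are flagged as reentrant (transmural): a
#' scroll-wave filament crosses the medium wall to wall (its equatorial
#' section may be hidden by the obstacle), whereas the isosurface seams
#' that driven wave trains carry are short arcs away from the walls.
#' The per-sample summaries \code{n_spanning},
#' \code{span_surface_dist} and \code{span_in_box} refer to those
#' reentrant components only.
#'
#' @param times Sample times.
#' @param points List of n x 3 point matrices, one per sample time.
#' @param domain A \code{phase_field_domain} (for center/radius).
#' @param params A \code{model_params} object (grid geometry).
#' @param span_frac Fraction of the box height a component must span to
#'   count as reentrant; default 0.6.
#' @param wall_tol Wall-contact tolerance (space units); default 4 dx.
#' @param link Linkage distance for components; default 3 dx.
#' @param box_half_width Half width of the success box used for the
#'   \code{span_in_box} flag; default 2 R.
#' @return An object of class \code{"filament_trace"} with per-sample
#'   \code{n_points}, \code{min_surface_dist} (Inf when no points),
#'   \code{max_center_dist}, \code{n_spanning},
#'   \code{span_surface_dist} and \code{span_in_box}.
#' @export
filament_trace <- function(times, points, domain, params,
                           span_frac = 0.6, wall_tol = 4 * params$dx,
                           link = 3 * params$dx,
                           box_half_width = 2 * domain$radius) {
  stopifnot(length(times) == length(points))
  n_points <- vapply(points, nrow, integer(1))
  center <- domain$center
  zext <- (params$grid[3] - 1) * params$dx
  surf <- vapply(seq_along(points), function(s) {
    p <- points[[s]]
    if (nrow(p) == 0) return(Inf)
    d <- sqrt(rowSums(sweep(p, 2, center)^2)) - domain$radius
    max(0, min(d))
  }, numeric(1))
  maxc <- vapply(seq_along(points), function(s) {
    p <- points[[s]]
    if (nrow(p) == 0) return(-Inf)
    max(abs(sweep(p, 2, center)))
  }, numeric(1))
  n_span <- integer(length(points))
  span_surf <- rep(Inf, length(points))
  span_box <- logical(length(points))
  for (s in seq_along(points)) {
    p <- points[[s]]
    if (nrow(p) == 0) next
    comp <- filament_components(p, link)
    flags <- reentrant_flags(p, comp, zext, span_frac, wall_tol)
    for (ki in seq_along(unique(comp))) {
      if (!flags[ki]) next
      q <- p[comp == unique(comp)[ki], , drop = FALSE]
      n_span[s] <- n_span[s] + 1L
      d <- sqrt(rowSums(sweep(q, 2, center)^2)) - domain$radius
      span_surf[s] <- min(span_surf[s], max(0, min(d)))
      if (any(apply(abs(sweep(q, 2, center)), 1, max) < box_half_width)) {
        span_box[s] <- TRUE
      }
    }
  }
  structure(list(times = times, points = points, n_points = n_points,
                 min_surface_dist = surf, max_center_dist = maxc,
                 n_spanning = n_span, span_surface_dist = span_surf,
                 span_in_box = span_box,
                 box_half_width = box_half_width, zext = zext,
                 link = link, span_frac = span_frac, wall_tol = wall_tol,
                 center = center, radius = domain$radius),
            class = "filament_trace")
}

#' @export
print.filament_trace <- function(x, ...) {
  cat(sprintf("Filament trace: %d samples over t = [%g, %g]\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.filament_trace <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$times), function(s) {
    p <- x$points[[s]]
    if (nrow(p) == 0) return(NULL)
    data.frame(time = x$times[s], x = p[, 1], y = p[, 2], z = p[, 3])
  }))
}

#' Classify detachment and removal of a pinned scroll wave
#'
#' Works through a \code{filament_trace} in terms of its reentrant
#' (transmural, box-spanning) filament components: detachment is the
#' first sample time at which no reentrant component reaches within
#' \code{detach_dist} of the obstacle surface; removal is the first
#' sample time at which no reentrant component has any point left
#' inside the obstacle-centered success box (a cube of the given half
#' width).  A removal within \code{t_limit} time units of field onset
#' counts as successful.  Confining the classification to reentrant
#' components matters because strongly driven wave trains themselves
#' carry short isosurface seams that are not rotation filaments.
#'
#' @param trace A \code{filament_trace}.
#' @param box_half_width Half width of the success box (space units);
#'   default twice the obstacle radius.
#' @param t_limit Success deadline (time units) measured from the first
#'   sample, default 500.
#' @param dx Grid spacing used for the detachment threshold.
#' @param detach_dist Surface-distance threshold for detachment (space
#'   units); default 2 dx.  An attached filament's tissue sections sit
#'   about one grid spacing outside the sphere, so the threshold must
#'   exceed that.
#' @return List with \code{success}, \code{t_detach}, \code{t_removed}
#'   (times relative to the first sample; NA when never reached).
#' @export
classify_removal <- function(trace, box_half_width = trace$box_half_width,
                             t_limit = 500, dx, detach_dist = 2 * dx) {
  stopifnot(inherits(trace, "filament_trace"))
  if (length(trace$times) == 0) stop("empty filament trace")
  t0 <- trace$times[1]
  detached <- trace$n_spanning == 0L | trace$span_surface_dist > detach_dist
  if (!isTRUE(all.equal(box_half_width, trace$box_half_width))) {
    # recompute the in-box flag for a non-default box
    outside <- vapply(seq_along(trace$times), function(s) {
      p <- trace$points[[s]]
      if (nrow(p) == 0) return(TRUE)
      comp <- filament_components(p, trace$link)
      flags <- reentrant_flags(p, comp, trace$zext, trace$span_frac,
                               trace$wall_tol)
      for (ki in seq_along(unique(comp))) {
        if (!flags[ki]) next
        q <- p[comp == unique(comp)[ki], , drop = FALSE]
        if (any(apply(abs(sweep(q, 2, trace$center)), 1, max) <
                  box_half_width)) {
          return(FALSE)
        }
      }
      TRUE
    }, logical(1))
  } else {
    outside <- !trace$span_in_box
  }
  t_detach <- if (any(detached)) trace$times[which(detached)[1]] - t0 else NA
  t_removed <- if (any(outside)) trace$times[which(outside)[1]] - t0 else NA
  list(success = is.finite(t_removed) && !is.na(t_removed) &&
         t_removed <= t_limit,
       t_detach = t_detach, t_removed = t_removed,
       box_half_width = box_half_width, t_limit = t_limit)
}

#' Is the medium quiescent?
#'
#' TRUE iff the maximum of u over tissue points is below \code{tol}.
#'
#' @param state A \code{medium_state}.
#' @param domain Optional \code{phase_field_domain}; when given, only
#'   active (tissue) points are inspected.
#' @param tol Threshold on u, default 0.01.
#' @return Logical scalar.
#' @export
is_quiescent <- function(state, domain = NULL, tol = 0.01) {
  u <- state$u
  if (!is.null(domain)) u <- u[domain$active == 1L]
  max(u) < tol
}
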