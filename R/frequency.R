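#' Probe time series container
#'
#' Uniformly sampled u values at one or more probe positions.
#'
#' @param positions n x 3 matrix of probe positions (space units).
#' @param times Strictly increasing, uniformly spaced sample times.
#' @param u Matrix of u samples, one column per probe.
#' @return An object of class \code{"probe_series"}.
#' @export
probe_series <- function(positions, times, u) {
  positions <- rbind(positions)
  if (is.null(u)) u <- matrix(numeric(0), 0, nrow(positions))
  u <- cbind(u)
  stopifnot(nrow(u) == length(times), ncol(u) == nrow(positions))
  if (length(times) > 2) {
    dts <- diff(times)
    stopifnot(all(dts > 0), diff(range(dts)) < 1e-6 * mean(dts) + 1e-12)
  }
  structure(list(positions = positions, times = times, u = u),
            class = "probe_series")
}

#' @export
print.probe_series <- function(x, ...) {
  cat(sprintf("Probe series: %d probes, %d samples", ncol(x$u),
              length(x$times)))
  if (length(x$times)) {
    cat(sprintf(" over t = [%g, %g]", x$times[1],
                x$times[length(x$times)]))
  }
  cat("\n")
  invisible(x)
}

# Upward threshold-crossing times of one series, linearly interpolated.
upward_crossings <- function(times, u, threshold) {
  below <- u < threshold
  idx <- which(below[-length(u)] & !below[-1])
  if (!length(idx)) return(numeric(0))
  frac <- (threshold - u[idx]) / (u[idx + 1] - u[idx])
  times[idx] + frac * (times[idx + 1] - times[idx])
}

#' Activation frequency from a probe series
#'
#' Detects upward crossings of u through \code{threshold}, discards the
#' first two (transient), and estimates the angular frequency as
#' \eqn{\omega = 2\pi / \overline{\Delta t}} from the mean inter-crossing
#' interval.  Also reports the coefficient of variation of the intervals,
#' used downstream to flag irregular (broken) wave trains.
#'
#' @param series A \code{probe_series} (a single column is used) or a
#'   list with \code{times} and \code{u} vectors.
#' @param threshold Crossing threshold on u, default 0.5.
#' @param column Which probe column to use, default 1.
#' @param discard Number of initial crossings treated as transient.
#' @return List with \code{omega}, \code{cv}, \code{n_crossings},
#'   \code{crossings} (times) and \code{intervals}.
#' @export
activation_frequency <- function(series, threshold = 0.5, column = 1,
                                 discard = 2) {
  if (inherits(series, "probe_series")) {
    times <- series$times
    u <- series$u[, column]
  } else {
    times <- series$times
    u <- series$u
  }
  cross <- upward_crossings(times, u, threshold)
  if (length(cross) > discard) cross <- cross[-seq_len(discard)] else
    cross <- numeric(0)
  if (length(cross) < 4) {
    stop("insufficient activations: need at least 4 upward crossings ",
         "after the transient, got ", length(cross))
  }
  iv <- diff(cross)
  list(omega = 2 * pi / mean(iv), cv = stats::sd(iv) / mean(iv),
       n_crossings = length(cross), crossings = cross, intervals = iv)
}

# Number of upward crossings (no transient discard); 0 for flat series.
count_activations <- function(series, threshold = 0.5, column = 1) {
  length(upward_crossings(series$times, series$u[, column], threshold))
}

#' Default probe positions around the obstacle
#'
#' Probes placed a fixed offset outside the obstacle surface along the
#' coordinate axes.
#'
#' @param domain A \code{phase_field_domain}.
#' @param params A \code{model_params} object.
#' @param offset Distance outside the surface, default 10 dx.
#' @param axes "all" for all six axis directions, "xy" for +x and +y.
#' @return Matrix of probe positions.
#' @export
axis_probes <- function(domain, params, offset = 10 * params$dx,
                        axes = c("all", "xy")) {
  axes <- match.arg(axes)
  r <- domain$radius + offset
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  if (axes == "xy") dirs <- dirs[c(1, 3), , drop = FALSE]
  sweep(r * dirs, 2, domain$center, "+")
}
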