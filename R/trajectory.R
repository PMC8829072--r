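#' Trajectory container
#'
#' A trajectory is a data frame with a time column \code{t} followed by
#' one density column per compartment (for the ISVOR model:
#' \code{I, S, V, O, R}; baselines use their own role columns).  Metadata
#' (model kind, variant, parameters, seeds, integrator) travels in the
#' \code{"metadata"} attribute.
#'
#' @param df data frame whose first column is \code{t}, strictly
#'   increasing.
#' @param metadata named list of provenance information.
#' @return an object of classes \code{"isvor_trajectory"} and
#'   \code{"data.frame"}.
#' @keywords internal
#' @export
new_trajectory <- function(df, metadata = list()) {
  stopifnot(is.data.frame(df), names(df)[1L] == "t")
  if (nrow(df) > 1L && any(diff(df$t) <= 0))
    stop("trajectory times must be strictly increasing", call. = FALSE)
  structure(df, metadata = metadata,
            class = c("isvor_trajectory", "data.frame"))
}

#' @rdname new_trajectory
#' @param x a trajectory.
#' @param ... ignored.
#' @export
print.isvor_trajectory <- function(x, ...) {
  md <- attr(x, "metadata")
  cat("trajectory (", md$kind %||% "unknown", "): ", nrow(x),
      " time points, t in [", x$t[1L], ", ", x$t[nrow(x)], "]\n", sep = "")
  roles <- setdiff(names(x), "t")
  last <- vapply(x[nrow(x), roles], as.numeric, 0)
  cat("final densities:",
      paste(sprintf("%s=%.4g", roles, last), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname new_trajectory
#' @param y ignored.
#' @param cols which density columns to draw (default: all).
#' @param main,xlab,ylab usual graphics parameters.
#' @export
plot.isvor_trajectory <- function(x, y = NULL, cols = NULL,
                                  main = "compartment densities",
                                  xlab = "t", ylab = "density", ...) {
  roles <- setdiff(names(x), "t")
  if (!is.null(cols)) roles <- intersect(roles, cols)
  graphics::matplot(x$t, as.matrix(x[, roles, drop = FALSE]), type = "l",
                    lty = 1, lwd = 2, col = seq_along(roles),
                    main = main, xlab = xlab, ylab = ylab, ...)
  graphics::legend("right", legend = roles, col = seq_along(roles),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peak density of the rumor diffusers
#'
#' The diffuser density is the sum \eqn{S(t) + V(t)} of the spreader and
#' variation compartments; its maximum over time is the headline summary
#' of a rumor outbreak's contagion capacity.  Ties are broken to the
#' earliest attaining time.
#'
#' @param traj a trajectory with columns \code{S} and \code{V} (or the
#'   columns named in \code{cols}).
#' @param cols columns to sum before taking the peak.
#' @return a named numeric vector \code{c(value, time)}.
#' @examples
#' tr <- isvor_meanfield(isvor_params(), isvor_state(I = 0.999, S = 0.001),
#'                       t_max = 20)
#' peak_diffuser(tr)
#' @export
peak_diffuser <- function(traj, cols = c("S", "V")) {
  stopifnot(nrow(traj) >= 1L, all(cols %in% names(traj)))
  tot <- unname(rowSums(as.matrix(traj[, cols, drop = FALSE])))
  i <- which.max(tot)   # which.max returns the first maximum
  c(value = tot[i], time = traj$t[i])
}
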