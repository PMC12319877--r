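# S3 model interface of the precomputed session.

#' @export
print.tms_realtime <- function(x, ...) {
  cat("Real-time TMS E-field session\n")
  cat(sprintf("  modes: %d (singular values %.3g .. %.3g)\n", x$n_modes,
              x$sv[1], x$sv[x$n_modes]))
  cat(sprintf("  head: %d tets (%d ROI); Huygens: %d facets at %g mm\n",
              x$meta$n_tets, x$meta$n_roi, nrow(x$huygens$tris),
              x$meta$huygens_distance))
  cat(sprintf("  coil: '%s'; grid %d x %d x %d at %g mm\n", x$coil$name,
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$grid$spacing))
  cat(sprintf("  evaluation surface: %d facets; dIdt = %.3g A/s\n",
              nrow(x$eval_surface$tris), x$dIdt))
  invisible(x)
}

#' @export
summary.tms_realtime <- function(object, ...) {
  s <- object$sv[seq_len(object$n_modes)]
  out <- list(n_modes = object$n_modes,
              sv_decay = s[length(s)] / s[1],
              sv_quartiles = stats::quantile(s / s[1]),
              n_facets_huygens = nrow(object$huygens$tris),
              n_facets_eval = nrow(object$eval_surface$tris),
              grid_nodes = prod(object$grid$dims),
              precompute_s = object$meta$elapsed_s,
              seed = object$seed)
  class(out) <- "summary.tms_realtime"
  out
}

#' @export
print.summary.tms_realtime <- function(x, ...) {
  cat(sprintf("tms_realtime session: %d modes, relative sv decay %.2e\n",
              x$n_modes, x$sv_decay))
  cat(sprintf("  Huygens facets %d, evaluation facets %d, grid nodes %d\n",
              x$n_facets_huygens, x$n_facets_eval, x$grid_nodes))
  cat(sprintf("  precompute time %.1f s (seed %d)\n",
              x$precompute_s, x$seed))
  invisible(x)
}

#' Predict the brain E-field for a coil placement
#'
#' The online stage as a `predict` method: equivalent to
#' [realtime_solve()].
#'
#' @param object a `tms_realtime` session.
#' @param placement a [placement()] or rigid 4x4 matrix.
#' @param n_modes truncation of the mode expansion.
#' @param dIdt coil current peak derivative, A/s.
#' @param ... unused.
#' @return n_eval_facets x 3 E-field matrix (V/m) with attribute
#'   `"coefficients"`.
#' @export
predict.tms_realtime <- function(object, placement,
                                 n_modes = object$n_modes,
                                 dIdt = object$dIdt, ...) {
  if (!inherits(placement, "placement"))
    placement <- placement_from_matrix(placement)
  realtime_solve(object, placement, n_use = n_modes, dIdt = dIdt)
}

#' Mode coefficients for a placement
#'
#' @inheritParams predict.tms_realtime
#' @param session a `tms_realtime` session.
#' @return coefficient vector `a` (unit-dIdt convention).
#' @export
mode_coefficients <- function(session, placement) {
  if (!inherits(placement, "placement"))
    placement <- placement_from_matrix(placement)
  attr(realtime_solve(session, placement, n_use = 0L), "coefficients")
}

#' Singular-value decay plot
#'
#' @param x a `tms_realtime` session.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tms_realtime <- function(x, ...) {
  s <- x$sv[seq_len(x$n_modes)]
  graphics::plot(seq_along(s), s / s[1], log = "y", type = "l",
                 xlab = "mode index", ylab = "relative singular value",
                 main = "Mode spectrum", ...)
  invisible(x)
}

#' Simulate random coil placements and their fields
#'
#' Draws `nsim` random tangential placements on the session's scalp
#' surface and evaluates the real-time field for each.
#'
#' @param object a `tms_realtime` session.
#' @param nsim number of placements.
#' @param seed RNG seed.
#' @param n_modes truncation used for the fields.
#' @param ... unused.
#' @return list with `placements` and `fields` (list of n x 3 matrices).
#' @export
simulate.tms_realtime <- function(object, nsim = 1, seed = 1L,
                                  n_modes = object$n_modes, ...) {
  pl <- sample_scalp_placements(object$scalp, nsim, seed = seed,
                                standoff = object$meta$standoff)
  list(placements = pl,
       fields = lapply(pl, function(T)
         realtime_solve(object, T, n_use = n_modes)))
}
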