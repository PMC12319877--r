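# Precomputed Cartesian grid of coil primary fields in the coil frame,
# rigid point transforms, and component-wise trilinear interpolation.

#' Precompute coil primary fields on a Cartesian grid
#'
#' Samples `E_p` and `H_p` (unit dI/dt, coil frame) at the nodes of an
#' axis-aligned grid.  The bounds must be large enough to contain the
#' Huygens surface transformed by the inverse of every admissible
#' placement; [default_grid_bounds()] builds such an envelope for
#' tangential placements.
#'
#' @param coil a [coil_model()].
#' @param spacing grid spacing in mm (default 4).
#' @param bounds list with numeric `xlim`, `ylim`, `zlim` (mm, coil
#'   frame); each upper limit is rounded up to a whole number of cells.
#' @return object of class `primary_field_grid`: axes, dims, and node
#'   sample matrices `E`, `H` (n_nodes x 3, x fastest axis).
#' @export
build_primary_grid <- function(coil, spacing = 4, bounds) {
  if (spacing <= 0) stop("spacing must be positive")
  ax <- lapply(list(bounds$xlim, bounds$ylim, bounds$zlim), function(l) {
    n <- ceiling((l[2] - l[1]) / spacing - 1e-9)
    seq(l[1], by = spacing, length.out = n + 1L)
  })
  dims <- vapply(ax, length, integer(1))
  pts <- cbind(rep(ax[[1]], times = dims[2] * dims[3]),
               rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
               rep(ax[[3]], each = dims[1] * dims[2]))
  pf <- coil_primary_fields(coil, pts, dIdt = 1)
  structure(list(axes = ax, dims = dims, spacing = spacing,
                 origin = c(ax[[1]][1], ax[[2]][1], ax[[3]][1]),
                 E = pf$E, H = pf$H, coil_name = coil$name),
            class = "primary_field_grid")
}

#' @export
print.primary_field_grid <- function(x, ...) {
  cat(sprintf("primary_field_grid: %d x %d x %d nodes at %g mm ('%s')\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$coil_name))
  invisible(x)
}

#' Grid envelope for tangential placements
#'
#' Bounds (coil frame) of a box guaranteed to contain a closed surface of
#' circumradius `R_h` for every placement tangent to it at up to
#' `standoff` mm: laterally `[-(R_h+margin), R_h+margin]`, vertically from
#' `-(2 R_h + standoff + margin)` up to `+margin`.
#'
#' @param surface the Huygens [tri_surface()] (head frame).
#' @param standoff maximum coil standoff from the surface, mm.
#' @param margin extra clearance, mm.
#' @return list of `xlim`, `ylim`, `zlim`.
#' @export
default_grid_bounds <- function(surface, standoff = 5, margin = 8) {
  ctr <- colMeans(surface$nodes)
  rh <- max(row_norms(sweep(surface$nodes, 2L, ctr)))
  list(xlim = c(-(rh + margin), rh + margin),
       ylim = c(-(rh + margin), rh + margin),
       zlim = c(-(2 * rh + standoff + margin), margin))
}

#' Apply a rigid placement transform to points
#'
#' Maps points by `T` (coil to head frame) or by `T^-1 = [R' | -R't]`
#' (head to coil frame; the online default, which moves the Huygens
#' surface into the grid instead of moving the grid).
#'
#' @param points n x 3 matrix, mm.
#' @param T a [placement()] or rigid 4x4 matrix.
#' @param inverse apply the inverse transform.
#' @return transformed n x 3 matrix.
#' @export
transform_points <- function(points, T, inverse = FALSE) {
  if (!inherits(T, "placement")) T <- placement_from_matrix(T)
  pts <- as_matrix3(points, "points")
  R <- T[1:3, 1:3]; t <- T[1:3, 4]
  if (inverse) sweep(pts, 2L, t) %*% R
  else sweep(pts %*% t(R), 2L, -t)
}

#' Trilinear interpolation of gridded primary fields
#'
#' Component-wise trilinear interpolation of the six field components at
#' arbitrary points; exact for fields affine in position.  Points outside
#' the grid bounds raise an error reporting how many fall outside (no
#' extrapolation).
#'
#' @param grid a `primary_field_grid`.
#' @param points n x 3 query points, mm (coil frame).
#' @return list of matrices `E`, `H` (n x 3).
#' @export
interpolate_fields <- function(grid, points) {
  pts <- as_matrix3(points, "points")
  d <- grid$dims
  u <- sweep(pts, 2L, grid$origin) / grid$spacing
  out_lo <- u < -1e-9
  out_hi <- sweep(u, 2L, d - 1L) > 1e-9
  bad <- rowSums(out_lo | out_hi) > 0
  if (any(bad))
    stop(sum(bad), " point(s) outside the primary-field grid bounds; ",
         "extent exceeded by up to ",
         format(max(abs(pmax(sweep(u, 2L, d - 1L), 0, -u)) * grid$spacing),
                digits = 3), " mm")
  i0 <- pmin(pmax(floor(u), 0), matrix(d - 2L, nrow(u), 3L, byrow = TRUE))
  f <- u - i0
  base <- 1L + i0[, 1] + d[1] * (i0[, 2] + d[2] * i0[, 3])
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  interp_one <- function(V) {
    acc <- matrix(0, nrow(pts), ncol(V))
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      w <- (if (cx) f[, 1] else 1 - f[, 1]) *
           (if (cy) f[, 2] else 1 - f[, 2]) *
           (if (cz) f[, 3] else 1 - f[, 3])
      idx <- base + cx * sx + cy * sy + cz * sz
      acc <- acc + w * V[idx, , drop = FALSE]
    }
    acc
  }
  list(E = interp_one(grid$E), H = interp_one(grid$H))
}
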