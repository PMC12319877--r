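# White-noise magnetic surface currents and the volume-weighted QR+SVD
# construction of the orthonormal E-field mode basis.

#' Gaussian white-noise magnetic surface currents
#'
#' Draws, for each realization, an i.i.d. standard-normal 3-vector of
#' magnetic surface current density at every facet of the Huygens surface.
#' The RNG stream is keyed per realization (a sub-seed derived from the
#' master seed and the realization index), so realization `i` is
#' bit-reproducible from `(seed, i)` and independent of how many
#' realizations are requested; the caller's RNG state is untouched.
#'
#' @param surface the Huygens [tri_surface()] (offset scalp).
#' @param n_realizations number of realizations (>= 1).
#' @param seed master seed.
#' @return object of class `noise_set`: array `W` of dim
#'   `(n_facets, 3, n_realizations)` (arbitrary units), plus `seed` and the
#'   facet count.
#' @export
sample_white_noise_currents <- function(surface, n_realizations, seed = 1L) {
  if (n_realizations < 1L) stop("n_realizations must be >= 1")
  nd <- nrow(surface$tris)
  seeds <- substream_seeds(seed, n_realizations)
  W <- array(0, dim = c(nd, 3L, n_realizations))
  for (i in seq_len(n_realizations))
    W[, , i] <- with_substream(seeds[i],
                               matrix(stats::rnorm(3L * nd), nd, 3L))
  structure(list(W = W, seed = seed, n_facets = nd,
                 n_realizations = n_realizations,
                 surface_hash = light_hash(surface$tris)),
            class = "noise_set")
}

# flatten a (nd x 3 x R) array into an nd x 3R matrix of stacked blocks
flatten_realizations <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(1L, 2L, 3L)), d[1], d[2] * d[3])
}

#' Primary E-field of magnetic surface currents
#'
#' Single-point-quadrature free-space field of piecewise-constant magnetic
#' surface current densities:
#' `E(r) = -(1/4pi) sum_j A_j W_j x (r - r_j) / |r - r_j|^3`.
#' Direct summation over facets; evaluation points must be strictly off
#' the facet centers (singular kernel).
#'
#' @param W n_facets x 3 matrix of facet current densities (one
#'   realization), or an `(n_facets, 3, R)` array / `noise_set` for many.
#' @param surface the source [tri_surface()].
#' @param points n x 3 evaluation points, mm.
#' @return n x 3 matrix (single realization) or n x 3R matrix (stacked
#'   blocks of three columns) of E-fields, in the units of `W`.
#' @export
magnetic_current_primary_efield <- function(W, surface, points) {
  if (inherits(W, "noise_set")) W <- W$W
  single <- is.matrix(W)
  Wm <- if (single) W else flatten_realizations(W)
  if (nrow(Wm) != nrow(surface$tris))
    stop("one current vector per facet required")
  pts <- as_matrix3(points, "points") * MM_TO_M
  src <- surface$center * MM_TO_M
  area_m2 <- surface$area * MM_TO_M^2
  s <- pair_field_sums(pts, src, Wm * area_m2, want_inv = FALSE,
                       want_cross = TRUE, min_dist = 1e-9)
  -s$cross / (4 * pi)
}

#' Orthonormal mode basis by volume-weighted QR+SVD
#'
#' Stacks the ROI fields of all noise realizations into a matrix `Z` whose
#' column `i` holds the components of field `i` scaled by `sqrt(V_k)`
#' (element volume), so that the Euclidean dot product of two columns
#' equals the volume-weighted inner product of the fields.  An economic QR
#' (`Z = QR`) followed by an SVD of `R` yields `U = Q Utilde`; mode `i` is
#' the `i`-th column of `U` with the `sqrt(V_k)` weight divided back out.
#' Modes are ordered by non-increasing singular value and truncated to
#' `n_keep`; they are orthonormal under the volume-weighted inner product.
#'
#' @param noise_fields ROI E-fields of the realizations: an
#'   `(n_roi, 3, R)` array or `n_roi x 3R` matrix.
#' @param mesh the [head_mesh()] the fields live on.
#' @param n_keep number of modes to retain (default: all realizations).
#' @return object of class `mode_basis`: `modes` (3*n_roi x n_keep matrix,
#'   mode `i` stacked per ROI tet as x,y,z), `sv` (singular values),
#'   `vol_m3` (ROI element volumes), `roi_index` (tet indices), `n_modes`.
#' @export
build_basis <- function(noise_fields, mesh, n_keep = NULL) {
  if (is.array(noise_fields) && length(dim(noise_fields)) == 3L)
    noise_fields <- flatten_realizations(noise_fields)
  nf <- as.matrix(noise_fields)
  n_roi <- sum(mesh$roi)
  if (nrow(nf) != n_roi)
    stop("noise fields must be given on the ", n_roi, " ROI tets")
  R <- ncol(nf) %/% 3L
  if (is.null(n_keep)) n_keep <- R
  if (n_keep > R) stop("n_keep exceeds the number of realizations")

  vol_m3 <- mesh$volume[mesh$roi] * MM_TO_M^3
  sw <- sqrt(rep(vol_m3, each = 3L))
  # column i of Z: sqrt(V)-weighted stacked field i
  Z <- matrix(0, 3L * n_roi, R)
  for (r in seq_len(R))
    Z[, r] <- as.vector(t(nf[, (3L * r - 2L):(3L * r), drop = FALSE])) * sw

  qrz <- qr(Z)
  Rm <- qr.R(qrz)
  sv <- svd(Rm)
  U <- qr.qy(qrz, rbind(sv$u, matrix(0, nrow(Z) - ncol(Rm), ncol(sv$u))))
  d <- sv$d
  rank_ok <- d / d[1] >= 1e-12
  if (!all(rank_ok[seq_len(n_keep)])) {
    warning("rank-deficient realization set: truncating to rank ",
            sum(rank_ok))
    n_keep <- min(n_keep, sum(rank_ok))
  }
  modes <- U[, seq_len(n_keep), drop = FALSE] / sw
  structure(list(modes = modes, sv = d, vol_m3 = vol_m3,
                 roi_index = which(mesh$roi), n_modes = n_keep,
                 mesh_hash = light_hash(list(mesh$tets, mesh$region))),
            class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf("mode_basis: %d modes on %d ROI tets; sv[1]=%.3g, sv[n]=%.3g\n",
              x$n_modes, length(x$vol_m3), x$sv[1], x$sv[x$n_modes]))
  invisible(x)
}

#' Gram matrix of a mode basis under the volume-weighted inner product
#'
#' `G[i, j] = sum_k V_k M_i(k) . M_j(k)`; identity for an orthonormal
#' basis.
#'
#' @param basis a `mode_basis`.
#' @return n_modes x n_modes matrix.
#' @export
basis_gram <- function(basis) {
  w <- rep(basis$vol_m3, each = 3L)
  crossprod(basis$modes, w * basis$modes)
}

# per-tet 3-column view of mode i
mode_field <- function(basis, i) {
  matrix(basis$modes[, i], ncol = 3L, byrow = TRUE)
}
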