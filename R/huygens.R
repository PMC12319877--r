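# Per-mode E/H fields on the Huygens surface radiated by the head volume
# currents, the equivalent surface current densities, and the dense
# reciprocity operator used by the online stage.

#' Fields of head volume currents on an exterior surface
#'
#' Single-point-per-tetrahedron quadrature of the magnetoquasistatic
#' fields of the total (impressed + conduction) volume current density
#' `J = M + sigma E` over the whole head, evaluated at the facet centers
#' of a surface strictly outside the head:
#' `E(r_j) = -(mu0/4pi) sum_k V_k J_k / |r_j - c_k|` (inductive part of
#' the vector potential, spatial factor of the peak current derivative)
#' and `H(r_j) = (1/4pi) sum_k V_k J_k x (r_j - c_k) / |r_j - c_k|^3`
#' (Biot-Savart).  Direct chunked summation in double precision.
#'
#' @param mesh the [head_mesh()] carrying the currents.
#' @param currents per-tet total current density: n_tets x 3 matrix for
#'   one mode or n_tets x 3R for R stacked modes (source units / m^2).
#' @param surface observation [tri_surface()]; every facet center must be
#'   at least `min_gap` mm away from every tet centroid.
#' @param min_gap minimum source-observer distance, mm (default 0.2).
#' @return object of class `surface_field_set`: matrices `E` and `H`
#'   (n_facets x 3R) at facet centers, plus the surface reference.
#' @export
mode_fields_on_surface <- function(mesh, currents, surface, min_gap = 0.2) {
  cur <- as.matrix(currents)
  if (nrow(cur) != nrow(mesh$tets))
    stop("one current vector per tetrahedron required (whole head)")
  inside <- locate_points(mesh, surface$center, error_outside = FALSE)
  if (any(!is.na(inside)))
    stop(sum(!is.na(inside)),
         " surface point(s) inside or touching the head")
  obs <- surface$center * MM_TO_M
  src <- mesh$centroid * MM_TO_M
  w <- cur * (mesh$volume * MM_TO_M^3)
  s <- tryCatch(
    pair_field_sums(obs, src, w, want_inv = TRUE, want_cross = TRUE,
                    min_dist = min_gap * MM_TO_M),
    error = function(e)
      stop("surface point inside or touching the head: ",
           conditionMessage(e)))
  structure(list(E = -(MU0 / (4 * pi)) * s$inv,
                 H = s$cross / (4 * pi),
                 surface = surface),
            class = "surface_field_set")
}

# convenience wrapper: total current of one impressed mode
total_mode_current <- function(mesh, mode_field_roi, conduction_field) {
  J <- conduction_field * mesh$sigma
  J[mesh$roi, ] <- J[mesh$roi, ] + mode_field_roi
  J
}

#' Equivalent electric and magnetic surface currents
#'
#' Surface-equivalence boundary conditions on the Huygens surface:
#' `J_S = n x H` and `K_S = -n x E` per facet and mode; both are exactly
#' tangential by construction.
#'
#' @param fields a `surface_field_set` from [mode_fields_on_surface()].
#' @param surface the Huygens [tri_surface()] (outward normals).
#' @return object of class `huygens_current_set` with matrices `JS` and
#'   `KS` (n_facets x 3R) and the surface reference.
#' @export
equivalent_currents <- function(fields, surface = fields$surface) {
  nd <- nrow(surface$tris)
  E <- as.matrix(fields$E); H <- as.matrix(fields$H)
  if (nrow(E) != nd || nrow(H) != nd) stop("field/surface shape mismatch")
  R <- ncol(E) %/% 3L
  JS <- matrix(0, nd, ncol(E)); KS <- JS
  nrm <- surface$normal
  for (r in seq_len(R)) {
    j <- (3L * r - 2L):(3L * r)
    JS[, j] <- row_cross(nrm, H[, j, drop = FALSE])
    KS[, j] <- -row_cross(nrm, E[, j, drop = FALSE])
  }
  structure(list(JS = JS, KS = KS, surface = surface, n_modes = R),
            class = "huygens_current_set")
}

#' Reciprocity operator
#'
#' Packs the single-point-quadrature reciprocity integral into a dense
#' matrix `B` of shape `n_modes x 6 n_facets` such that for primary fields
#' stacked per facet (`E_p` then `H_p`, each facet contributing its x,y,z
#' components in order), `a = B %*% c(Ep, Hp)` reproduces
#' `a_i = sum_j A_j [E_p(r_j) . J_S_i(r_j) - H_p(r_j) . K_S_i(r_j)]`.
#'
#' @param currents a `huygens_current_set`.
#' @param surface the Huygens [tri_surface()].
#' @return object of class `reciprocity_operator` with the dense matrix
#'   `B`, facet centers and areas.
#' @export
build_reciprocity_operator <- function(currents, surface = currents$surface) {
  area_m2 <- surface$area * MM_TO_M^2
  R <- currents$n_modes
  nd <- nrow(surface$tris)
  BJ <- matrix(0, R, 3L * nd)
  BK <- matrix(0, R, 3L * nd)
  for (r in seq_len(R)) {
    j <- (3L * r - 2L):(3L * r)
    BJ[r, ] <- as.vector(t(currents$JS[, j, drop = FALSE] * area_m2))
    BK[r, ] <- as.vector(t(currents$KS[, j, drop = FALSE] * area_m2))
  }
  structure(list(B = cbind(BJ, -BK), n_modes = R, n_facets = nd,
                 centers = surface$center, areas = surface$area),
            class = "reciprocity_operator")
}
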