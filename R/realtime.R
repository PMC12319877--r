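# Offline session precompute (noise probing -> FEM -> basis -> equivalent
# currents -> grid) and the online per-placement solve: transform,
# interpolate, reciprocity coefficients, mode-expansion reconstruction.

# --- point location -------------------------------------------------------

# uniform-grid spatial hash over tet bounding boxes; cached on the mesh
point_locator <- function(mesh) {
  if (!is.null(mesh$cache$locator)) return(mesh$cache$locator)
  nodes <- mesh$nodes; tets <- mesh$tets
  px <- matrix(nodes[tets, 1], ncol = 4L)
  py <- matrix(nodes[tets, 2], ncol = 4L)
  pz <- matrix(nodes[tets, 3], ncol = 4L)
  lo <- cbind(apply(px, 1L, min), apply(py, 1L, min), apply(pz, 1L, min))
  hi <- cbind(apply(px, 1L, max), apply(py, 1L, max), apply(pz, 1L, max))
  h <- max(stats::quantile(hi - lo, 0.9), 1e-6)
  orig <- apply(lo, 2L, min) - 1e-9
  nc <- pmax(ceiling((apply(hi, 2L, max) - orig) / h), 1L) + 1L
  cell_of <- function(p) pmin(pmax(floor(sweep(p, 2L, orig) / h), 0),
                              matrix(nc - 1L, nrow(p), 3L, byrow = TRUE))
  key_of <- function(cid) 1 + cid[, 1] + nc[1] * (cid[, 2] + nc[2] * cid[, 3])
  # register each tet in all cells its bbox overlaps
  cl <- cell_of(lo); ch <- cell_of(hi)
  span <- (ch[, 1] - cl[, 1] + 1L) * (ch[, 2] - cl[, 2] + 1L) *
          (ch[, 3] - cl[, 3] + 1L)
  tid <- integer(sum(span)); keys <- numeric(sum(span))
  pos <- 1L
  for (k in seq_len(nrow(tets))) {
    xs <- cl[k, 1]:ch[k, 1]; ys <- cl[k, 2]:ch[k, 2]; zs <- cl[k, 3]:ch[k, 3]
    cells <- as.matrix(expand.grid(xs, ys, zs))
    kk <- key_of(cells)
    tid[pos:(pos + length(kk) - 1L)] <- k
    keys[pos:(pos + length(kk) - 1L)] <- kk
    pos <- pos + length(kk)
  }
  buckets <- split(tid, keys)
  # per-tet barycentric machinery: gradients of lambda_2..4 (in 1/mm)
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  c1 <- row_cross(e2, e3); c2 <- row_cross(e3, e1); c3 <- row_cross(e1, e2)
  det <- rowSums(e1 * c1)
  loc <- list(orig = orig, h = h, nc = nc, buckets = buckets,
              key_of = key_of, cell_of = cell_of,
              p1 = p1, g2 = c1 / det, g3 = c2 / det, g4 = c3 / det)
  mesh$cache$locator <- loc
  loc
}

#' Locate points in a tetrahedral mesh
#'
#' Returns the index of the tetrahedron containing each point (barycentric
#' test with tolerance `tol`), using a uniform-grid candidate search.
#'
#' @param mesh a [head_mesh()].
#' @param points n x 3 query points, mm.
#' @param error_outside error (default) or return `NA` for points outside
#'   the mesh.
#' @param tol barycentric containment tolerance.
#' @return integer vector of tet indices (NA for outside points when
#'   `error_outside = FALSE`).
#' @export
locate_points <- function(mesh, points, error_outside = TRUE, tol = 1e-9) {
  loc <- point_locator(mesh)
  pts <- as_matrix3(points, "points")
  keys <- loc$key_of(loc$cell_of(pts))
  out <- rep(NA_integer_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cand <- loc$buckets[[as.character(keys[i])]]
    if (is.null(cand)) next
    dp <- sweep(matrix(pts[i, ], length(cand), 3L, byrow = TRUE),
                2L, 0) - loc$p1[cand, , drop = FALSE]
    l2 <- rowSums(loc$g2[cand, , drop = FALSE] * dp)
    l3 <- rowSums(loc$g3[cand, , drop = FALSE] * dp)
    l4 <- rowSums(loc$g4[cand, , drop = FALSE] * dp)
    l1 <- 1 - l2 - l3 - l4
    hit <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol & l4 >= -tol)
    if (length(hit)) out[i] <- cand[hit[1]]
  }
  if (error_outside && anyNA(out))
    stop(sum(is.na(out)), " point(s) outside the mesh")
  out
}

#' Sample mode fields at surface barycenters
#'
#' The piecewise-constant value of every mode at each facet barycenter of
#' an evaluation surface (the containing ROI tet's value).  Errors if any
#' barycenter falls outside the ROI.
#'
#' @param basis a [build_basis()] result.
#' @param mesh the [head_mesh()] the basis was built on.
#' @param surface evaluation [tri_surface()] (e.g. middle grey matter).
#' @return list with `samples` (3*n_facets x n_modes matrix, stacked
#'   x,y,z per facet) and `tet_map` (ROI-local tet index per facet).
#' @export
sample_modes_at_surface <- function(basis, mesh, surface) {
  tet <- locate_points(mesh, surface$center)
  roi_pos <- match(tet, basis$roi_index)
  if (anyNA(roi_pos))
    stop(sum(is.na(roi_pos)), " evaluation point(s) outside the ROI")
  nd <- nrow(surface$tris)
  rows <- as.vector(t(matrix(3L * (roi_pos - 1L), nd, 3L) +
                      matrix(1:3, nd, 3L, byrow = TRUE)))
  list(samples = basis$modes[rows, , drop = FALSE], tet_map = roi_pos)
}

# --- offline stage (Algorithm 1) -----------------------------------------

#' Precompute a real-time TMS session (offline stage)
#'
#' Runs the full offline pipeline on a head mesh: extract (or accept) the
#' scalp surface, extrude the Huygens surface, draw `n_modes` white-noise
#' magnetic surface current realizations, compute their primary fields and
#' FEM-corrected total brain fields, build the volume-weighted QR+SVD mode
#' basis, solve the impressed-current FEM problem per mode, radiate each
#' mode's total current to the Huygens surface and form the equivalent
#' currents and the reciprocity operator, precompute the coil primary
#' fields on a Cartesian grid, and sample the modes at the evaluation
#' surface barycenters.  Deterministic for a fixed `seed`.
#'
#' This is the model-fitting step of the package: the returned
#' `tms_realtime` object answers arbitrary coil placements via
#' [predict.tms_realtime()] / [realtime_solve()].
#'
#' @param mesh a [head_mesh()].
#' @param coil a [coil_model()].
#' @param eval_surface evaluation [tri_surface()] inside the ROI
#'   (middle grey matter).
#' @param n_modes number of noise realizations = maximum mode count.
#' @param seed RNG seed for the noise currents.
#' @param scalp optional scalp [tri_surface()]; extracted from the mesh
#'   boundary when omitted.
#' @param huygens_distance Huygens surface offset from the scalp, mm.
#' @param grid_spacing primary-field grid spacing, mm.
#' @param grid_bounds optional grid bounds; defaults to the tangential
#'   placement envelope of [default_grid_bounds()].
#' @param standoff maximum coil standoff assumed for the grid envelope, mm.
#' @param dIdt peak coil current derivative, A/s (applied at
#'   reconstruction; all stored quantities are unit-dIdt).
#' @param keep_basis keep the full ROI mode basis in the session (needed
#'   for validation against direct FEM; adds memory).
#' @param tol FEM solver tolerance.
#' @param verbose print stage progress.
#' @return object of class `tms_realtime`.
#' @export
tms_precompute <- function(mesh, coil, eval_surface, n_modes = 400L,
                           seed = 1L, scalp = NULL, huygens_distance = 1,
                           grid_spacing = 4, grid_bounds = NULL,
                           standoff = 5, dIdt = 6.6e7, keep_basis = TRUE,
                           tol = 1e-10, verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  stage <- function(lab) say("[%6.1f s] %s", proc.time()[3] - t0, lab)

  stage("assembling conduction operator")
  op <- assemble_conduction_system(mesh)
  if (is.null(scalp)) scalp <- extract_boundary_surface(mesh)
  huygens <- extrude_surface(scalp, huygens_distance)

  stage(sprintf("sampling %d white-noise realizations", n_modes))
  noise <- sample_white_noise_currents(huygens, n_modes, seed)

  stage("noise primary fields at tet centroids")
  Ewp <- magnetic_current_primary_efield(noise, huygens, mesh$centroid)

  stage("noise FEM solves")
  phi <- solve_neumann(op, build_rhs(op, Ewp * mesh$sigma), tol = tol)
  Ew <- Ewp - gradient_field(op, phi)
  rm(phi, Ewp)

  stage("volume-weighted QR+SVD basis")
  basis <- build_basis(Ew[mesh$roi, , drop = FALSE], mesh, n_keep = n_modes)
  rm(Ew)

  stage("impressed-current FEM solves")
  Mroi <- matrix(0, sum(mesh$roi), 3L * basis$n_modes)
  for (i in seq_len(basis$n_modes))
    Mroi[, (3L * i - 2L):(3L * i)] <- mode_field(basis, i)
  Mfull <- matrix(0, nrow(mesh$tets), 3L * basis$n_modes)
  Mfull[mesh$roi, ] <- Mroi
  phiM <- solve_neumann(op, build_rhs(op, Mfull), tol = tol)
  Jtot <- Mfull - gradient_field(op, phiM) * mesh$sigma
  rm(phiM, Mfull, Mroi)

  stage("radiating mode currents to the Huygens surface")
  sf <- mode_fields_on_surface(mesh, Jtot, huygens)
  rm(Jtot)
  hc <- equivalent_currents(sf, huygens)
  rm(sf)
  B <- build_reciprocity_operator(hc, huygens)
  rm(hc)

  stage("primary-field grid")
  if (is.null(grid_bounds))
    grid_bounds <- default_grid_bounds(huygens, standoff = standoff)
  grid <- build_primary_grid(coil, spacing = grid_spacing,
                             bounds = grid_bounds)

  stage("sampling modes at the evaluation surface")
  ev <- sample_modes_at_surface(basis, mesh, eval_surface)

  stage("done")
  structure(list(
    B = B$B, n_modes = basis$n_modes, sv = basis$sv[seq_len(basis$n_modes)],
    modes_eval = ev$samples, eval_tet_map = ev$tet_map,
    eval_surface = eval_surface, huygens = huygens, scalp = scalp,
    grid = grid, coil = coil, dIdt = dIdt, seed = seed,
    basis = if (keep_basis) basis else NULL,
    meta = list(mesh_hash = op$mesh_hash, coil_hash = light_hash(coil),
                n_tets = nrow(mesh$tets), n_roi = sum(mesh$roi),
                huygens_distance = huygens_distance,
                grid_spacing = grid_spacing, standoff = standoff,
                elapsed_s = unname(proc.time()[3] - t0))),
    class = "tms_realtime")
}

# --- online stage (Algorithm 2) ------------------------------------------

#' Mode coefficients from primary fields on the Huygens surface
#'
#' `a = B [E_p; H_p]`, the quadrature form of the reciprocity integral
#' `a_i = sum_j A_j [E_p . J_S_i - H_p . K_S_i]`.
#'
#' @param session a `tms_realtime` session.
#' @param Ep,Hp n_facets x 3 primary fields at the session's Huygens facet
#'   centers (unit-dIdt convention).
#' @return numeric coefficient vector of length `n_modes`.
#' @export
compute_coefficients <- function(session, Ep, Hp) {
  nd <- nrow(session$huygens$tris)
  if (nrow(Ep) != nd || nrow(Hp) != nd)
    stop("primary fields must be sampled at the ", nd,
         " Huygens facet centers")
  drop(session$B %*% c(as.vector(t(Ep)), as.vector(t(Hp))))
}

#' Reconstruct the brain E-field from mode coefficients
#'
#' `E(r) = dIdt * sum_{i<=n_use} a_i M_i(r)` at the evaluation surface
#' barycenters, using the leading (largest singular value) modes.
#'
#' @param session a `tms_realtime` session.
#' @param a coefficient vector.
#' @param n_use number of leading modes used (default: all).
#' @param dIdt current-derivative scaling; defaults to the session value.
#' @return n_facets x 3 E-field matrix (V/m).
#' @export
reconstruct_field <- function(session, a, n_use = session$n_modes,
                              dIdt = session$dIdt) {
  if (n_use > session$n_modes) stop("n_use exceeds stored modes")
  nd <- nrow(session$eval_surface$tris)
  if (n_use == 0L) return(matrix(0, nd, 3L))
  v <- session$modes_eval[, seq_len(n_use), drop = FALSE] %*%
       a[seq_len(n_use)]
  matrix(v, ncol = 3L, byrow = TRUE) * dIdt
}

#' Real-time E-field for a coil placement
#'
#' Algorithm 2: transform the Huygens facet centers into the coil frame by
#' the inverse placement, interpolate the precomputed primary-field grid,
#' evaluate the reciprocity coefficients and reconstruct the mode
#' expansion at the evaluation surface.
#'
#' @param session a `tms_realtime` session.
#' @param T a [placement()] (coil frame to head frame).
#' @param n_use number of leading modes used.
#' @param dIdt current-derivative scaling, A/s.
#' @return n_facets x 3 E-field matrix (V/m) with attributes
#'   `"coefficients"` (full coefficient vector) and `"timings"` (seconds
#'   per stage, informational).
#' @export
realtime_solve <- function(session, T, n_use = session$n_modes,
                           dIdt = session$dIdt) {
  t1 <- proc.time()[3]
  pts <- transform_points(session$huygens$center, T, inverse = TRUE)
  t2 <- proc.time()[3]
  pf <- interpolate_fields(session$grid, pts)
  # interpolation happens in the coil frame; rotate the field vectors back
  # into the head frame where the equivalent currents live
  R <- T[1:3, 1:3]
  t3 <- proc.time()[3]
  a <- compute_coefficients(session, pf$E %*% t(R), pf$H %*% t(R))
  t4 <- proc.time()[3]
  E <- reconstruct_field(session, a, n_use = n_use, dIdt = dIdt)
  t5 <- proc.time()[3]
  attr(E, "coefficients") <- a
  attr(E, "timings") <- c(transform = t2 - t1, interpolate = t3 - t2,
                          coefficients = t4 - t3, reconstruct = t5 - t4)
  E
}

#' Reference-solver field sampled at the evaluation surface
#'
#' Direct FEM solve for a placement, returned at the session's evaluation
#' barycenters (piecewise-constant sampling through the stored tet map),
#' for validation of the real-time expansion.
#'
#' @inheritParams realtime_solve
#' @param mesh the session's [head_mesh()].
#' @param op optional pre-assembled conduction operator.
#' @return n_facets x 3 reference E-field matrix (V/m), with the ROI field
#'   in attribute `"roi_field"`.
#' @export
reference_solve <- function(session, mesh, T, dIdt = session$dIdt,
                            op = NULL) {
  Eroi <- solve_direct_tms(mesh, session$coil, T, dIdt = dIdt, op = op)
  out <- Eroi[session$eval_tet_map, , drop = FALSE]
  attr(out, "roi_field") <- Eroi
  out
}

#' Save / load a precomputed session
#'
#' Sessions are stored with R's native serialization.
#'
#' @param session a `tms_realtime` object.
#' @param path file path.
#' @export
save_session <- function(session, path) {
  saveRDS(session, path)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  s <- readRDS(path)
  if (!inherits(s, "tms_realtime")) stop("not a tms_realtime session file")
  s
}
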