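# First-order tetrahedral FEM for the quasi-static scalar-potential
# problems: conduction stiffness assembly, weak-form right-hand sides,
# pure-Neumann solves and piecewise-constant gradient fields.
#
# All FEM algebra is in SI units: node coordinates are converted from mm to
# meters during assembly, element volumes to m^3, so potentials are in volts
# and gradients in V/m.

#' Assemble the conduction stiffness operator
#'
#' Builds the P1 stiffness matrix `A[m, n] = sum_k sigma_k V_k
#' grad(lambda_m) . grad(lambda_n)` of the quasi-static problem
#' `div(sigma grad(phi)) = div(F)` with natural (insulating-exterior)
#' boundary conditions: the boundary condition enters through the
#' right-hand side, no rows are modified.  The operator is symmetric
#' positive-semidefinite with the constants as nullspace.
#'
#' @param mesh a [head_mesh()].
#' @return object of class `conduction_operator` holding the sparse
#'   stiffness `A` (V), the per-tet gradient operator `G` (3m x n, units
#'   1/m), element volumes `vol_m3` and conductivities, and a factorization
#'   cache reused across right-hand sides.
#' @export
assemble_conduction_system <- function(mesh) {
  if (any(mesh$volume <= 0))
    stop("zero-volume tetrahedron at index ", which(mesh$volume <= 0)[1])
  nodes_m <- mesh$nodes * MM_TO_M
  tets <- mesh$tets
  m <- nrow(tets); n <- nrow(nodes_m)

  p1 <- nodes_m[tets[, 1], , drop = FALSE]
  e1 <- nodes_m[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes_m[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes_m[tets[, 4], , drop = FALSE] - p1
  # inverse of J = [e1; e2; e3] row-wise via cofactors; rows of inv(J)^T
  # are the gradients of lambda_2..4
  c1 <- row_cross(e2, e3)
  c2 <- row_cross(e3, e1)
  c3 <- row_cross(e1, e2)
  det <- rowSums(e1 * c1)                     # 6 * signed volume (m^3)
  g2 <- c1 / det
  g3 <- c2 / det
  g4 <- c3 / det
  g1 <- -(g2 + g3 + g4)

  rows <- rep(3L * (seq_len(m) - 1L), each = 12L) + rep(1:3, times = 4L)
  cols <- rep(t(tets), each = 3L)
  vals <- as.vector(t(cbind(g1, g2, g3, g4)))
  # vals ordering: for each tet, (g1x g1y g1z g2x ... g4z)
  G <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(3L * m, n))

  vol_m3 <- mesh$volume * MM_TO_M^3
  w <- rep(mesh$sigma * vol_m3, each = 3L)
  A <- Matrix::forceSymmetric(Matrix::crossprod(G, w * G))

  structure(list(A = A, G = G, vol_m3 = vol_m3, sigma = mesh$sigma,
                 n_nodes = n, n_tets = m,
                 mesh_hash = light_hash(list(mesh$tets, mesh$region)),
                 cache = new.env(parent = emptyenv())),
            class = "conduction_operator")
}

#' Weak-form right-hand side for a cell source field
#'
#' Computes `b[m] = sum_k V_k F_k . grad(lambda_m)`, the weak form of
#' `div F` with the natural boundary condition `n . sigma grad(phi) =
#' n . F`.  `F` is `sigma * E_primary` for induced-field problems and the
#' impressed mode current density for the equivalent-current problems.  The
#' result sums to zero (compatibility of the pure-Neumann problem).
#'
#' @param op a `conduction_operator` from [assemble_conduction_system()].
#' @param cell_source m x 3 matrix (or m x 3R for R stacked fields) of the
#'   per-tet source field F.
#' @return nodal vector (or n x R matrix) `b`.
#' @export
build_rhs <- function(op, cell_source) {
  cs <- as.matrix(cell_source)
  if (nrow(cs) != op$n_tets)
    stop("source field defined on a different mesh (", nrow(cs),
         " tets, expected ", op$n_tets, ")")
  if (ncol(cs) %% 3L != 0L) stop("cell source must have 3R columns")
  R <- ncol(cs) %/% 3L
  # stack per-tet vectors into length-3m columns, volume-weighted
  stacked <- matrix(0, 3L * op$n_tets, R)
  for (r in seq_len(R)) {
    blk <- cs[, (3L * r - 2L):(3L * r), drop = FALSE] * op$vol_m3
    stacked[, r] <- as.vector(t(blk))
  }
  b <- as.matrix(Matrix::crossprod(op$G, stacked))
  if (R == 1L) drop(b) else b
}

#' Solve the pure-Neumann conduction problem
#'
#' Solves `A phi = b` for the gauge-fixed nodal potential.  The right-hand
#' side is projected onto the range of `A` (its mean is removed), the
#' system is solved with a sparse Cholesky factorization of the one-node
#' grounded operator (cached and shared across all right-hand sides), and
#' the solution is gauge-fixed to zero mean.  A Jacobi-preconditioned
#' conjugate-gradient path (`method = "cg"`) is available as an
#' alternative.  The relative residual is verified against `tol`.
#'
#' @param op a `conduction_operator`.
#' @param b nodal vector, or matrix of stacked right-hand sides.
#' @param tol relative residual tolerance (default 1e-10).
#' @param method `"cholesky"` (default) or `"cg"`.
#' @param maxit CG iteration cap.
#' @return gauge-fixed nodal potential(s), same shape as `b`, with the
#'   attained relative residual(s) in attribute `"residual"`.
#' @export
solve_neumann <- function(op, b, tol = 1e-10, method = c("cholesky", "cg"),
                          maxit = 10000L) {
  method <- match.arg(method)
  bm <- as.matrix(b)
  if (nrow(bm) != op$n_nodes) stop("rhs length does not match node count")
  nb <- sqrt(colSums(bm^2))
  bproj <- sweep(bm, 2L, colMeans(bm))

  if (method == "cholesky") {
    n <- op$n_nodes
    if (is.null(op$cache$chol)) {
      Ared <- op$A[-n, -n]
      op$cache$chol <- Matrix::Cholesky(Ared, LDL = FALSE, perm = TRUE)
    }
    xr <- as.matrix(Matrix::solve(op$cache$chol, bproj[-n, , drop = FALSE]))
    x <- rbind(xr, 0)
  } else {
    x <- cg_solve(op$A, bproj, tol = tol, maxit = maxit)
  }
  x <- sweep(x, 2L, colMeans(x))

  res <- as.matrix(op$A %*% x) - bproj
  rr <- sqrt(colSums(res^2)) / pmax(nb, .Machine$double.xmin)
  rr[nb == 0] <- 0
  if (any(rr > tol * 50)) {
    # re-check against the projected rhs scale; a genuinely incompatible b
    # (large constant component) is the usual cause
    np <- sqrt(colSums(bproj^2))
    rrp <- sqrt(colSums(res^2)) / pmax(np, .Machine$double.xmin)
    if (any(rrp > tol * 50))
      stop(sprintf("Neumann solve did not reach tolerance: residual %.3g",
                   max(rrp)))
  }
  out <- if (is.matrix(b)) x else drop(x)
  attr(out, "residual") <- rr
  out
}

# Jacobi-preconditioned CG on the singular consistent system, with
# projection of the constant mode at every step.
cg_solve <- function(A, B, tol = 1e-10, maxit = 10000L) {
  d <- Matrix::diag(A)
  d[d <= 0] <- 1
  X <- matrix(0, nrow(B), ncol(B))
  for (j in seq_len(ncol(B))) {
    b <- B[, j]
    nb <- sqrt(sum(b^2))
    if (nb == 0) next
    x <- numeric(length(b))
    r <- b
    z <- r / d
    p <- z
    rz <- sum(r * z)
    for (it in seq_len(maxit)) {
      Ap <- as.numeric(A %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      r <- r - mean(r)
      if (sqrt(sum(r^2)) <= tol * nb) break
      z <- r / d
      rz_new <- sum(r * z)
      beta <- rz_new / rz
      rz <- rz_new
      p <- z + beta * p
    }
    if (sqrt(sum(r^2)) > tol * nb)
      stop(sprintf("CG did not converge in %d iterations (residual %.3g)",
                   maxit, sqrt(sum(r^2)) / nb))
    X[, j] <- x
  }
  X
}

#' Per-tet gradient of a nodal potential
#'
#' Evaluates the P1 gradient, constant within each tetrahedron, in V/m.
#'
#' @param op a `conduction_operator`.
#' @param phi nodal potential vector (or matrix of R potentials).
#' @return m x 3 matrix (or m x 3R, blocks of three columns per input
#'   column) of gradients.
#' @export
gradient_field <- function(op, phi) {
  pm <- as.matrix(phi)
  g <- as.matrix(op$G %*% pm)
  R <- ncol(pm)
  out <- matrix(0, op$n_tets, 3L * R)
  for (r in seq_len(R))
    out[, (3L * r - 2L):(3L * r)] <- matrix(g[, r], ncol = 3L, byrow = TRUE)
  out
}

#' Direct FEM reference solve for a TMS coil placement
#'
#' The reference path of the validation protocol: the coil is transformed
#' directly into head coordinates (no grid interpolation), its primary
#' E-field is evaluated at every tetrahedron centroid, the scalar-potential
#' problem is solved, and the total field `E = dIdt * (E_p - grad phi)` is
#' returned on the ROI tetrahedra.
#'
#' @param mesh a [head_mesh()].
#' @param coil a [coil_model()].
#' @param placement a [placement()] (coil frame to head frame).
#' @param dIdt peak coil current derivative in A/s (default 6.6e7).
#' @param op optional pre-assembled `conduction_operator` for `mesh`.
#' @param tol solver tolerance passed to [solve_neumann()].
#' @return ROI-tet 3-column E-field matrix (V/m) with attribute
#'   `"roi_index"` (tet indices).
#' @export
solve_direct_tms <- function(mesh, coil, placement, dIdt = 6.6e7, op = NULL,
                             tol = 1e-10) {
  if (is.null(op)) op <- assemble_conduction_system(mesh)
  tc <- transform_coil(coil, placement)
  inside <- tryCatch(
    locate_points(mesh, tc$positions, error_outside = FALSE),
    error = function(e) NULL)
  if (!is.null(inside) && any(!is.na(inside)))
    warning(sum(!is.na(inside)),
            " coil element(s) inside the head volume: physically invalid placement")
  pf <- coil_primary_fields(tc, mesh$centroid, dIdt = 1)
  b <- build_rhs(op, pf$E * mesh$sigma)
  phi <- solve_neumann(op, b, tol = tol)
  E <- (pf$E - gradient_field(op, phi)) * dIdt
  out <- E[mesh$roi, , drop = FALSE]
  attr(out, "roi_index") <- which(mesh$roi)
  out
}
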