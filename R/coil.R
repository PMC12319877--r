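# Coil models: clouds of weighted current elements (electric, dl*I per
# element) or magnetic dipoles, in a coil-local frame with the winding flat
# on and centered about the x-y plane and the head in the z < 0 half-space.

#' Coil model constructor
#'
#' @param positions n x 3 element positions, mm, coil frame.
#' @param weights n x 3 element weight vectors: current elements `dl * I`
#'   (A.m per unit current) for the electric representation, magnetic
#'   dipole moments for the magnetic representation.
#' @param representation `"electric"` or `"magnetic"`.
#' @param name coil name string.
#' @return object of class `coil_model`.
#' @export
coil_model <- function(positions, weights,
                       representation = c("electric", "magnetic"),
                       name = "coil") {
  representation <- match.arg(representation)
  positions <- as_matrix3(positions, "positions")
  weights <- as_matrix3(weights, "weights")
  if (nrow(positions) != nrow(weights))
    stop("positions and weights must have the same number of rows")
  if (nrow(positions) < 1L) stop("coil needs at least one element")
  if (!all(is.finite(weights))) stop("non-finite coil weights")
  structure(list(positions = positions, weights = weights,
                 representation = representation, name = name),
            class = "coil_model")
}

#' @export
print.coil_model <- function(x, ...) {
  cat(sprintf("coil_model '%s': %d %s elements\n", x$name,
              nrow(x$positions), x$representation))
  invisible(x)
}

#' Figure-8 TMS coil from printed geometry
#'
#' Builds a figure-8 coil as two side-by-side 9-turn windings of concentric
#' circular loops with radii linearly spaced between the inner and outer
#' radius (53 mm and 88 mm diameters by default), lying in the x-y plane
#' and touching at the origin.  Every turn is a closed polygon of straight
#' current elements, so each loop's element weights sum to the zero vector
#' exactly.  The right winding is the mirror image of the left one, which
#' makes the pair counter-wound so the fields of the two windings add under
#' the coil center; the build is exactly symmetric under a half-turn about
#' the coil axis (up to current reversal).
#'
#' @param inner_diam,outer_diam inner/outer loop diameters, mm.
#' @param turns number of turns per winding.
#' @param segments_per_turn polygon segments per turn (>= 16).
#' @return a `coil_model` (electric representation, unit drive current)
#'   with `2 * turns * segments_per_turn` elements and a `loop` field
#'   giving the closed-loop index of every element.
#' @export
build_figure8_coil <- function(inner_diam = 53, outer_diam = 88, turns = 9,
                               segments_per_turn = 32) {
  if (segments_per_turn < 16) stop("segments_per_turn must be >= 16")
  r_in <- inner_diam / 2; r_out <- outer_diam / 2
  if (r_in >= r_out) stop("inner diameter must be smaller than outer")
  radii <- seq(r_in, r_out, length.out = turns)
  th <- 2 * pi * (seq_len(segments_per_turn) - 1L) / segments_per_turn
  nxt <- c(seq_len(segments_per_turn)[-1L], 1L)
  cx <- -r_out  # left winding center; windings touch at the origin
  pos_l <- NULL; w_l <- NULL
  for (r in radii) {
    vx <- cx + r * cos(th); vy <- r * sin(th)
    pos_l <- rbind(pos_l, cbind((vx + vx[nxt]) / 2, (vy + vy[nxt]) / 2, 0))
    w_l <- rbind(w_l, cbind(vx[nxt] - vx, vy[nxt] - vy, 0))
  }
  # mirror (x -> -x): reverses orientation, i.e. counter-wound right winding
  pos_r <- pos_l; pos_r[, 1] <- -pos_r[, 1]
  w_r <- w_l; w_r[, 1] <- -w_r[, 1]
  cl <- coil_model(rbind(pos_l, pos_r), rbind(w_l, w_r),
                   representation = "electric",
                   name = sprintf("figure8-%g/%gmm", inner_diam, outer_diam))
  cl$loop <- rep(seq_len(2L * turns), each = segments_per_turn)
  cl
}

#' Read / write ASCII coil element files
#'
#' One element per line, `x y z wx wy wz`, preceded by a header line
#' `representation=<electric|magnetic> units=mm`.  Comment lines starting
#' with `#` are skipped.
#'
#' @param path file path.
#' @return `load_coil_file`: a `coil_model`.
#' @export
load_coil_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("empty coil file: ", path)
  hdr <- lines[idx[1]]
  m <- regmatches(hdr, regexec("representation=(electric|magnetic)", hdr))[[1]]
  if (length(m) < 2L)
    stop("coil file header must declare 'representation=electric|magnetic' ",
         "and units: ", path)
  rep_tag <- m[2]
  body_idx <- idx[-1L]
  rows <- lapply(seq_along(body_idx), function(k) {
    ln <- body_idx[k]
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]),
                                              "[[:space:]]+")[[1]]))
    if (length(v) != 6L || anyNA(v))
      stop(sprintf("malformed coil element at line %d of %s", ln, path))
    v
  })
  tab <- do.call(rbind, rows)
  coil_model(tab[, 1:3, drop = FALSE], tab[, 4:6, drop = FALSE],
             representation = rep_tag,
             name = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname load_coil_file
#' @param coil a `coil_model`.
#' @export
write_coil_file <- function(coil, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("representation=%s units=mm", coil$representation), con)
  writeLines(sprintf("%.17g %.17g %.17g %.17g %.17g %.17g",
                     coil$positions[, 1], coil$positions[, 2],
                     coil$positions[, 3], coil$weights[, 1],
                     coil$weights[, 2], coil$weights[, 3]), con)
  invisible(path)
}

#' Primary (free-space) coil fields
#'
#' Evaluates the coil primary electric and magnetic fields at arbitrary
#' points by direct summation over coil elements.  For the electric
#' representation with unit-normalized current waveform,
#' `E_p(r) = -(mu0 dIdt / 4 pi) sum_j w_j / |r - r_j|` (inductive term of
#' the vector potential) and `H_p(r) = (1 / 4 pi) sum_j w_j x (r - r_j) /
#' |r - r_j|^3` (Biot-Savart, unit peak current).  The magnetic
#' representation uses the dual dipole formulas.  Lengths are converted
#' from mm to meters internally; fields are in V/m and A/m.
#'
#' @param coil a `coil_model`.
#' @param points n x 3 evaluation points, mm (same frame as the coil).
#' @param dIdt scaling of the electric field, A/s; `H` is not scaled.
#' @return list with matrices `E` (n x 3, V/m) and `H` (n x 3, A/m).
#' @export
coil_primary_fields <- function(coil, points, dIdt = 1) {
  pts <- as_matrix3(points, "points") * MM_TO_M
  src <- coil$positions * MM_TO_M
  if (coil$representation == "electric") {
    w_si <- coil$weights * MM_TO_M     # dl in mm -> A.m per unit current
    s <- pair_field_sums(pts, src, w_si, want_inv = TRUE, want_cross = TRUE,
                         min_dist = 1e-9)
    E <- -(MU0 * dIdt / (4 * pi)) * s$inv
    H <- s$cross / (4 * pi)
  } else {
    m_si <- coil$weights               # dipole moments, A.m^2
    s <- pair_field_sums(pts, src, m_si, want_inv = FALSE, want_cross = TRUE,
                         min_dist = 1e-9)
    E <- -(MU0 * dIdt / (4 * pi)) * s$cross
    H <- dipole_h_field(pts, src, m_si) / (4 * pi)
  }
  list(E = E, H = H)
}

# sum_j [3 (m_j . u) u - m_j] / d^3 with u the unit separation vector
dipole_h_field <- function(pts, src, m, chunk_obs = 4096L) {
  n <- nrow(pts)
  out <- matrix(0, n, 3L)
  for (o0 in seq(1L, n, by = chunk_obs)) {
    o1 <- min(o0 + chunk_obs - 1L, n)
    oi <- o0:o1
    dx <- outer(pts[oi, 1], src[, 1], "-")
    dy <- outer(pts[oi, 2], src[, 2], "-")
    dz <- outer(pts[oi, 3], src[, 3], "-")
    d2 <- dx * dx + dy * dy + dz * dz
    d <- sqrt(d2)
    K3 <- 1 / (d2 * d)
    K5 <- K3 / d2
    mdotr <- sweep(dx, 2L, m[, 1], "*") + sweep(dy, 2L, m[, 2], "*") +
             sweep(dz, 2L, m[, 3], "*")
    out[oi, 1] <- rowSums(3 * mdotr * K5 * dx) - (K3 %*% m[, 1])
    out[oi, 2] <- rowSums(3 * mdotr * K5 * dy) - (K3 %*% m[, 2])
    out[oi, 3] <- rowSums(3 * mdotr * K5 * dz) - (K3 %*% m[, 3])
  }
  out
}

#' Rigid coil placement transforms
#'
#' A placement is a 4x4 affine `T = [R | t; 0 1]` mapping coil-frame
#' coordinates (mm) to head-frame coordinates: `R` a proper rotation,
#' `t` a translation in mm.
#'
#' @param R 3x3 proper rotation matrix.
#' @param t length-3 translation, mm.
#' @return a `placement` (4x4 matrix with class attribute).
#' @export
placement <- function(R, t = c(0, 0, 0)) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L))) stop("R must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-10 || det(R) < 0)
    stop("R must be a proper rotation (R'R = I, det = +1)")
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  structure(T, class = c("placement", "matrix"))
}

#' @rdname placement
#' @param T 4x4 affine matrix (or 16 numbers, row-major).
#' @export
placement_from_matrix <- function(T) {
  if (is.null(dim(T))) T <- matrix(T, 4L, 4L, byrow = TRUE)
  if (!all(dim(T) == c(4L, 4L))) stop("T must be 4x4")
  if (max(abs(T[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("last row of a placement must be (0 0 0 1)")
  placement(T[1:3, 1:3], T[1:3, 4])
}

#' @rdname placement
#' @param point,normal scalp landmark and outward unit normal (mm).
#' @param standoff coil center height above the landmark, mm (default 5).
#' @param angle in-plane coil rotation, radians.
#' @export
tangential_placement <- function(point, normal, standoff = 5, angle = 0) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])  # n x u
  ca <- cos(angle); sa <- sin(angle)
  R <- cbind(ca * u + sa * v, -sa * u + ca * v, n)
  placement(R, point + standoff * n)
}

# apply placement to coil geometry (positions and weight vectors)
transform_coil <- function(coil, placement) {
  R <- placement[1:3, 1:3]
  t <- placement[1:3, 4]
  out <- coil
  out$positions <- sweep(coil$positions %*% t(R), 2L, -t)
  out$weights <- coil$weights %*% t(R)
  out
}

#' Random tangential coil placements over the upper scalp
#'
#' Samples facets of the scalp surface above an equator plane
#' (area-weighted), orients the coil tangent to the facet with a uniform
#' random in-plane rotation, and centers it `standoff` mm above the facet
#' center along the outward normal.
#'
#' @param surface scalp [tri_surface()].
#' @param n number of placements.
#' @param seed RNG seed.
#' @param standoff coil height above the scalp, mm.
#' @param equator_z facets with center z above this are admissible;
#'   defaults to the mean node z (the equator of a centered sphere).
#' @return list of [placement()] objects.
#' @export
sample_scalp_placements <- function(surface, n, seed = 1L, standoff = 5,
                                    equator_z = NULL) {
  if (is.null(equator_z)) equator_z <- mean(surface$nodes[, 3])
  ok <- which(surface$center[, 3] > equator_z)
  if (!length(ok)) stop("no scalp facets above the equator plane")
  with_substream(seed, {
    fi <- sample(ok, n, replace = TRUE, prob = surface$area[ok])
    ang <- stats::runif(n, 0, 2 * pi)
    lapply(seq_len(n), function(k)
      tangential_placement(surface$center[fi[k], ], surface$normal[fi[k], ],
                           standoff = standoff, angle = ang[k]))
  })
}
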