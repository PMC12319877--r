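# Synthetic layered-sphere head phantom.
#
# Concentric spherical shells are meshed conformally: every radial level
# carries the same subdivided-icosahedron triangulation; consecutive levels
# are joined by prisms split into three tetrahedra with globally consistent
# diagonals (Dompierre-style smallest-index rule), and the innermost level
# is joined to the center by a tetrahedral fan.

# unit icosphere: vertices + outward-wound faces after `subdiv` midpoint
# subdivisions (20 * 4^subdiv faces)
icosphere <- function(subdiv) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / row_norms(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    e1 <- edge_key(f[, 1], f[, 2])
    e2 <- edge_key(f[, 2], f[, 3])
    e3 <- edge_key(f[, 3], f[, 1])
    keys <- unique(c(e1, e2, e3))
    pair <- matrix(as.integer(unlist(strsplit(keys, " "))), ncol = 2,
                   byrow = TRUE)
    mid <- (v[pair[, 1], ] + v[pair[, 2], ]) / 2
    mid <- mid / row_norms(mid)
    midx <- nrow(v) + seq_along(keys)
    v <- rbind(v, mid)
    m1 <- midx[match(e1, keys)]
    m2 <- midx[match(e2, keys)]
    m3 <- midx[match(e3, keys)]
    f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
  }
  # enforce outward winding
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  nrm <- row_cross(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])
  flip <- rowSums(nrm * ctr) < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  list(vertices = v, faces = f)
}

#' Layered concentric-sphere head phantom
#'
#' Generates a conformal tetrahedral mesh of concentric spherical shells
#' (innermost ball plus shell layers), a scalp boundary surface, and a
#' "middle grey matter" evaluation sphere at the mid-radius of the second
#' shell.  Shell `i` (inside out) receives tissue tag `i` and
#' `conductivities[i]`; the ROI is tags 1:2 (white + grey matter analogue).
#'
#' The lateral resolution is a subdivided icosahedron with subdivision level
#' `floor(log2(max(radii) / (2 * target_edge)))`; the innermost ball is
#' additionally split radially in steps of about `radial_step`
#' (default `6 * target_edge`).  With the default radii 70/75/78/82/85 mm
#' and `target_edge = 4` this yields 24,320 tetrahedra.
#'
#' @param radii strictly increasing shell interface radii in mm.
#' @param target_edge nominal resolution parameter in mm.
#' @param conductivities one value in S/m per shell (inside out); defaults
#'   to the five-tissue table of [tissue_conductivities()].
#' @param radial_step maximum radial layer thickness inside the innermost
#'   ball, mm.
#' @return list with elements `mesh` ([head_mesh()]), `scalp`
#'   ([tri_surface()] at `max(radii)`), `mid_gm` (evaluation sphere) and
#'   `subdiv` (icosphere level used).
#' @export
make_layered_sphere_phantom <- function(radii = c(70, 75, 78, 82, 85),
                                        target_edge = 4,
                                        conductivities = unname(tissue_conductivities()),
                                        radial_step = 6 * target_edge) {
  radii <- as.numeric(radii)
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stop("'radii' must be strictly increasing and positive")
  if (length(conductivities) != length(radii))
    stop("need one conductivity per shell")
  rmax <- max(radii)
  subdiv <- floor(log2(rmax / (2 * target_edge)))
  if (subdiv < 1)
    stop(sprintf(paste0("target_edge %.3g mm too coarse for these radii; ",
                        "minimum feasible edge is %.3g mm"),
                 target_edge, rmax / 4))
  ico <- icosphere(subdiv)
  nv <- nrow(ico$vertices)

  # radial ladder: sub-layers inside the innermost ball, then one or more
  # layers per shell (thin shells get a single layer)
  levels <- numeric(0)
  labels <- integer(0)    # tissue tag of the layer below each level
  r_lo <- 0
  for (i in seq_along(radii)) {
    nsub <- max(1L, ceiling((radii[i] - r_lo) / radial_step))
    rs <- r_lo + (radii[i] - r_lo) * seq_len(nsub) / nsub
    levels <- c(levels, rs)
    labels <- c(labels, rep(i, nsub))
    r_lo <- radii[i]
  }
  ns <- length(levels)

  nodes <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(levels, function(r) ico$vertices * r)))
  off <- function(s) 1L + (s - 1L) * nv   # node offset of level s

  f <- ico$faces
  # rotate each face so the smallest vertex index comes first (winding kept)
  rot <- cbind(f, f[, 1:2])
  pick <- max.col(-f, ties.method = "first")
  f <- cbind(rot[cbind(seq_len(nrow(f)), pick)],
             rot[cbind(seq_len(nrow(f)), pick + 1L)],
             rot[cbind(seq_len(nrow(f)), pick + 2L)])

  tet_list <- vector("list", ns)
  lab_list <- vector("list", ns)

  # central fan: center node to level 1
  tet_list[[1]] <- cbind(1L, f[, 1] + off(1L), f[, 2] + off(1L),
                         f[, 3] + off(1L))
  lab_list[[1]] <- rep(labels[1], nrow(f))

  if (ns > 1L) {
    caseA <- f[, 2] < f[, 3]
    for (s in 1:(ns - 1L)) {
      p <- f + off(s); q <- f + off(s + 1L)
      tA <- rbind(cbind(p[caseA, 1], p[caseA, 2], p[caseA, 3], q[caseA, 3]),
                  cbind(p[caseA, 1], p[caseA, 2], q[caseA, 3], q[caseA, 2]),
                  cbind(p[caseA, 1], q[caseA, 2], q[caseA, 3], q[caseA, 1]))
      tB <- rbind(cbind(p[!caseA, 1], p[!caseA, 2], p[!caseA, 3], q[!caseA, 2]),
                  cbind(p[!caseA, 1], q[!caseA, 2], p[!caseA, 3], q[!caseA, 3]),
                  cbind(p[!caseA, 1], q[!caseA, 2], q[!caseA, 3], q[!caseA, 1]))
      tet_list[[s + 1L]] <- rbind(tA, tB)
      lab_list[[s + 1L]] <- rep(labels[s + 1L], nrow(tA) + nrow(tB))
    }
  }
  tets <- do.call(rbind, tet_list)
  region <- unlist(lab_list)

  cond_table <- stats::setNames(conductivities,
                                as.character(seq_along(radii)))
  roi_labels <- if (length(radii) >= 2L) c(1L, 2L) else 1L
  mesh <- head_mesh(nodes, tets, region, conductivity_table = cond_table,
                    roi_labels = roi_labels)

  scalp <- tri_surface(ico$vertices * rmax, ico$faces)
  mid_r <- if (length(radii) >= 2L) (radii[1] + radii[2]) / 2 else radii[1] / 2
  mid_gm <- tri_surface(ico$vertices * mid_r, ico$faces)

  list(mesh = mesh, scalp = scalp, mid_gm = mid_gm, subdiv = subdiv)
}
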