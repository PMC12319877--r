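#' Labeled tetrahedral head mesh
#'
#' Constructs the volumetric head model used throughout the package: a
#' tetrahedral mesh with an integer tissue label, a piece-wise constant
#' conductivity and a region-of-interest (ROI) flag per element.  Node
#' coordinates are in mm (SimNIBS convention); conductivities in S/m.
#' Tetrahedra with negative signed volume are reordered so that all volumes
#' are positive.
#'
#' @param nodes numeric n x 3 matrix of node positions (mm).
#' @param tets integer m x 4 matrix of 1-based node indices.
#' @param region_label integer vector (length m) of tissue tags.
#' @param conductivity_table named numeric vector mapping tissue tag
#'   (as name) to conductivity in S/m.  Every tag present in
#'   `region_label` must be covered.
#' @param roi_labels integer vector of tags forming the ROI ("brain");
#'   defaults to tags 1 and 2 (white and grey matter).
#' @return An object of class `head_mesh` with fields `nodes`, `tets`,
#'   `region`, `sigma` (S/m per tet), `roi` (logical per tet), `volume`
#'   (mm^3), `centroid` (mm) and `cond_table`.
#' @seealso [load_head_mesh()], [make_layered_sphere_phantom()]
#' @export
head_mesh <- function(nodes, tets, region_label,
                      conductivity_table = tissue_conductivities(),
                      roi_labels = c(1L, 2L)) {
  nodes <- as_matrix3(nodes, "nodes")
  tets <- as.matrix(tets)
  if (ncol(tets) != 4L) stop("'tets' must be an m x 4 index matrix")
  storage.mode(tets) <- "integer"
  region_label <- as.integer(region_label)
  if (length(region_label) != nrow(tets))
    stop("one region label per tetrahedron required")
  if (any(tets < 1L) || any(tets > nrow(nodes)))
    stop("tetrahedron node index out of range")

  tags <- sort(unique(region_label))
  have <- suppressWarnings(as.integer(names(conductivity_table)))
  if (anyNA(have)) stop("conductivity table names must be integer tissue tags")
  missing_tags <- setdiff(tags, have)
  if (length(missing_tags))
    stop("no conductivity for tissue tag(s): ",
         paste(missing_tags, collapse = ", "))
  sigma <- unname(conductivity_table[as.character(region_label)])

  sv <- tet_signed_volumes(nodes, tets)
  flip <- sv < 0
  if (any(flip)) tets[flip, c(3L, 4L)] <- tets[flip, c(4L, 3L)]
  vol <- abs(sv)
  if (any(vol <= 0))
    stop("zero-volume tetrahedron at index ", which(vol <= 0)[1])

  centroid <- (nodes[tets[, 1], , drop = FALSE] +
               nodes[tets[, 2], , drop = FALSE] +
               nodes[tets[, 3], , drop = FALSE] +
               nodes[tets[, 4], , drop = FALSE]) / 4

  roi <- region_label %in% as.integer(roi_labels)
  if (any(roi & sigma <= 0))
    stop("ROI tetrahedra must have positive conductivity")

  structure(list(nodes = nodes, tets = tets, region = region_label,
                 sigma = as.numeric(sigma), roi = roi, volume = vol,
                 centroid = centroid, cond_table = conductivity_table,
                 units = "mm", cache = new.env(parent = emptyenv())),
            class = "head_mesh")
}

# signed volume of each tet (mm^3): det([p2-p1; p3-p1; p4-p1]) / 6
tet_signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Default tissue conductivity table
#'
#' Five-compartment head conductivities (S/m), tags 1..5 = white matter,
#' grey matter, CSF, skull, scalp: 0.126, 0.275, 1.654, 0.01, 0.465.
#'
#' @return named numeric vector (names are tissue tags).
#' @export
tissue_conductivities <- function() {
  c(`1` = 0.126, `2` = 0.275, `3` = 1.654, `4` = 0.01, `5` = 0.465)
}

#' @export
print.head_mesh <- function(x, ...) {
  cat(sprintf("head_mesh: %d nodes, %d tets, %d region(s), %d ROI tets\n",
              nrow(x$nodes), nrow(x$tets), length(unique(x$region)),
              sum(x$roi)))
  cat(sprintf("  total volume %.1f mm^3; conductivities [%s] S/m\n",
              sum(x$volume),
              paste(format(unique(x$sigma), digits = 3), collapse = ", ")))
  invisible(x)
}

#' Read a Gmsh v2 ASCII mesh with tetrahedral physical tags
#'
#' Parses `$Nodes` and the tetrahedral entries (element type 4) of
#' `$Elements`; the physical tag (first element tag) becomes the tissue
#' label.  Elements of other types are ignored with a message stating the
#' count.
#'
#' @inheritParams head_mesh
#' @param path path to a Gmsh `.msh` v2 ASCII file.
#' @return A [head_mesh()].
#' @export
load_head_mesh <- function(path, conductivity_table = tissue_conductivities(),
                           roi_labels = c(1L, 2L)) {
  lines <- readLines(path, warn = FALSE)
  sec <- function(tag) {
    i0 <- match(paste0("$", tag), lines)
    i1 <- match(paste0("$End", tag), lines)
    if (is.na(i0) || is.na(i1)) stop("missing $", tag, " section in ", path)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  nl <- sec("Nodes")
  n_nodes <- as.integer(nl[1])
  ntab <- matrix(scan(text = nl[-1], quiet = TRUE), ncol = 4, byrow = TRUE)
  if (nrow(ntab) != n_nodes) stop("node count mismatch in ", path)
  ord <- order(ntab[, 1])
  if (any(ntab[ord, 1] != seq_len(n_nodes)))
    stop("non-contiguous node numbering not supported")
  nodes <- ntab[ord, 2:4, drop = FALSE]

  el <- sec("Elements")
  n_el <- as.integer(el[1])
  body <- el[-1]
  if (length(body) != n_el) stop("element count mismatch in ", path)
  toks <- strsplit(trimws(body), "[[:space:]]+")
  type <- vapply(toks, function(t) as.integer(t[2]), integer(1))
  is_tet <- type == 4L
  if (sum(!is_tet) > 0)
    message(sum(!is_tet), " non-tetrahedral element(s) ignored")
  if (!any(is_tet)) stop("no tetrahedral elements in ", path)
  tt <- toks[is_tet]
  parse_tet <- function(t) {
    ntags <- as.integer(t[3])
    c(as.integer(t[4]), as.integer(t[(4 + ntags):(7 + ntags)]))
  }
  rec <- t(vapply(tt, parse_tet, integer(5)))
  head_mesh(nodes, rec[, 2:5, drop = FALSE], rec[, 1],
            conductivity_table = conductivity_table, roi_labels = roi_labels)
}

#' Write a head mesh as Gmsh v2 ASCII
#'
#' @param mesh a [head_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_head_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n)), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(n),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(m)), con)
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(m),
                     mesh$region, mesh$region,
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Triangle surface with facet geometry
#'
#' Builds a triangle surface (mm) and computes per-facet area (mm^2),
#' barycenter and unit normal.  Normal orientation follows the winding
#' (right-hand rule).  Closedness and consistent orientation are detected
#' from the edge structure: a surface is flagged closed when every
#' undirected edge is shared by exactly two facets, and oriented when the
#' two traversals run in opposite directions.
#'
#' @param nodes n x 3 node positions (mm).
#' @param tris m x 3 matrix of 1-based node indices.
#' @return object of class `tri_surface` with fields `nodes`, `tris`,
#'   `area`, `center`, `normal`, `closed`, `oriented`.
#' @export
tri_surface <- function(nodes, tris) {
  nodes <- as_matrix3(nodes, "nodes")
  tris <- as.matrix(tris)
  if (ncol(tris) != 3L) stop("'tris' must be an m x 3 index matrix")
  storage.mode(tris) <- "integer"
  if (any(tris < 1L) || any(tris > nrow(nodes)))
    stop("triangle node index out of range")
  s <- structure(list(nodes = nodes, tris = tris), class = "tri_surface")
  surface_geometry(s)
}

#' Recompute facet areas, barycenters and normals
#'
#' Call after editing node positions; connectivity is unchanged.  Degenerate
#' (zero-area) facets raise an error naming the first offending index.
#'
#' @param surface a [tri_surface()].
#' @return the surface with updated `area`, `center`, `normal`, `closed`
#'   and `oriented` fields.
#' @export
surface_geometry <- function(surface) {
  nodes <- surface$nodes; tris <- surface$tris
  p1 <- nodes[tris[, 1], , drop = FALSE]
  p2 <- nodes[tris[, 2], , drop = FALSE]
  p3 <- nodes[tris[, 3], , drop = FALSE]
  cr <- row_cross(p2 - p1, p3 - p1)
  a2 <- row_norms(cr)
  if (any(a2 <= 0))
    stop("degenerate (zero-area) triangle at index ", which(a2 <= 0)[1])
  surface$area <- a2 / 2
  surface$center <- (p1 + p2 + p3) / 3
  surface$normal <- cr / a2

  # edge structure: closed iff every undirected edge appears exactly twice,
  # oriented iff no directed edge repeats
  de <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  key_d <- paste(de[, 1], de[, 2])
  key_u <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  cnt <- table(key_u)
  surface$closed <- all(cnt == 2L)
  surface$oriented <- !anyDuplicated(key_d) && all(cnt <= 2L)
  surface
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("tri_surface: %d nodes, %d facets, area %.1f mm^2%s%s\n",
              nrow(x$nodes), nrow(x$tris), sum(x$area),
              if (isTRUE(x$closed)) ", closed" else "",
              if (isTRUE(x$oriented)) ", oriented" else ""))
  invisible(x)
}

#' Extract the outer boundary surface of a tetrahedral mesh
#'
#' Boundary facets are those appearing in exactly one tetrahedron.  Facets
#' are wound so normals point away from the adjacent tetrahedron (outward
#' for a watertight mesh).  Faces shared by more than two tetrahedra are
#' reported as a non-manifold error.
#'
#' @param mesh a [head_mesh()].
#' @return a closed, oriented [tri_surface()] (the scalp for a head mesh).
#' @export
extract_boundary_surface <- function(mesh) {
  tets <- mesh$tets
  # the face opposite to local vertex v, wound so its normal points away
  # from v (outward when v is the interior vertex)
  faces <- rbind(tets[, c(2, 4, 3)], tets[, c(1, 3, 4)],
                 tets[, c(1, 4, 2)], tets[, c(1, 2, 3)])
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  cnt <- table(key)
  if (any(cnt > 2L))
    stop("non-manifold boundary: face(s) shared by >2 tets: ",
         paste(utils::head(names(cnt)[cnt > 2L], 5L), collapse = "; "))
  once <- key %in% names(cnt)[cnt == 1L]
  bf <- faces[once, , drop = FALSE]
  bopp <- opp[once]

  # verify winding: normal should point away from the opposite vertex
  p1 <- mesh$nodes[bf[, 1], , drop = FALSE]
  p2 <- mesh$nodes[bf[, 2], , drop = FALSE]
  p3 <- mesh$nodes[bf[, 3], , drop = FALSE]
  nrm <- row_cross(p2 - p1, p3 - p1)
  inward <- rowSums(nrm * (mesh$nodes[bopp, , drop = FALSE] - p1)) > 0
  bf[inward, c(2, 3)] <- bf[inward, c(3, 2)]

  keep <- sort(unique(as.vector(bf)))
  remap <- integer(nrow(mesh$nodes)); remap[keep] <- seq_along(keep)
  out <- tri_surface(mesh$nodes[keep, , drop = FALSE],
                     matrix(remap[bf], ncol = 3L))
  if (!isTRUE(out$closed))
    warning("extracted boundary is not closed")
  out
}

# angle-weighted node normals of a triangle surface
node_normals <- function(surface) {
  tris <- surface$tris; nodes <- surface$nodes
  acc <- matrix(0, nrow(nodes), 3L)
  corner_angle <- function(a, b, c) {
    u <- nodes[b, , drop = FALSE] - nodes[a, , drop = FALSE]
    v <- nodes[c, , drop = FALSE] - nodes[a, , drop = FALSE]
    cosang <- rowSums(u * v) / (row_norms(u) * row_norms(v))
    acos(pmin(1, pmax(-1, cosang)))
  }
  ang <- cbind(corner_angle(tris[, 1], tris[, 2], tris[, 3]),
               corner_angle(tris[, 2], tris[, 3], tris[, 1]),
               corner_angle(tris[, 3], tris[, 1], tris[, 2]))
  for (v in 1:3) {
    w <- ang[, v] * surface$normal
    s <- rowsum(w, group = tris[, v])
    acc[as.integer(rownames(s)), ] <- acc[as.integer(rownames(s)), ] + s
  }
  acc / pmax(row_norms(acc), .Machine$double.eps)
}

#' Offset a closed surface along its node normals
#'
#' Moves every node by `distance` along its angle-weighted node normal
#' (average of incident facet normals weighted by the incident corner
#' angle); connectivity is unchanged.  Used to build the Huygens surface
#' 1 mm outside the scalp.  If any facet normal flips direction after the
#' offset (a fold/self-intersection proxy), a warning reports the count and
#' the surface is returned anyway.
#'
#' @param surface a closed, outward-oriented [tri_surface()].
#' @param distance offset in mm (default 1).
#' @return the extruded [tri_surface()].
#' @export
extrude_surface <- function(surface, distance = 1) {
  if (!isTRUE(surface$closed))
    stop("extrusion requires a closed surface")
  nn <- node_normals(surface)
  out <- surface
  out$nodes <- surface$nodes + distance * nn
  out <- surface_geometry(out)
  flipped <- sum(rowSums(out$normal * surface$normal) < 0)
  if (flipped > 0)
    warning(sprintf("%d facet(s) folded after extrusion; proceeding", flipped))
  out
}

#' Read / write STL triangle surfaces
#'
#' `read_stl` auto-detects binary versus ASCII STL; `write_stl` writes
#' ASCII (default) or binary.  STL duplicates vertices per facet; on read,
#' vertices are merged exactly by coordinate.
#'
#' @param path file path.
#' @return `read_stl`: a [tri_surface()].
#' @export
read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 84L)
  is_ascii <- identical(rawToChar(hdr[1:5]), "solid") && {
    txt <- tryCatch(readLines(path, n = 10L, warn = FALSE),
                    error = function(e) "")
    any(grepl("facet", txt))
  }
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    v <- matrix(scan(text = gsub("vertex", "", vl), quiet = TRUE),
                ncol = 3, byrow = TRUE)
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", 80L)
    nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    rec <- readBin(con, "raw", n = nf * 50L)
    m <- matrix(rec, nrow = 50L)
    v <- matrix(0, nf * 3L, 3L)
    for (k in 1:3) {
      off <- 12L * k  # skip normal (12 bytes), then vertex k
      v[seq(k, by = 3L, length.out = nf), ] <-
        matrix(readBin(as.vector(m[(off + 1L):(off + 12L), ]), "numeric",
                       n = 3L * nf, size = 4L, endian = "little"),
               ncol = 3L, byrow = TRUE)
    }
  }
  key <- paste(v[, 1], v[, 2], v[, 3])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  tri_surface(v[uk, , drop = FALSE], matrix(idx, ncol = 3L, byrow = TRUE))
}

#' @rdname read_stl
#' @param surface a [tri_surface()].
#' @param binary write binary STL instead of ASCII.
#' @export
write_stl <- function(surface, path, binary = FALSE) {
  tris <- surface$tris; nodes <- surface$nodes
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(tris)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(tris))) {
      writeBin(as.numeric(c(surface$normal[i, ],
                            t(nodes[tris[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid surface", con)
    for (i in seq_len(nrow(tris))) {
      writeLines(sprintf("facet normal %g %g %g", surface$normal[i, 1],
                         surface$normal[i, 2], surface$normal[i, 3]), con)
      writeLines("  outer loop", con)
      writeLines(sprintf("    vertex %.9g %.9g %.9g",
                         nodes[tris[i, ], 1], nodes[tris[i, ], 2],
                         nodes[tris[i, ], 3]), con)
      writeLines(c("  endloop", "endfacet"), con)
    }
    writeLines("endsolid surface", con)
  }
  invisible(path)
}
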