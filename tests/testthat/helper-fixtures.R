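# Shared lazily-built fixtures, memoized across test files.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# coarse 5-layer phantom (subdiv 2: 5120 tets, 320 scalp facets)
small_phantom <- function() memo("ph8", function()
  make_layered_sphere_phantom(target_edge = 8))

small_operator <- function() memo("op8", function()
  assemble_conduction_system(small_phantom()$mesh))

# compact session on the coarse phantom for online-stage tests
small_session <- function() memo("ses8", function() {
  ph <- small_phantom()
  tms_precompute(ph$mesh, build_figure8_coil(segments_per_turn = 16),
                 ph$mid_gm, n_modes = 60, seed = 11, scalp = ph$scalp,
                 grid_spacing = 8, verbose = FALSE)
})

# one-triangle surface with prescribed area at the origin in the x-y plane
single_facet_surface <- function(side = 2) {
  tri_surface(rbind(c(-side / 2, -side / 3, 0), c(side / 2, -side / 3, 0),
                    c(0, 2 * side / 3, 0)),
              matrix(1:3, 1))
}

# regular tetrahedron with unit edge, one corner pattern
regular_tet_nodes <- function(edge = 1) {
  edge * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(6) / 3))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(sqrt(sum((x - y)^2)) / max(sqrt(sum(y^2)),
                                       .Machine$double.xmin), tol)
}
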