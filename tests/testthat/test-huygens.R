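test_that("zero volume current radiates zero surface fields", {
  ph <- small_phantom()
  huy <- extrude_surface(ph$scalp, 1)
  sf <- mode_fields_on_surface(ph$mesh, matrix(0, nrow(ph$mesh$tets), 3), huy)
  expect_equal(max(abs(sf$E)), 0)
  expect_equal(max(abs(sf$H)), 0)
})

test_that("single-tet current matches hand-evaluated kernels and is linear", {
  m <- head_mesh(regular_tet_nodes(), matrix(1:4, 1), 1L, roi_labels = 1L)
  J <- matrix(c(0, 0, 1), 1, 3)            # unit z current density
  d_mm <- 400                               # far observer on +x
  obs <- single_facet_surface()
  obs$nodes <- sweep(obs$nodes, 2L, -c(d_mm, 0, 0))
  obs <- surface_geometry(obs)
  sf <- mode_fields_on_surface(m, J, obs)
  V_m3 <- m$volume * 1e-9
  dvec <- (obs$center[1, ] - m$centroid[1, ]) * 1e-3
  dn <- sqrt(sum(dvec^2))
  # Biot-Savart: H = V (z-hat x d) / (4 pi |d|^3), dominated by +y here
  h_ref <- V_m3 * c(-dvec[2], dvec[1], 0) / (4 * pi * dn^3)
  expect_rel_equal(drop(sf$H), h_ref, 1e-10)
  expect_gt(h_ref[2], 0)                   # +(z-hat x x-hat) direction
  # inductive E: -(mu0/4pi) V J / d
  mu0 <- 4 * pi * 1e-7
  expect_rel_equal(drop(sf$E), c(0, 0, -mu0 * V_m3 / (4 * pi * dn)), 1e-10)
  sf2 <- mode_fields_on_surface(m, 2 * J, obs)
  expect_equal(sf2$E, 2 * sf$E, tolerance = 1e-14)
  expect_equal(sf2$H, 2 * sf$H, tolerance = 1e-14)
})

test_that("observers touching the head are rejected", {
  ph <- small_phantom()
  inner <- tri_surface(ph$mid_gm$nodes, ph$mid_gm$tris)  # inside the head
  expect_error(mode_fields_on_surface(ph$mesh,
                                      matrix(1, nrow(ph$mesh$tets), 3),
                                      inner),
               "inside or touching")
})

test_that("equivalent currents obey the boundary-condition cross products", {
  huy <- extrude_surface(small_phantom()$scalp, 1)
  nd <- nrow(huy$tris)
  set.seed(31)
  E <- matrix(rnorm(nd * 6), nd, 6)        # two modes
  H <- matrix(rnorm(nd * 6), nd, 6)
  hc <- equivalent_currents(structure(list(E = E, H = H, surface = huy),
                                      class = "surface_field_set"), huy)
  for (r in 1:2) {
    j <- (3 * r - 2):(3 * r)
    expect_lt(max(abs(rowSums(hc$JS[, j] * huy$normal))),
              1e-10 * max(abs(hc$JS[, j])))
    expect_lt(max(abs(rowSums(hc$KS[, j] * huy$normal))),
              1e-10 * max(abs(hc$KS[, j])))
  }
  # purely normal H gives zero electric current
  hc2 <- equivalent_currents(structure(list(E = E, H = cbind(huy$normal,
                                                             huy$normal),
                                            surface = huy),
                                       class = "surface_field_set"), huy)
  expect_lt(max(abs(hc2$JS)), 1e-12)
  # tangential unit E gives |K_S| = 1, K_S = -n x t; build tangents from
  # the least-aligned coordinate axis so they never degenerate
  ax <- diag(3)[apply(abs(huy$normal), 1L, which.min), , drop = FALSE]
  t1 <- ax - huy$normal * rowSums(huy$normal * ax)
  t1 <- t1 / sqrt(rowSums(t1^2))
  hc3 <- equivalent_currents(structure(list(E = cbind(t1, t1),
                                            H = H, surface = huy),
                                       class = "surface_field_set"), huy)
  expect_equal(sqrt(rowSums(hc3$KS[, 1:3]^2)), rep(1, nd), tolerance = 1e-10)
})

test_that("reciprocity operator reproduces the explicit quadrature loop", {
  huy <- extrude_surface(small_phantom()$scalp, 1)
  nd <- nrow(huy$tris)
  set.seed(32)
  R <- 3L
  hc <- structure(list(JS = matrix(rnorm(nd * 3 * R), nd, 3 * R),
                       KS = matrix(rnorm(nd * 3 * R), nd, 3 * R),
                       surface = huy, n_modes = R),
                  class = "huygens_current_set")
  B <- build_reciprocity_operator(hc, huy)
  Ep <- matrix(rnorm(nd * 3), nd, 3)
  Hp <- matrix(rnorm(nd * 3), nd, 3)
  a <- drop(B$B %*% c(as.vector(t(Ep)), as.vector(t(Hp))))
  # explicit loop oracle
  a_ref <- numeric(R)
  for (i in seq_len(R)) {
    ji <- (3 * i - 2):(3 * i)
    for (j in seq_len(nd))
      a_ref[i] <- a_ref[i] + huy$area[j] * 1e-6 *
        (sum(Ep[j, ] * hc$JS[j, ji]) - sum(Hp[j, ] * hc$KS[j, ji]))
  }
  expect_rel_equal(a, a_ref, 1e-12)
  # zero currents give the zero operator
  hc0 <- hc; hc0$JS[] <- 0; hc0$KS[] <- 0
  expect_equal(max(abs(build_reciprocity_operator(hc0, huy)$B)), 0)
  # consistent facet reordering leaves the coefficients unchanged
  perm <- sample(nd)
  huyp <- huy
  huyp$tris <- huy$tris[perm, , drop = FALSE]
  huyp <- surface_geometry(huyp)
  pj <- as.vector(t(matrix(3 * (perm - 1), nd, 3) +
                    matrix(1:3, nd, 3, byrow = TRUE)))
  hcp <- structure(list(JS = hc$JS[perm, , drop = FALSE],
                        KS = hc$KS[perm, , drop = FALSE],
                        surface = huyp, n_modes = R),
                   class = "huygens_current_set")
  Bp <- build_reciprocity_operator(hcp, huyp)
  ap <- drop(Bp$B %*% c(as.vector(t(Ep[perm, ])), as.vector(t(Hp[perm, ]))))
  expect_rel_equal(ap, a, 1e-12)
})
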