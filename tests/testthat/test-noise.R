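test_that("noise realizations are keyed by (seed, i), independent of count", {
  huy <- extrude_surface(small_phantom()$scalp, 1)
  n1 <- sample_white_noise_currents(huy, 3, seed = 7)
  n2 <- sample_white_noise_currents(huy, 3, seed = 7)
  expect_identical(n1$W, n2$W)
  n3 <- sample_white_noise_currents(huy, 10, seed = 7)
  expect_identical(n3$W[, , 3], n1$W[, , 3])
  n4 <- sample_white_noise_currents(huy, 3, seed = 8)
  expect_false(isTRUE(all.equal(n4$W, n1$W)))
  expect_error(sample_white_noise_currents(huy, 0, seed = 1), ">= 1")
})

test_that("noise draws are standard normal and uncorrelated across realizations", {
  huy <- extrude_surface(small_phantom()$scalp, 1)    # 320 facets
  ns <- sample_white_noise_currents(huy, 110, seed = 2)
  draws <- as.numeric(ns$W)
  n <- length(draws)
  expect_gte(n, 1e5)
  expect_lt(abs(mean(draws)), 3 / sqrt(n))
  expect_lt(abs(stats::sd(draws) - 1), 0.02)
  # pairwise correlation between distinct realizations (3*320 = 960 draws
  # each) stays at chance level
  ph4 <- make_layered_sphere_phantom(target_edge = 4)
  huy4 <- extrude_surface(ph4$scalp, 1)
  ns4 <- sample_white_noise_currents(huy4, 4, seed = 3)
  for (i in 1:3)
    expect_lt(abs(stats::cor(as.numeric(ns4$W[, , i]),
                             as.numeric(ns4$W[, , i + 1]))), 0.05)
})

test_that("magnetic-current primary field matches the hand-evaluated kernel", {
  s <- single_facet_surface()
  A_m2 <- s$area * 1e-6
  W <- matrix(c(0, 0, 2.5), 1, 3)
  d_mm <- 40
  ctr <- s$center[1, ]
  # observer on the facet-normal axis: W parallel to the separation, E = 0
  E0 <- magnetic_current_primary_efield(W, s, rbind(ctr + c(0, 0, d_mm)))
  expect_lt(max(abs(E0)), 1e-14)
  # observer along +x from the center: E = -(A W / 4 pi d^2) y-hat
  E1 <- magnetic_current_primary_efield(W, s, rbind(ctr + c(d_mm, 0, 0)))
  expect_equal(drop(E1),
               c(0, -A_m2 * 2.5 / (4 * pi * (d_mm * 1e-3)^2), 0),
               tolerance = 1e-12)
  # linear in the current scale
  E5 <- magnetic_current_primary_efield(5 * W, s, rbind(ctr + c(d_mm, 0, 0)))
  expect_equal(E5, 5 * E1, tolerance = 1e-12)
  # singular at a facet center
  expect_error(magnetic_current_primary_efield(W, s, rbind(ctr)), "source")
})

test_that("duplicated input fields collapse to rank one", {
  ph <- small_phantom()
  n_roi <- sum(ph$mesh$roi)
  set.seed(9)
  f <- matrix(rnorm(n_roi * 3), n_roi, 3)
  basis <- suppressWarnings(build_basis(cbind(f, f), ph$mesh))
  expect_lt(basis$sv[2], 1e-10 * basis$sv[1])
})

test_that("modes are orthonormal under the volume-weighted inner product", {
  ses <- small_session()
  G <- basis_gram(ses$basis)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  expect_true(all(diff(ses$basis$sv) <= 1e-12))
})

test_that("qr+svd route matches a dense svd of Z on a toy ROI", {
  ph <- small_phantom()
  mesh <- ph$mesh
  roi_tets <- which(mesh$roi)
  set.seed(12)
  R <- 12L
  n_roi <- sum(mesh$roi)
  f <- matrix(rnorm(n_roi * 3 * R), n_roi, 3 * R)
  basis <- build_basis(f, mesh)
  # dense-SVD oracle on the same sqrt(V)-weighted matrix
  sw <- sqrt(rep(mesh$volume[mesh$roi] * 1e-9, each = 3L))
  Z <- sapply(seq_len(R), function(r)
    as.vector(t(f[, (3 * r - 2):(3 * r)])) * sw)
  sv_ref <- svd(Z)
  expect_lt(max(abs(basis$sv - sv_ref$d)) / sv_ref$d[1], 1e-10)
  # same span: weighted modes and reference left vectors give the same
  # projector
  Pw <- basis$modes * sw
  D <- abs(crossprod(Pw, sv_ref$u))
  expect_lt(max(abs(D - diag(R))), 1e-8)
})

test_that("mode basis is invariant to the overall noise scale", {
  ph <- small_phantom()
  n_roi <- sum(ph$mesh$roi)
  set.seed(13)
  f <- matrix(rnorm(n_roi * 3 * 5), n_roi, 15)
  b1 <- build_basis(f, ph$mesh)
  b2 <- build_basis(137.5 * f, ph$mesh)
  expect_equal(abs(b1$modes), abs(b2$modes), tolerance = 1e-10)
})

test_that("truncated reconstruction error equals the singular-value tail", {
  ph <- small_phantom()
  mesh <- ph$mesh
  set.seed(14)
  n_roi <- sum(mesh$roi)
  R <- 10L
  f <- matrix(rnorm(n_roi * 3 * R), n_roi, 3 * R)
  basis <- build_basis(f, mesh)
  w <- rep(mesh$volume[mesh$roi] * 1e-9, each = 3L)
  for (k in c(3L, 7L)) {
    P <- basis$modes[, seq_len(k), drop = FALSE]
    tail2 <- 0
    for (r in seq_len(R)) {
      v <- as.vector(t(f[, (3 * r - 2):(3 * r)]))
      a <- crossprod(P, w * v)
      tail2 <- tail2 + sum(w * (v - P %*% a)^2)
    }
    expect_equal(tail2, sum(basis$sv[(k + 1):R]^2), tolerance = 1e-8)
  }
})
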