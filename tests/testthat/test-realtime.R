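test_that("point location agrees with a brute-force containment oracle", {
  ph <- small_phantom()
  mesh <- ph$mesh
  set.seed(51)
  # random points inside the head ball
  u <- matrix(rnorm(300), 100, 3)
  pts <- u / sqrt(rowSums(u^2)) * runif(100, 5, 80)
  got <- locate_points(mesh, pts, error_outside = FALSE)
  # brute force: barycentric test over all tets via the 4x4 system
  brute_one <- function(p) {
    for (k in seq_len(nrow(mesh$tets))) {
      Vm <- t(cbind(1, mesh$nodes[mesh$tets[k, ], ]))
      lam <- solve(Vm, c(1, p))
      if (all(lam >= -1e-9)) return(k)
    }
    NA_integer_
  }
  ref <- vapply(seq_len(25), function(i) brute_one(pts[i, ]), integer(1))
  # containment can tie on shared faces; compare by containment validity
  for (i in 1:25) {
    expect_false(is.na(got[i]))
    Vm <- t(cbind(1, mesh$nodes[mesh$tets[got[i], ], ]))
    expect_true(all(solve(Vm, c(1, pts[i, ])) >= -1e-6))
    expect_false(is.na(ref[i]))
  }
  expect_error(locate_points(mesh, rbind(c(0, 0, 200))), "outside")
})

test_that("precompute is deterministic in the seed", {
  ph <- small_phantom()
  cl <- build_figure8_coil(segments_per_turn = 16)
  s1 <- tms_precompute(ph$mesh, cl, ph$mid_gm, n_modes = 8, seed = 5,
                       scalp = ph$scalp, grid_spacing = 16, verbose = FALSE)
  s2 <- tms_precompute(ph$mesh, cl, ph$mid_gm, n_modes = 8, seed = 5,
                       scalp = ph$scalp, grid_spacing = 16, verbose = FALSE)
  expect_identical(s1$basis$modes, s2$basis$modes)
  expect_identical(s1$B, s2$B)
  expect_identical(s1$modes_eval, s2$modes_eval)
})

test_that("requesting more modes than realizations fails", {
  ph <- small_phantom()
  n_roi <- sum(ph$mesh$roi)
  f <- matrix(rnorm(n_roi * 9), n_roi, 9)
  expect_error(build_basis(f, ph$mesh, n_keep = 5), "exceeds")
})

test_that("coefficients are linear and reconstruct single modes exactly", {
  ses <- small_session()
  nd <- nrow(ses$huygens$tris)
  a0 <- compute_coefficients(ses, matrix(0, nd, 3), matrix(0, nd, 3))
  expect_equal(a0, rep(0, ses$n_modes))
  set.seed(52)
  Ep <- matrix(rnorm(nd * 3), nd, 3); Hp <- matrix(rnorm(nd * 3), nd, 3)
  a1 <- compute_coefficients(ses, Ep, Hp)
  a3 <- compute_coefficients(ses, 3 * Ep, 3 * Hp)
  expect_equal(a3, 3 * a1, tolerance = 1e-12)
  # unit first coefficient returns the first mode samples
  e1 <- c(1, rep(0, ses$n_modes - 1))
  E <- reconstruct_field(ses, e1, dIdt = 1)
  expect_equal(as.vector(t(E)), as.numeric(ses$modes_eval[, 1]),
               tolerance = 1e-14)
  expect_equal(reconstruct_field(ses, a1, n_use = 0L),
               matrix(0, nrow(ses$eval_surface$tris), 3))
})

test_that("online solve composes its stages and scales with dIdt", {
  ses <- small_session()
  T <- sample_scalp_placements(ses$scalp, 1, seed = 6)[[1]]
  E <- realtime_solve(ses, T, dIdt = 1)
  pts <- transform_points(ses$huygens$center, T, inverse = TRUE)
  pf <- interpolate_fields(ses$grid, pts)
  R <- T[1:3, 1:3]
  a <- compute_coefficients(ses, pf$E %*% t(R), pf$H %*% t(R))
  E2 <- reconstruct_field(ses, a, dIdt = 1)
  expect_equal(unclass(E), E2, tolerance = 1e-14, ignore_attr = TRUE)
  Es <- realtime_solve(ses, T, dIdt = 2.5)
  expect_equal(unclass(Es), 2.5 * unclass(E), tolerance = 1e-12,
               ignore_attr = TRUE)
  # predict method is the same path
  Ep <- predict(ses, T, dIdt = 1)
  expect_equal(unclass(Ep), unclass(E), ignore_attr = TRUE)
})

test_that("out-of-envelope placements are refused by the interpolator", {
  ses <- small_session()
  T_far <- placement(diag(3), c(0, 0, 500))
  expect_error(realtime_solve(ses, T_far), "outside")
})

test_that("rotating the figure-8 about its axis by pi preserves |E|", {
  # exact primary fields (no grid) isolate the coil/reciprocity symmetry
  ses <- small_session()
  T <- sample_scalp_placements(ses$scalp, 1, seed = 8)[[1]]
  Rz <- rbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1))
  T2 <- placement(T[1:3, 1:3] %*% Rz, T[1:3, 4])
  field_mag <- function(Tk) {
    tc <- rtefield:::transform_coil(ses$coil, Tk)
    pf <- coil_primary_fields(tc, ses$huygens$center, dIdt = 1)
    a <- compute_coefficients(ses, pf$E, pf$H)
    sqrt(rowSums(reconstruct_field(ses, a, dIdt = 1)^2))
  }
  m1 <- field_mag(T)
  m2 <- field_mag(T2)
  expect_lt(sqrt(sum((m1 - m2)^2) / sum(m1^2)), 1e-8)
})

test_that("sessions round trip through the serialized container", {
  ses <- small_session()
  f <- tempfile(fileext = ".rds")
  save_session(ses, f)
  s2 <- load_session(f)
  expect_identical(s2$B, ses$B)
  T <- sample_scalp_placements(ses$scalp, 1, seed = 9)[[1]]
  expect_equal(unclass(realtime_solve(s2, T)),
               unclass(realtime_solve(ses, T)), ignore_attr = TRUE)
  unlink(f)
})

test_that("reciprocity coefficients agree with direct projection up to quadrature", {
  # loose regression bound: correct signs and constants put the two routes
  # within quadrature error (a few percent); any sign error yields ~200%
  ses <- small_session()
  ph <- small_phantom()
  op <- small_operator()
  T <- sample_scalp_placements(ses$scalp, 2, seed = 10)
  for (k in 1:2) {
    a11 <- mode_coefficients(ses, T[[k]])
    Eref <- solve_direct_tms(ph$mesh, ses$coil, T[[k]], dIdt = 1, op = op)
    w <- rep(ses$basis$vol_m3, each = 3)
    a7 <- drop(crossprod(ses$basis$modes, w * as.vector(t(Eref))))
    expect_lt(sqrt(sum((a11 - a7)^2) / sum(a7^2)), 0.10)
    expect_gt(sum(a11 * a7) / sum(a7^2), 0.9)
  }
})
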