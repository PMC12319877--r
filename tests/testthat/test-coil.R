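test_that("figure-8 windings are closed polygons with the stated element count", {
  cl <- build_figure8_coil(segments_per_turn = 24)
  expect_equal(nrow(cl$positions), 2L * 9L * 24L)
  for (l in unique(cl$loop)) {
    s <- colSums(cl$weights[cl$loop == l, ])
    expect_lt(max(abs(s)), 1e-10)
  }
})

test_that("figure-8 field is mirror symmetric about the junction plane", {
  cl <- build_figure8_coil(segments_per_turn = 20)
  set.seed(21)
  p <- cbind(runif(20, 5, 60), runif(20, -60, 60), runif(20, -80, -20))
  pm <- p; pm[, 1] <- -pm[, 1]
  f1 <- coil_primary_fields(cl, p, dIdt = 1)
  f2 <- coil_primary_fields(cl, pm, dIdt = 1)
  expect_equal(sqrt(rowSums(f1$E^2)), sqrt(rowSums(f2$E^2)),
               tolerance = 1e-8)
  expect_equal(sqrt(rowSums(f1$H^2)), sqrt(rowSums(f2$H^2)),
               tolerance = 1e-8)
})

test_that("coil files round trip and reject malformed input", {
  cl <- build_figure8_coil(segments_per_turn = 16)
  f <- tempfile(fileext = ".ccd")
  write_coil_file(cl, f)
  c2 <- load_coil_file(f)
  expect_equal(c2$positions, cl$positions, tolerance = 1e-12)
  expect_equal(c2$weights, cl$weights, tolerance = 1e-12)
  expect_identical(c2$representation, "electric")
  # single element file
  f1 <- tempfile()
  writeLines(c("representation=magnetic units=mm", "0 0 0 0 0 1"), f1)
  c3 <- load_coil_file(f1)
  expect_equal(nrow(c3$positions), 1L)
  expect_identical(c3$representation, "magnetic")
  # missing header
  f2 <- tempfile()
  writeLines("0 0 0 0 0 1", f2)
  expect_error(load_coil_file(f2), "representation")
  # malformed line is reported by number
  f3 <- tempfile()
  writeLines(c("representation=electric units=mm", "0 0 0 0 0 1",
               "0 0 bad 0 0 1"), f3)
  expect_error(load_coil_file(f3), "line 3")
  unlink(c(f, f1, f2, f3))
})

test_that("single current element reproduces the hand-evaluated kernels", {
  cl <- coil_model(matrix(0, 1, 3), matrix(c(0, 0, 1), 1, 3), "electric")
  d_mm <- 25; dIdt <- 2e7
  pf <- coil_primary_fields(cl, rbind(c(d_mm, 0, 0)), dIdt = dIdt)
  mu0 <- 4 * pi * 1e-7
  # E parallel to -z with magnitude mu0 dIdt |dl| / (4 pi d)
  expect_equal(drop(pf$E),
               c(0, 0, -mu0 * dIdt * 1e-3 / (4 * pi * d_mm * 1e-3)),
               tolerance = 1e-12)
  # H = dl x r / (4 pi d^3)
  expect_equal(drop(pf$H),
               c(0, 1e-3 * (d_mm * 1e-3) / (4 * pi * (d_mm * 1e-3)^3), 0),
               tolerance = 1e-12)
  # dIdt = 0 kills E but not H
  pf0 <- coil_primary_fields(cl, rbind(c(d_mm, 0, 0)), dIdt = 0)
  expect_equal(max(abs(pf0$E)), 0)
  expect_equal(pf0$H, pf$H)
})

test_that("closed small loop has dipole-like far-field decay", {
  th <- 2 * pi * (0:15) / 16
  v <- cbind(5 * cos(th), 5 * sin(th), 0)
  nxt <- c(2:16, 1)
  cl <- coil_model((v + v[nxt, ]) / 2, v[nxt, ] - v,
                   representation = "electric")
  d <- 40 * 2^(0:4)    # over a decade, along the loop axis, far field
  H <- coil_primary_fields(cl, cbind(0, 0, d), dIdt = 1)$H
  mag <- sqrt(rowSums(H^2))
  slope <- coef(lm(log(mag) ~ log(d)))[2]
  expect_lt(abs(slope + 3), 0.1)
})

test_that("placements are rigid and validated", {
  expect_error(placement(diag(3) * 2), "rotation")
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  T <- placement(Rz(0.3), c(1, 2, 3))
  expect_equal(det(T[1:3, 1:3]), 1, tolerance = 1e-12)
  Tm <- placement_from_matrix(as.numeric(t(unclass(T))))
  expect_equal(unclass(Tm), unclass(T), tolerance = 1e-15)
  Tt <- tangential_placement(c(0, 0, 85), c(0, 0, 1), standoff = 5)
  expect_equal(Tt[1:3, 4], c(0, 0, 90))
  expect_equal(Tt[1:3, 3], c(0, 0, 1))
})

test_that("scalp placement sampler is seeded and respects the equator", {
  scalp <- small_phantom()$scalp
  p1 <- sample_scalp_placements(scalp, 5, seed = 3)
  p2 <- sample_scalp_placements(scalp, 5, seed = 3)
  expect_equal(p1, p2)
  for (T in p1) {
    t <- T[1:3, 4]
    expect_gt(t[3], 0)
    expect_equal(sqrt(sum(t^2)), 85 * 0.98 + 5, tolerance = 0.05 * 90)
    # outward z-axis: coil normal aligned with the radial direction
    expect_gt(sum(T[1:3, 3] * t) / sqrt(sum(t^2)), 0.99)
  }
})
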