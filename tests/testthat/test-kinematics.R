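test_that("spline weight matches both branch values and is C1 at the knot", {
  expect_equal(spline_weight(0), 1)
  expect_equal(spline_weight(1), 0)
  expect_equal(spline_weight(2.5), 0)
  # both polynomial branches at r = 1/2
  expect_equal(1 - 6 * 0.25 + 6 * 0.125, 0.25)
  expect_equal(2 - 6 * 0.5 + 6 * 0.25 - 2 * 0.125, 0.25)
  expect_equal(spline_weight(0.5), 0.25)
  # value and slope continuity across the knot (central difference)
  h <- 1e-6
  dl <- (spline_weight(0.5) - spline_weight(0.5 - h)) / h
  dr <- (spline_weight(0.5 + h) - spline_weight(0.5)) / h
  expect_equal(dl, dr, tolerance = 1e-4)
  expect_error(spline_weight(-0.1), "non-negative")
})

test_that("weight is non-increasing on [0, 1] and continuous", {
  r <- seq(0, 1.2, by = 1e-3)
  w <- spline_weight(r)
  expect_true(all(diff(w[r <= 1]) <= 1e-12))
  expect_true(all(w >= 0 & w <= 1))
  expect_lt(max(abs(diff(w))), 0.01) # no jumps at this resolution
})

test_that("deformation gradient is the identity for rigid translation and exact for affine maps", {
  cnt <- make_shape_contour("disk", list(radius = 8), M = 48L)
  still <- deformation_gradient_field(cnt, cnt)
  expect_true(all(still$valid))
  expect_lt(max(abs(sweep(still$F, c(1, 2), diag(2)))), 1e-12)
  Fm <- matrix(c(1.1, 0, 0, 0.9), 2, 2)
  cell <- apply_affine_sequence(cnt, list(Fm))
  df <- deformation_gradient_field(cell$contours[[1]], cell$contours[[2]])
  expect_lt(max(abs(sweep(df$F[, , df$valid], c(1, 2), Fm))), 1e-9)
  # and G = F - I
  expect_lt(max(abs(df$G[, , df$valid][1, 1, ] - 0.1)), 1e-9)
})

test_that("a pure rotation is recovered as the rotation matrix", {
  cnt <- random_contour(M = 40L)
  Rm <- rotation_matrix(pi / 6)
  cell <- apply_affine_sequence(cnt, list(Rm))
  df <- deformation_gradient_field(cell$contours[[1]], cell$contours[[2]])
  expect_lt(max(abs(sweep(df$F[, , df$valid], c(1, 2), Rm))), 1e-9)
})

test_that("estimator agrees with the unweighted normal-equations oracle and ignores translations", {
  set.seed(21)
  cnt <- random_contour(M = 32L)
  Fm <- matrix(c(1.04, 0.02, -0.05, 0.97), 2, 2)
  cell <- apply_affine_sequence(cnt, list(Fm), list(c(4, -2)))
  ref <- cell$contours[[1]]$points
  cur <- cell$contours[[2]]$points
  df <- deformation_gradient_field(cell$contours[[1]], cell$contours[[2]])
  for (i in c(1L, 9L, 17L, 30L)) {
    expect_equal(df$F[, , i], oracle_affine_F(ref, cur, i),
                 tolerance = 1e-9)
  }
  # adding a constant to the current configuration changes nothing
  shifted <- new_contour(sweep(cur, 2, c(12, 7), `+`))
  df2 <- deformation_gradient_field(cell$contours[[1]], shifted)
  expect_equal(df$F, df2$F, tolerance = 1e-12)
})

test_that("updated-Lagrangian composition of frame-to-frame gradients matches the direct map", {
  cnt <- make_shape_contour("disk", list(radius = 6), M = 40L)
  F1 <- matrix(c(1.05, 0.01, 0.02, 0.96), 2, 2)
  F2 <- matrix(c(0.99, -0.03, 0.01, 1.04), 2, 2)
  cell <- apply_affine_sequence(cnt, list(F1, F2))
  d1 <- deformation_gradient_field(cell$contours[[1]], cell$contours[[2]])
  d2 <- deformation_gradient_field(cell$contours[[2]], cell$contours[[3]])
  i <- which(d1$valid & d2$valid)[1]
  expect_equal(d2$F[, , i] %*% d1$F[, , i], F2 %*% F1, tolerance = 1e-6)
})

test_that("infinitesimal strain has the expected simple-shear and isotropic forms", {
  expect_equal(infinitesimal_strain(diag(2)), matrix(0, 2, 2))
  gam <- 0.02
  eps <- infinitesimal_strain(matrix(c(1, 0, gam, 1), 2, 2))
  expect_equal(eps, matrix(c(0, 0.01, 0.01, 0), 2, 2))
  e <- 0.05
  expect_equal(infinitesimal_strain((1 + e) * diag(2)), e * diag(2))
  # array form stays symmetric
  arr <- array(runif(2 * 2 * 5), c(2, 2, 5))
  s <- infinitesimal_strain(arr)
  expect_lt(max(abs(s[1, 2, ] - s[2, 1, ])), 1e-12)
})

test_that("adjusted strain applies the Maxwell and geometry scaling", {
  eps <- matrix(c(0.1, 0.02, 0.02, -0.05), 2, 2)
  # beta 0.1, w_n 5 nm, l 25 um, A 50 um^2 (all in metres)
  adj <- adjusted_strain(eps, beta_e = 0.1, w_n = 5e-9, l = 25e-6,
                         A_cell = 50e-12)
  expect_equal(adj$scale, 2.5e-4)
  expect_equal(adj$eps, eps * 2.5e-4)
  # identity scaling when beta = 1 and w_n * l = A
  adj2 <- adjusted_strain(eps, beta_e = 1, w_n = 2, l = 3, A_cell = 6)
  expect_equal(adj2$eps, eps)
  expect_equal(adjusted_strain(matrix(0, 2, 2), l = 1, A_cell = 1)$eps,
               matrix(0, 2, 2))
  expect_error(adjusted_strain(eps, beta_e = 0, l = 1, A_cell = 1), "beta_e")
  expect_error(adjusted_strain(eps, l = 1, A_cell = 0), "area")
})

test_that("contour geometry reproduces analytic square and circle values", {
  sq <- new_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  g <- contour_geometry(sq)
  expect_equal(g$A_cell, 1)
  expect_equal(g$l, 4)
  expect_equal(g$centroid, c(0.5, 0.5))
  circ <- make_shape_contour("disk", list(radius = 5), M = 512L)
  gc <- contour_geometry(circ)
  expect_equal(gc$A_cell, 25 * pi, tolerance = 1e-3)
  expect_equal(gc$l, 10 * pi, tolerance = 1e-3)
  expect_equal(gc$dl, gc$l / 512)
  # outward normal at the rightmost point is along +x
  i <- which.max(circ$points[, 1])
  expect_lt(abs(gc$theta[i]), 0.05)
  # all normals point away from the centroid
  expect_true(all(rowSums(gc$normals * gc$X) > 0))
  # dl arithmetic: l = 30, M = 200 -> 0.15
  expect_equal(30 / 200, 0.15)
})

test_that("edge-proximity mask flags axis-aligned staircase points only", {
  # a rasterised square boundary: long flat axis-aligned runs
  m <- matrix(0L, 20, 20); m[5:15, 5:15] <- 1L
  cnt <- resample_contour(trace_boundary(m), 44L)
  flags <- edge_proximity_mask(cnt)
  expect_gt(sum(flags), 0)
  # a smooth analytic circle has no flat pixel runs
  circ <- make_shape_contour("disk", list(radius = 30), M = 100L)
  expect_equal(sum(edge_proximity_mask(circ)), 0L)
})
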