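test_that("contrast stretch maps the window endpoints to 0 and 255 and clamps", {
  f <- matrix(c(30, 100, 150, 200), 2, 2)
  g <- contrast_stretch(f, a = 100, b = 200)
  expect_equal(g[1, 1], 0)    # below the window clamps to 0
  expect_equal(g[2, 1], 0)    # f = a
  expect_equal(g[1, 2], 128)  # midpoint, rounded half away from zero
  expect_equal(g[2, 2], 255)  # f = b
  g2 <- contrast_stretch(matrix(c(0, 255, 90, 240), 2, 2), a = 100, b = 200)
  expect_equal(g2[1, 1], 0)
  expect_equal(g2[2, 1], 255) # above the window clamps to 255
  expect_error(contrast_stretch(f, a = 200, b = 100), "a < b")
})

test_that("contrast stretch is monotone and idempotent on the full window", {
  set.seed(11)
  f <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  g <- contrast_stretch(f, a = 40, b = 200)
  ord <- order(f)
  expect_true(all(diff(g[ord]) >= 0))
  expect_equal(contrast_stretch(f, a = 0, b = 255), f)
})

test_that("gaussian kernel is normalised with the expected shape", {
  K <- gaussian_kernel(5L, 7)
  expect_equal(sum(K), 1)
  expect_equal(K[1, 1] / K[3, 3], exp(-8 / (2 * 49)))
  expect_true(all(K > 0))
  expect_equal(K, t(K))
  expect_error(gaussian_kernel(4L, 7), "odd")
  expect_error(gaussian_kernel(5L, 0), "positive")
})

test_that("smoothing preserves constants and the intensity range", {
  cst <- matrix(77, 12, 15)
  expect_equal(gaussian_smooth(cst), cst)
  set.seed(3)
  f <- matrix(runif(900, 0, 255), 30, 30)
  g <- gaussian_smooth(f)
  expect_true(all(g >= min(f) - 1e-9 & g <= max(f) + 1e-9))
})

test_that("binary threshold is an inclusive cut at beta", {
  f <- matrix(c(67, 68, 69, 0), 2, 2)
  m <- binary_threshold(f, 68)
  expect_equal(as.vector(m), c(0L, 1L, 1L, 0L))
  expect_equal(binary_threshold(matrix(0, 3, 3), 68), matrix(0L, 3, 3))
})

test_that("opening removes isolated pixels and preserves solid blocks", {
  m <- matrix(0L, 7, 7); m[4, 4] <- 1L
  expect_equal(morphological_open(m), matrix(0L, 7, 7))
  sq <- matrix(0L, 9, 9); sq[3:7, 3:7] <- 1L
  expect_equal(morphological_open(sq), bf_open(sq))
  expect_equal(sum(morphological_open(sq)), 25L)
  expect_error(morphological_open(sq, c(2L, 3L)), "odd")
})

test_that("opening matches the brute-force oracle, is idempotent and anti-extensive on random masks", {
  set.seed(42)
  for (k in 1:20) {
    m <- matrix(rbinom(32 * 32, 1L, 0.5), 32, 32)
    o1 <- morphological_open(m)
    expect_equal(o1, bf_open(m))
    expect_true(all(o1 <= m))               # anti-extensive
    expect_equal(morphological_open(o1), o1) # idempotent
  }
})

test_that("opening agrees with an independent morphology library away from borders", {
  skip_if_not_installed("EBImage")
  set.seed(9)
  for (k in 1:5) {
    m <- matrix(0L, 20, 20)
    m[3:18, 3:18] <- rbinom(16 * 16, 1L, 0.45)
    ours <- morphological_open(m)
    ref <- EBImage::opening(m, EBImage::makeBrush(3, "box"))
    expect_equal(ours[2:19, 2:19], matrix(as.integer(ref), 20, 20)[2:19, 2:19])
  }
})

test_that("boundary tracing handles degenerate and small objects", {
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  cnt <- trace_boundary(m)
  expect_equal(cnt$M, 1L)
  expect_equal(unname(cnt$points[1, ]), c(2, 2))
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  cnt2 <- trace_boundary(sq)
  expect_equal(cnt2$M, 8L) # all of the 3x3 block except its centre
  expect_false(any(cnt2$points[, 1] == 2 & cnt2$points[, 2] == 2))
  expect_error(trace_boundary(matrix(0L, 4, 4)), "no foreground")
  two <- matrix(0L, 5, 5); two[1, 1] <- 1L; two[5, 5] <- 1L
  expect_error(trace_boundary(two), "multiple")
})

test_that("traced contours are closed, 8-connected, and match disk geometry", {
  for (r in c(5, 10, 20)) {
    m <- disk_mask(r)
    cnt <- trace_boundary(m)
    P <- cnt$points
    steps <- rbind(P[-1, , drop = FALSE], P[1, , drop = FALSE]) - P
    expect_true(all(abs(steps) <= 1))            # 8-adjacent incl. closure
    expect_true(all(rowSums(abs(steps)) > 0))
    expect_lt(abs(polygon_perimeter(P) / (2 * pi * r) - 1), 0.1)
    # enclosed area consistent with the pixel count to within the boundary
    expect_lt(abs(polygon_area(P) - sum(m)), cnt$M + 1)
  }
})

test_that("tracing agrees with an independent reference tracer on a disk", {
  skip_if_not_installed("EBImage")
  m <- disk_mask(20)
  ours <- trace_boundary(m)
  oc <- EBImage::ocontour(EBImage::Image(t(m)))[[1]]
  expect_equal(ours$M, nrow(oc), tolerance = 0.05)
  expect_equal(polygon_perimeter(ours$points), polygon_perimeter(oc),
               tolerance = 0.05)
})

test_that("resampling yields equal spacing and preserves the perimeter", {
  circ <- make_shape_contour("disk", list(radius = 10), M = 100L)
  seg <- sqrt(rowSums((rbind(circ$points[-1, ], circ$points[1, ]) -
                         circ$points)^2))
  expect_equal(max(seg), min(seg), tolerance = 1e-6)
  expect_equal(mean(seg), 2 * pi * 10 / 100, tolerance = 1e-3)
  # identity on an already-uniform contour
  again <- resample_contour(circ, 100L)
  expect_lt(max(abs(again$points - circ$points)), 1e-6)
  # perimeter preservation at M >= 64
  set.seed(5)
  for (k in 1:5) {
    cnt <- random_contour(M = 200L)
    rs <- resample_contour(cnt, 64L)
    expect_equal(polygon_perimeter(rs$points), polygon_perimeter(cnt$points),
                 tolerance = 5e-3)
  }
})

test_that("resampling a square to M = 4 returns the corners from the canonical start", {
  sq <- new_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  rs <- resample_contour(sq, 4L)
  # independent arc-length walk: start at the vertex with minimal positive
  # angle from the centroid ((1,1) at 45 degrees), step perimeter/4 = 1
  expect_equal(unname(rs$points),
               rbind(c(1, 1), c(0, 1), c(0, 0), c(1, 0)))
  expect_error(resample_contour(new_contour(rbind(c(0, 0), c(0, 0))), 8L))
})

test_that("contour CSV round-trips through write/read", {
  cell <- apply_affine_sequence(make_shape_contour("disk", list(radius = 8),
                                                   M = 32L),
                                list(diag(2), diag(2)),
                                list(c(1, 0), c(1, 0)), cell_id = "rt")
  path <- tempfile(fileext = ".csv")
  write_contours_csv(cell, path, hash = "deadbeef")
  back <- read_contours_csv(path)
  expect_equal(back$cell_id, "rt")
  expect_equal(length(back$contours), 3L)
  expect_equal(back$contours[[2]]$points, cell$contours[[2]]$points,
               tolerance = 1e-12)
  expect_match(readLines(path, n = 1L), "deadbeef")
})
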