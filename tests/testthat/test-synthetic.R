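test_that("shape contours are closed, sized correctly and degenerate sensibly", {
  disk <- make_shape_contour("disk", list(radius = 7), M = 256L)
  expect_equal(polygon_perimeter(disk$points), 2 * pi * 7, tolerance = 5e-3)
  expect_equal(disk$M, 256L)
  # parachute with zero concavity reduces to the disk
  para0 <- make_shape_contour("parachute",
                              list(radius = 7, concavity = 0), M = 256L)
  expect_equal(polygon_area(para0$points), polygon_area(disk$points),
               tolerance = 1e-6)
  para <- make_shape_contour("parachute",
                             list(radius = 7, concavity = 0.5), M = 256L)
  expect_lt(polygon_area(para$points), polygon_area(disk$points))
  bic <- make_shape_contour("biconcave", list(radius = 7), M = 256L)
  expect_lt(polygon_area(bic$points), pi * 49)
  expect_error(make_shape_contour("disk", list(radius = -1)), "positive")
  expect_error(make_shape_contour("parachute",
                                  list(radius = 7, concavity = 2)),
               "concavity")
})

test_that("affine sequences carry their ground truth and compose", {
  cnt <- make_shape_contour("disk", list(radius = 5), M = 32L)
  idcell <- apply_affine_sequence(cnt, list(diag(2), diag(2)),
                                  list(c(1, 0), c(1, 0)))
  # pure translation: ground-truth strain is zero
  for (Ft in attr(idcell, "F_true"))
    expect_equal(infinitesimal_strain(Ft), matrix(0, 2, 2))
  d <- idcell$contours[[2]]$points - idcell$contours[[1]]$points
  expect_equal(unname(colMeans(d)), c(1, 0), tolerance = 1e-12)
  F1 <- matrix(c(1.05, 0, 0, 0.95), 2, 2)
  F2 <- matrix(c(1, 0.02, 0, 1), 2, 2)
  cell <- apply_affine_sequence(cnt, list(F1, F2))
  # centroid-referenced two-step composition equals the direct product
  c0 <- polygon_centroid(cell$contours[[1]]$points)
  direct <- sweep(sweep(cell$contours[[1]]$points, 2, c0) %*% t(F2 %*% F1),
                  2, c0, `+`)
  # (translations are zero and centroids coincide for linear maps about them)
  expect_equal(unname(cell$contours[[3]]$points), unname(direct),
               tolerance = 1e-9)
  expect_error(apply_affine_sequence(cnt, list(matrix(0, 2, 2))), "singular")
})

test_that("manufactured fields satisfy the planted balance to machine precision", {
  for (lm in list(c(30e6, 1e6), c(170e6, 12e6), c(22e6, 0.9e6))) {
    mf <- manufacture_navier_cauchy(lm[1], lm[2])
    res <- sapply(seq_len(dim(mf$A)[3]), function(i) {
      max(abs(mf$A[, , i] %*% lm - mf$b[i, ]))
    })
    expect_lt(max(res / pmax(abs(mf$b), 1)), 1e-10)
  }
  # degenerate field with no curvature is rejected
  flat <- list(u = matrix(c(0, 1, 0, 0), 2, 2), v = matrix(0, 2, 2))
  expect_error(manufacture_navier_cauchy(1e6, 1e6, field_spec = flat),
               "curvature")
})

test_that("the quadratic example field assembles the expected constant matrix", {
  # u = (X1^2, X2^2): dG11/dX1 = 2, dG22/dX2 = 2, all others 0
  spec <- list(u = {m <- matrix(0, 3, 3); m[3, 1] <- 1; m},
               v = {m <- matrix(0, 3, 3); m[1, 3] <- 1; m})
  mf <- manufacture_navier_cauchy(30e6, 1e6, field_spec = spec)
  for (i in c(1L, 50L)) {
    expect_equal(mf$A[, , i], matrix(c(2, 2, 4, 4), 2, 2))
  }
})

test_that("rendering is deterministic and cells stay inside the lumen", {
  sc <- synthetic_scene(n_frames = 4L, noise_sd = 6, seed = 31)
  v1 <- render_video(sc)
  v2 <- render_video(sc)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$roi_track, v2$roi_track)
  v3 <- render_video(synthetic_scene(n_frames = 4L, noise_sd = 6, seed = 32))
  expect_false(identical(v1$frames, v3$frames))
  expect_true(all(sapply(v1$frames, function(f) all(f >= 0 & f <= 255))))
  expect_error(render_video(synthetic_scene(radius_um = 50)), "fit")
})

test_that("extraction recovers the rendered ground truth", {
  sc <- synthetic_scene(n_frames = 10L, noise_sd = 0, seed = 12)
  v <- render_video(sc)
  cell <- extract_cell_sequence(v$frames, v$roi_track,
                                scene_contour_params(sc),
                                sc$pixel_size_um, sc$dt_s, "gt")
  cents <- t(sapply(cell$contours, function(cnt)
    polygon_centroid(cnt$points)))
  expect_lt(max(abs(cents - v$truth$centroids)), 0.5)
  steps <- diff(cents[, 1])
  expect_equal(mean(steps), sc$velocity_px, tolerance = 0.05)
  # noisy rendering: extracted areas stay within 5% of the truth
  scn <- synthetic_scene(n_frames = 10L, noise_sd = 4, seed = 13)
  vn <- render_video(scn)
  celln <- extract_cell_sequence(vn$frames, vn$roi_track,
                                 scene_contour_params(scn),
                                 scn$pixel_size_um, scn$dt_s, "gtn")
  a_true <- sapply(vn$truth$contours, function(cnt) polygon_area(cnt$points))
  a_ext <- sapply(celln$contours, function(cnt) polygon_area(cnt$points))
  expect_lt(max(abs(a_ext / a_true - 1)), 0.05)
})

test_that("the pipeline survives heavy noise on nearly all frames", {
  sc <- synthetic_scene(n_frames = 20L, noise_sd = 8, seed = 77)
  v <- render_video(sc)
  ok <- 0L
  for (k in seq_along(v$frames)) {
    res <- tryCatch({
      cell <- extract_cell_sequence(v$frames[k],
                                    transform(v$roi_track[k, ], frame = 0L),
                                    scene_contour_params(sc, M = 100L),
                                    sc$pixel_size_um, sc$dt_s, "n")
      cell$contours[[1]]$M == 100L
    }, error = function(e) FALSE)
    if (isTRUE(res)) ok <- ok + 1L
  }
  expect_gte(ok / length(v$frames), 0.95)
})

test_that("synthetic feature populations are reproducible and correctly planted", {
  p1 <- synthetic_feature_populations(n_base = 20, n_out = 5, offset_sd = 8,
                                      seed = 44)
  p2 <- synthetic_feature_populations(n_base = 20, n_out = 5, offset_sd = 8,
                                      seed = 44)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$baseline), 20L)
  expect_equal(sum(p1$truth), 5L)
  # null case: no planted offset means test cells look like baseline
  p0 <- synthetic_feature_populations(n_base = 200, n_out = 0, offset_sd = 0,
                                      seed = 45, n_in = 200)
  expect_lt(abs(mean(p0$test$lambda_Pa) / mean(p0$baseline$lambda_Pa) - 1),
            0.1)
  expect_error(synthetic_feature_populations(n_base = 2), "n_base")
})

test_that("TIFF stacks round-trip through write/read", {
  sc <- synthetic_scene(n_frames = 3L, noise_sd = 2, seed = 8)
  v <- render_video(sc)
  path <- tempfile(fileext = ".tif")
  write_video_tiff(v, path)
  back <- read_video_tiff(path)
  expect_equal(length(back), 3L)
  expect_equal(back[[2]], v$frames[[2]])
})
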