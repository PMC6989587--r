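#' Parametric cell-shape contours
#'
#' Generates closed, non-self-intersecting contours for the shapes seen
#' in capillary plug flow: a disk, a biconcave resting profile (classic
#' dumbbell cross-section), and a parachute with a trailing concavity.
#' Points are returned at equal arc-length spacing.
#'
#' @param kind `"disk"`, `"biconcave"` or `"parachute"`.
#' @param params named list: `radius` (all kinds); `concavity` in
#'   `[0, 0.95]` and `width` (angular, radians) for `"parachute"`;
#'   `c0`, `c2`, `c4` profile coefficients for `"biconcave"`.
#' @param M number of contour points.
#' @return an `rbc_contour` with `M` points.
#' @export
make_shape_contour <- function(kind = c("disk", "biconcave", "parachute"),
                               params = list(radius = 4), M = 200L) {
  kind <- match.arg(kind)
  R <- params$radius %||% 4
  if (R <= 0) stop("radius must be positive", call. = FALSE)
  t <- 2 * pi * (seq_len(4L * M) - 1L) / (4L * M)
  if (kind == "disk") {
    P <- cbind(R * cos(t), R * sin(t))
  } else if (kind == "parachute") {
    depth <- params$concavity %||% 0.4
    if (depth < 0 || depth > 0.95)
      stop("parachute concavity must lie in [0, 0.95]", call. = FALSE)
    width <- params$width %||% 0.8
    r <- R * (1 - depth * exp(-((t - pi) %% (2 * pi) - pi)^2 /
                                (2 * width^2)))
    # dimple centred on the trailing (upstream, -x) side
    ang <- t + pi
    P <- cbind(r * cos(ang), r * sin(ang))
  } else {
    c0 <- params$c0 %||% 0.207
    c2 <- params$c2 %||% 2.002
    c4 <- params$c4 %||% -1.122
    xs <- cos(t)
    half <- 0.5 * sqrt(pmax(1 - xs^2, 0)) * (c0 + c2 * xs^2 + c4 * xs^4)
    if (any(half < 0))
      stop("biconcave profile parameters self-intersect", call. = FALSE)
    P <- cbind(R * xs, R * sign(sin(t)) * half)
  }
  resample_contour(new_contour(P), M)
}

#' Apply a sequence of affine deformations to a contour
#'
#' Builds a ground-truth tracked cell: frame `j` points are
#' `F_j (P_{j-1} - centroid_{j-1}) + centroid_{j-1} + translation_j`.
#' The applied gradients are stored alongside, so the kinematics
#' estimator can be checked against exact truth.
#'
#' @param contour starting `rbc_contour`.
#' @param F_list list of invertible 2x2 matrices (one per step).
#' @param translations list (or n x 2 matrix) of per-step translation
#'   vectors; defaults to zero.
#' @param pixel_size_um,dt_s physical scale for the resulting cell.
#' @param cell_id identifier.
#' @return a `tracked_cell` with attribute `F_true` (the list of applied
#'   gradients).
#' @export
apply_affine_sequence <- function(contour, F_list, translations = NULL,
                                  pixel_size_um = 1, dt_s = 1e-3,
                                  cell_id = "affine") {
  n <- length(F_list)
  if (is.null(translations)) translations <- matrix(0, n, 2L)
  if (is.list(translations)) translations <- do.call(rbind, translations)
  contours <- vector("list", n + 1L)
  contours[[1L]] <- new_contour(contour$points, 0L)
  P <- contour$points
  for (j in seq_len(n)) {
    Fj <- F_list[[j]]
    if (abs(det(Fj)) < 1e-12)
      stop(sprintf("step %d: singular deformation gradient", j),
           call. = FALSE)
    ctr <- polygon_centroid(P)
    P <- sweep(sweep(P, 2L, ctr) %*% t(Fj), 2L, ctr + translations[j, ], `+`)
    contours[[j + 1L]] <- new_contour(P, j)
  }
  cell <- new_tracked_cell(contours, pixel_size_um, dt_s, cell_id)
  attr(cell, "F_true") <- F_list
  cell
}

#' Default polynomial displacement field for manufactured solutions
#'
#' A quadratic displacement field with mixed terms, chosen so the
#' assembled per-point coefficient matrix is constant, nonsingular and
#' exercises every displacement-gradient derivative entering the
#' Navier-Cauchy system.
#'
#' @return list with poly2d coefficient matrices `u` and `v`
#'   (`C[p+1, q+1]` multiplies `X1^p X2^q`).
#' @export
default_field_spec <- function() {
  u <- matrix(0, 3, 3)
  u[3, 1] <- 1.0    # X1^2
  u[2, 2] <- 0.5    # X1 X2
  u[1, 3] <- 0.2    # X2^2
  v <- matrix(0, 3, 3)
  v[3, 1] <- 0.3
  v[2, 2] <- -0.4
  v[1, 3] <- 0.6
  list(u = u, v = v)
}

#' Manufacture a Navier-Cauchy field with planted Lame constants
#'
#' Runs the momentum balance forward: a chosen polynomial displacement
#' field is differentiated analytically to give the displacement
#' gradient `G` and its spatial derivatives at the contour points, and
#' the right-hand side is *constructed* as `b = A (lambda*, mu*)'` so the
#' planted constants satisfy every per-point system exactly. The
#' returned object can be fed directly to [solve_lame()] (analytic
#' route) or re-derived through [gradient_on_contour()] from the sampled
#' `G` values (discretisation route).
#'
#' @param lambda_star,mu_star planted Lame constants (Pa).
#' @param field_spec list with poly2d matrices `u`, `v` (degree >= 2);
#'   see [default_field_spec()].
#' @param contour evaluation contour (`rbc_contour`, coordinates in the
#'   field's length unit).
#' @return object of class `manufactured_field`: per-point `A`
#'   (2 x 2 x M), `b` (M x 2), sampled `G` components (M x 4 matrix with
#'   columns G11, G12, G21, G22), analytic derivative list `dG`,
#'   `geom`, and the planted constants.
#' @export
manufacture_navier_cauchy <- function(lambda_star, mu_star,
                                      field_spec = default_field_spec(),
                                      contour = make_shape_contour("disk")) {
  if (lambda_star + mu_star <= 0)
    stop("lambda* + mu* must be positive", call. = FALSE)
  geom <- contour_geometry(contour)
  X1 <- geom$X[, 1L]
  X2 <- geom$X[, 2L]
  u <- field_spec$u
  v <- field_spec$v
  # displacement gradient components as polynomials
  G11 <- poly2d_deriv(u, 1L); G12 <- poly2d_deriv(u, 2L)
  G21 <- poly2d_deriv(v, 1L); G22 <- poly2d_deriv(v, 2L)
  dG <- list(dG11_d1 = poly2d_eval(poly2d_deriv(G11, 1L), X1, X2),
             dG11_d2 = poly2d_eval(poly2d_deriv(G11, 2L), X1, X2),
             dG12_d2 = poly2d_eval(poly2d_deriv(G12, 2L), X1, X2),
             dG21_d1 = poly2d_eval(poly2d_deriv(G21, 1L), X1, X2),
             dG22_d1 = poly2d_eval(poly2d_deriv(G22, 1L), X1, X2),
             dG22_d2 = poly2d_eval(poly2d_deriv(G22, 2L), X1, X2))
  M <- geom$M
  A <- array(NA_real_, c(2L, 2L, M))
  A[1, 1, ] <- dG$dG11_d1 + dG$dG22_d1
  A[1, 2, ] <- 2 * dG$dG11_d1 + dG$dG22_d1 + dG$dG12_d2
  A[2, 1, ] <- dG$dG22_d2 + dG$dG11_d2
  A[2, 2, ] <- 2 * dG$dG22_d2 + dG$dG11_d2 + dG$dG21_d1
  if (all(abs(A) < 1e-14))
    stop("field has no curvature: assembled systems are identically zero",
         call. = FALSE)
  b <- cbind(A[1, 1, ] * lambda_star + A[1, 2, ] * mu_star,
             A[2, 1, ] * lambda_star + A[2, 2, ] * mu_star)
  Gvals <- cbind(G11 = poly2d_eval(G11, X1, X2),
                 G12 = poly2d_eval(G12, X1, X2),
                 G21 = poly2d_eval(G21, X1, X2),
                 G22 = poly2d_eval(G22, X1, X2))
  structure(list(A = A, b = b, G = Gvals, dG = dG, geom = geom,
                 lambda_star = lambda_star, mu_star = mu_star,
                 field_spec = field_spec),
            class = "manufactured_field")
}

#' Synthetic plug-flow scene description
#'
#' Parameters of the rendered capillary scene. The defaults emulate a
#' high-frame-rate transillumination recording: a dark cell (intensity
#' 40) on a bright plasma background (180) between darker capillary
#' walls (120), sampled at 1/15 um per pixel so a 4-um-radius cell spans
#' 60 px, 1 ms between frames, Gaussian intensity noise of SD 4.
#'
#' @param shape shape kind for [make_shape_contour()].
#' @param radius_um cell radius (um).
#' @param n_frames number of frames.
#' @param width,height frame size in pixels.
#' @param velocity_px per-frame translation along the flow (+x) axis.
#' @param deform_amp,deform_period amplitude and period (frames) of an
#'   area-preserving elliptical pulsation: the x scale oscillates as
#'   `1 + deform_amp * sin(2 pi t / deform_period)` with the y scale its
#'   reciprocal.
#' @param wall_gap_px lumen clearance between cell and each wall.
#' @param noise_sd Gaussian intensity noise SD (8-bit counts).
#' @param bg,fg,wall background / cell / wall intensities.
#' @param pixel_size_um micrometres per pixel.
#' @param dt_s inter-frame interval (s).
#' @param roi_margin_px margin added around the true contour to form the
#'   tracked ROI.
#' @param seed RNG seed; identical seeds give bit-identical stacks.
#' @return list of class `synthetic_scene`.
#' @export
synthetic_scene <- function(shape = "disk", radius_um = 4, n_frames = 50L,
                            width = 256L, height = 160L, velocity_px = 1,
                            deform_amp = 0.03, deform_period = 20,
                            wall_gap_px = 6, noise_sd = 4, bg = 180,
                            fg = 40, wall = 120, pixel_size_um = 1 / 15,
                            dt_s = 1e-3, roi_margin_px = 8L, seed = 1L) {
  structure(list(shape = shape, radius_um = radius_um,
                 n_frames = as.integer(n_frames), width = as.integer(width),
                 height = as.integer(height), velocity_px = velocity_px,
                 deform_amp = deform_amp, deform_period = deform_period,
                 wall_gap_px = wall_gap_px, noise_sd = noise_sd, bg = bg,
                 fg = fg, wall = wall, pixel_size_um = pixel_size_um,
                 dt_s = dt_s, roi_margin_px = as.integer(roi_margin_px),
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

# Even-odd rasterisation of a polygon onto pixel centres of a bounding
# window; returns matrix row/col indices of interior pixels.
rasterize_polygon <- function(P, nr, nc) {
  # pixel centre (row r, col c) -> Cartesian (x = c - 1, y = nr - r)
  xmin <- max(1L, floor(min(P[, 1L])) - 1L)
  xmax <- min(nc, ceiling(max(P[, 1L])) + 2L)
  rmin <- max(1L, nr - ceiling(max(P[, 2L])) - 1L)
  rmax <- min(nr, nr - floor(min(P[, 2L])) + 1L)
  if (xmin > xmax || rmin > rmax) return(NULL)
  cols <- xmin:xmax
  rows <- rmin:rmax
  px <- rep(cols - 1, each = length(rows))
  py <- rep(nr - rows, times = length(cols))
  inside <- rep(FALSE, length(px))
  n <- nrow(P)
  j <- n
  for (i in seq_len(n)) {
    xi <- P[i, 1L]; yi <- P[i, 2L]
    xj <- P[j, 1L]; yj <- P[j, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & (yj != yi))
    j <- i
  }
  if (!any(inside)) return(NULL)
  cbind(row = rep(rows, times = length(cols))[inside],
        col = rep(cols, each = length(rows))[inside])
}

#' Render a synthetic plug-flow image stack with ground truth
#'
#' Rasterises the translating, pulsating cell into 8-bit grayscale
#' frames with capillary walls and additive Gaussian noise (clamped to
#' `[0, 255]`), and emits the exact ground truth alongside: the true
#' contour polygon, centroid per frame, and a tracked-ROI table in the
#' dialect of [extract_cell_sequence()].
#'
#' @param scene a [synthetic_scene()].
#' @return list with `frames` (list of matrices), `truth` (list with
#'   per-frame `contours`, `centroids` matrix), `roi_track` data frame,
#'   and `scene`.
#' @export
render_video <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  R_px <- scene$radius_um / scene$pixel_size_um
  nr <- scene$height; nc <- scene$width
  lumen_half <- R_px + scene$wall_gap_px
  cy <- nr / 2
  if (2 * R_px + 2 > nr || 2 * R_px + 2 > nc)
    stop("cell does not fit inside the frame", call. = FALSE)
  base <- make_shape_contour(scene$shape, list(radius = R_px), M = 128L)
  with_seed(scene$seed, {
    frames <- vector("list", scene$n_frames)
    contours <- vector("list", scene$n_frames)
    cents <- matrix(NA_real_, scene$n_frames, 2L)
    roi <- vector("list", scene$n_frames)
    x0 <- R_px + 4
    for (k in seq_len(scene$n_frames)) {
      tfrm <- k - 1L
      sx <- 1 + scene$deform_amp * sin(2 * pi * tfrm / scene$deform_period)
      sy <- 1 / sx
      ctr <- c(x0 + scene$velocity_px * tfrm, cy)
      P <- cbind(base$points[, 1L] * sx + ctr[1L],
                 base$points[, 2L] * sy + ctr[2L])
      if (max(P[, 1L]) > nc - 2)
        stop("cell translated outside the frame; reduce n_frames or ",
             "velocity", call. = FALSE)
      img <- matrix(scene$bg, nr, nc)
      wall_rows_top <- seq_len(max(0L, floor(cy - lumen_half)))
      wall_rows_bot <- seq(min(nr, ceiling(cy + lumen_half)), nr)
      img[wall_rows_top, ] <- scene$wall
      img[wall_rows_bot, ] <- scene$wall
      pix <- rasterize_polygon(P, nr, nc)
      if (!is.null(pix)) img[pix] <- scene$fg
      if (scene$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(nr * nc, 0, scene$noise_sd), nr, nc)
      }
      img <- floor(pmin(pmax(img, 0), 255) + 0.5)
      frames[[k]] <- img
      contours[[k]] <- new_contour(P, tfrm)
      cents[k, ] <- polygon_centroid(P)
      m <- scene$roi_margin_px
      y_lo <- max(ceiling(cy - lumen_half) + 1, floor(min(P[, 2L])) - m)
      y_hi <- min(floor(cy + lumen_half) - 1, ceiling(max(P[, 2L])) + m)
      roi[[k]] <- data.frame(frame = tfrm,
                             x_min = max(0L, floor(min(P[, 1L])) - m),
                             y_min = y_lo,
                             x_max = min(nc - 1L, ceiling(max(P[, 1L])) + m),
                             y_max = y_hi,
                             cell_id = "synthetic")
    }
    list(frames = frames,
         truth = list(contours = contours, centroids = cents),
         roi_track = do.call(rbind, roi), scene = scene)
  })
}

#' Segmentation parameters calibrated to a synthetic scene
#'
#' The automatic contrast window `[mu - sigma, mu]` assumes the cell
#' occupies a modest fraction of the ROI; in tightly cropped synthetic
#' scenes the cell dominates the histogram and the window collapses onto
#' the cell intensity. For rendered scenes the foreground intensity is
#' known exactly, so the window `[fg, 255]` is used instead: the cell
#' interior clamps to 0, the background stays far above the binary
#' threshold, and the traced boundary lands within half a pixel of the
#' true edge. This mirrors the empirical per-recording calibration used
#' on real microscopy.
#'
#' @param scene a [synthetic_scene()].
#' @param ... further arguments passed to [contour_params()].
#' @return a [contour_params()] list.
#' @export
scene_contour_params <- function(scene, ...) {
  contour_params(a = scene$fg, b = 255, ...)
}

#' Write a rendered stack as a multi-page 8-bit TIFF
#'
#' @param video output of [render_video()].
#' @param path TIFF path.
#' @return `path` invisibly.
#' @export
write_video_tiff <- function(video, path) {
  imgs <- lapply(video$frames, function(f) f / 255)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit grayscale stack (multi-page TIFF)
#'
#' @param path TIFF path.
#' @return list of intensity matrices in `[0, 255]`.
#' @export
read_video_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1L]
    round(f * 255)
  })
}

#' Synthetic two-population mechanical feature sets
#'
#' Draws a baseline population from a correlated six-feature Gaussian
#' calibrated to healthy-cell scales (tens of MPa for `lambda` and `K`,
#' ~1 MPa for `mu`, a few MPa for `E`, ~1 Pa wall shear stress, ~0.05
#' shear strain) and a planted outlier population shifted by `offset_sd`
#' baseline standard deviations along each of the two leading principal
#' axes of the *realized* baseline sample. Planting relative to the
#' sample (rather than the generating covariance) makes the offset
#' meaningful in the same coordinates any baseline-derived outlier rule
#' operates in: with a finite baseline the estimated principal axes
#' rotate away from the population ones, and an offset defined against
#' the population axes would partially leak between components. True
#' labels are returned for sensitivity/specificity checks.
#'
#' The test set mixes `n_in` fresh in-distribution cells (for
#' specificity) with `n_out` shifted cells (for sensitivity).
#'
#' @param n_base,n_out baseline / outlier cell counts.
#' @param offset_sd planted shift in baseline-SD units (0 = null case).
#' @param seed RNG seed.
#' @param n_in fresh in-distribution cells included in the test set.
#' @return list with `baseline`, `test` (feature data frames) and
#'   `truth` (logical: is each test cell a planted outlier).
#' @export
synthetic_feature_populations <- function(n_base = 32L, n_out = 11L,
                                          offset_sd = 6, seed = 1L,
                                          n_in = 24L) {
  if (n_base < 3L) stop("n_base must be >= 3", call. = FALSE)
  if (offset_sd < 0) stop("offset_sd must be >= 0", call. = FALSE)
  mu0 <- c(35e6, 1.1e6, 3.3e6, 36e6, 1.0, 0.05)
  sd0 <- c(8e6, 0.2e6, 0.6e6, 8e6, 0.25, 0.012)
  # correlation: stiffness features strongly co-vary; stress/strain mildly
  R <- diag(6)
  stiff <- 1:4
  R[stiff, stiff] <- 0.8
  diag(R) <- 1
  R[5, 6] <- R[6, 5] <- 0.3
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  with_seed(seed, {
    draw <- function(n, shift = NULL) {
      z <- matrix(stats::rnorm(n * 6L), n, 6L) %*% t(L)
      if (!is.null(shift)) z <- sweep(z, 2L, shift, `+`)
      m <- sweep(sweep(z, 2L, sd0, `*`), 2L, mu0, `+`)
      colnames(m) <- feature_columns
      m
    }
    base <- draw(n_base)
    # plant the offset along the two leading principal axes of the
    # realized baseline sample (z-scored with its own mean and SD)
    zb <- scale(sweep(sweep(base, 2L, mu0), 2L, sd0, `/`))
    pc <- stats::prcomp(zb, center = FALSE, scale. = FALSE)
    shift_zb <- offset_sd * (pc$sdev[1L] * pc$rotation[, 1L] +
                               pc$sdev[2L] * pc$rotation[, 2L])
    # back from sample-z units to the generator's z units
    shift_z <- shift_zb * attr(zb, "scaled:scale")
    shift_z0 <- attr(zb, "scaled:center")
    n_test <- n_in + n_out
    test_m <- matrix(numeric(0), 0L, 6L,
                     dimnames = list(NULL, feature_columns))
    if (n_test > 0L)
      test_m <- rbind(if (n_in > 0L) draw(n_in),
                      if (n_out > 0L) draw(n_out, shift_z0 + shift_z))
    truth <- c(rep(FALSE, n_in), rep(TRUE, n_out))
    baseline <- data.frame(cell_id = sprintf("NC%03d", seq_len(n_base)),
                           base, check.names = FALSE)
    test <- data.frame(cell_id = sprintf("TX%03d", seq_len(n_test)),
                       test_m, check.names = FALSE)
    list(baseline = baseline, test = test, truth = truth)
  })
}
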