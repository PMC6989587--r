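#' Cubic-spline cluster weighting function
#'
#' The compactly supported cubic spline used to weight cluster neighbours
#' in the discrete deformation-gradient and contour-gradient estimators:
#' \deqn{w(r) = 1 - 6r^2 + 6r^3 \ (r \le 1/2);\quad
#'       2 - 6r + 6r^2 - 2r^3 \ (1/2 < r < 1);\quad 0 \ (r \ge 1)}
#' It is continuous with continuous first derivative, equals 1 at `r = 0`
#' and vanishes for `r >= 1`.
#'
#' @param r non-negative adjusted radius (dimensionless).
#' @return weight in `[0, 1]`, vectorised over `r`.
#' @export
#' @examples
#' spline_weight(c(0, 0.5, 1))
spline_weight <- function(r) {
  if (any(r < 0)) stop("adjusted radius must be non-negative", call. = FALSE)
  w <- numeric(length(r))
  lo <- r <= 0.5
  mid <- r > 0.5 & r < 1
  w[lo] <- 1 - 6 * r[lo]^2 + 6 * r[lo]^3
  w[mid] <- 2 - 6 * r[mid] + 6 * r[mid]^2 - 2 * r[mid]^3
  w
}

# Adjusted cluster radii for point i: r = (r_gl - r_g1) / r_cut, where
# r_g1 is the distance to the nearest neighbour (which therefore has
# weight 1) and r_cut the cutoff radius.
cluster_weights <- function(d, r_cut) {
  r_g1 <- min(d)
  spline_weight(pmax(d - r_g1, 0) / r_cut)
}

#' Discrete deformation-gradient field between two corresponding contours
#'
#' Estimates the per-point 2x2 deformation gradient `F` mapping the
#' reference contour onto the current contour by weighted cluster least
#' squares. For each point the relative vectors to every other contour
#' point are formed in both configurations and
#' `F = A D^{-1}` with `A = sum w dx dX'`, `D = sum w dX dX'`, the weights
#' coming from [spline_weight()] on the adjusted radius. A large default
#' cutoff (half the contour diameter) keeps the cluster wide, which
#' absorbs membrane treadmilling and the residual point-correspondence
#' error of arc-length resampling. The estimator is exact for affine
#' motions regardless of the weighting.
#'
#' Points whose moment matrix `D` is ill-conditioned (condition number
#' above `cond_cutoff`) and points listed in `exclude` are marked invalid.
#'
#' @param ref,cur `rbc_contour` objects with identical `M` and point
#'   correspondence (`cur` deformed state, `ref` previous frame).
#' @param r_cut cutoff radius in contour length units; `NULL` uses half
#'   the reference contour diameter.
#' @param cond_cutoff condition-number guard for inverting `D`.
#' @param exclude optional logical vector of points to mark invalid (e.g.
#'   from [edge_proximity_mask()]).
#' @return object of class `deformation_field`: list with `F` and `G`
#'   (2 x 2 x M arrays, `G = F - I`) and `valid` (logical M-vector).
#' @export
deformation_gradient_field <- function(ref, cur, r_cut = NULL,
                                       cond_cutoff = 1e8, exclude = NULL) {
  stopifnot(inherits(ref, "rbc_contour"), inherits(cur, "rbc_contour"))
  X <- ref$points; x <- cur$points
  M <- nrow(X)
  if (nrow(x) != M)
    stop("contours must share the same number of points", call. = FALSE)
  if (is.null(r_cut)) r_cut <- contour_diameter(X) / 2
  if (r_cut <= 0) stop("r_cut must be positive", call. = FALSE)
  Farr <- array(NA_real_, c(2L, 2L, M))
  valid <- rep(FALSE, M)
  for (i in seq_len(M)) {
    dX <- sweep(X[-i, , drop = FALSE], 2L, X[i, ])
    dx <- sweep(x[-i, , drop = FALSE], 2L, x[i, ])
    d <- sqrt(rowSums(dX^2))
    w <- cluster_weights(d, r_cut)
    keep <- w > 0
    if (sum(keep) < 2L) next
    sw <- sqrt(w[keep])
    A <- crossprod(dx[keep, , drop = FALSE] * sw,
                   dX[keep, , drop = FALSE] * sw)
    D <- crossprod(dX[keep, , drop = FALSE] * sw)
    Dinv <- solve_2x2(D, cond_cutoff)
    if (is.null(Dinv)) next
    Farr[, , i] <- A %*% Dinv
    valid[i] <- TRUE
  }
  if (!is.null(exclude)) valid <- valid & !exclude
  G <- Farr
  G[1, 1, ] <- Farr[1, 1, ] - 1
  G[2, 2, ] <- Farr[2, 2, ] - 1
  structure(list(F = Farr, G = G, valid = valid, r_cut = r_cut),
            class = "deformation_field")
}

contour_diameter <- function(P) {
  rng_x <- range(P[, 1L]); rng_y <- range(P[, 2L])
  sqrt(diff(rng_x)^2 + diff(rng_y)^2)
}

#' Flag contour points near axis-aligned pixelation artefacts
#'
#' Binary segmentation quantises the membrane into pixel runs; where the
#' boundary is locally flat and axis-aligned the traced contour carries
#' staircase discontinuities that corrupt local gradient estimates. A
#' point is flagged when its outward normal lies within `tol_deg` of an
#' image axis *and* one of its coordinates is exactly constant over a
#' neighbourhood spanning at least `run_px` pixels of arc length. Pixel
#' staircases (and points resampled along them) have exactly constant
#' rows or columns, while a genuinely curved boundary always carries a
#' residual coordinate spread, so smooth contours are never flagged.
#'
#' @param contour an `rbc_contour` in pixel units.
#' @param geom optional precomputed [contour_geometry()] record.
#' @param tol_deg angular tolerance around the axes, degrees.
#' @param run_px minimum axis-aligned run length, pixels.
#' @return logical vector, `TRUE` where the point should be ignored.
#' @export
edge_proximity_mask <- function(contour, geom = NULL, tol_deg = 5,
                                run_px = 3) {
  if (is.null(geom)) geom <- contour_geometry(contour)
  th <- geom$theta %% (pi / 2)
  near_axis <- pmin(th, pi / 2 - th) < tol_deg * pi / 180
  P <- contour$points
  M <- nrow(P)
  half <- max(1L, ceiling((run_px / 2) / geom$dl))
  flat <- vapply(seq_len(M), function(i) {
    idx <- ((i - 1L + seq(-half, half)) %% M) + 1L
    seg <- P[idx, , drop = FALSE]
    diff(range(seg[, 1L])) < 1e-6 || diff(range(seg[, 2L])) < 1e-6
  }, logical(1))
  near_axis & flat
}

#' Infinitesimal strain from a deformation gradient
#'
#' `eps = (F + F') / 2 - I`, the symmetric small-strain tensor.
#'
#' @param F 2x2 matrix or 2 x 2 x M array of deformation gradients.
#' @return tensor(s) of the same shape, exactly symmetric.
#' @export
infinitesimal_strain <- function(F) {
  if (is.matrix(F)) return((F + t(F)) / 2 - diag(2))
  out <- F
  out[1, 1, ] <- F[1, 1, ] - 1
  out[2, 2, ] <- F[2, 2, ] - 1
  off <- (F[1, 2, ] + F[2, 1, ]) / 2
  out[1, 2, ] <- off
  out[2, 1, ] <- off
  out
}

#' Viscoelastic- and geometry-adjusted membrane strain
#'
#' The raw image-plane strain overstates the elastic strain of the
#' membrane: the membrane behaves as a Maxwell material over the imaging
#' interval, so only a fraction `beta_e` (default 0.1) of the total
#' strain is elastic, and the tracked contour represents a membrane
#' ribbon of thickness `w_n` and length `l` rather than the full
#' projected cell area `A_cell`. The adjusted strain is
#' `eps = beta_e * (w_n * l / A_cell) * eps_raw`.
#'
#' All three geometric quantities must share one length unit.
#'
#' @param eps_raw 2x2 matrix or 2 x 2 x M array of raw strain.
#' @param beta_e elastic fraction in `(0, 1]`.
#' @param w_n membrane thickness (default 5 nm, in metres -- pass
#'   consistently with `l` and `A_cell`).
#' @param l cell perimeter.
#' @param A_cell projected cell area.
#' @return list with `eps` (adjusted), `eps_raw`, `scale`, and the inputs.
#' @export
adjusted_strain <- function(eps_raw, beta_e = 0.1, w_n = 5e-9, l, A_cell) {
  if (beta_e <= 0 || beta_e > 1)
    stop("beta_e must lie in (0, 1]", call. = FALSE)
  if (w_n <= 0 || l <= 0) stop("w_n and l must be positive", call. = FALSE)
  if (A_cell <= 0) stop("cell area must be positive", call. = FALSE)
  scale <- beta_e * w_n * l / A_cell
  list(eps = eps_raw * scale, eps_raw = eps_raw, scale = scale,
       beta_e = beta_e, w_n = w_n, l = l, A_cell = A_cell)
}

#' Geometric summary of a closed membrane contour
#'
#' Computes the quantities the mechanics modules need from one contour:
#' perimeter `l`, enclosed area `A_cell` (shoelace formula, absolute
#' value), the area centroid (taken as the coordinate origin for all
#' force balances), the outward unit-normal angle `theta` per point
#' (measured from the `+x` flow axis, in `[0, 2pi)`), the arc-length
#' element `dl = l / M`, and centroid-centred coordinates `X1`, `X2`.
#'
#' @param contour an `rbc_contour`.
#' @param pixel_size length of one pixel in the desired output unit
#'   (e.g. `1e-6 * pixel_size_um` for metres); contour coordinates are
#'   multiplied by it.
#' @return list with `l`, `A_cell`, `centroid`, `theta`, `normals`,
#'   `dl`, `X` (M x 2 centred coordinates), `M`.
#' @export
contour_geometry <- function(contour, pixel_size = 1) {
  stopifnot(inherits(contour, "rbc_contour"))
  P <- contour$points * pixel_size
  M <- nrow(P)
  if (M < 3L) stop("contour geometry needs at least 3 points", call. = FALSE)
  A <- abs(shoelace_area_signed(P))
  nxt <- c(seq_len(M)[-1L], 1L)
  l <- sum(sqrt(rowSums((P[nxt, , drop = FALSE] - P)^2)))
  ctr <- polygon_centroid(P)
  X <- sweep(P, 2L, ctr)
  prv <- c(M, seq_len(M)[-M])
  tangent <- P[nxt, , drop = FALSE] - P[prv, , drop = FALSE]
  tl <- sqrt(rowSums(tangent^2))
  tl[tl == 0] <- 1
  tangent <- tangent / tl
  # two normal candidates; keep the one pointing away from the centroid
  n1 <- cbind(tangent[, 2L], -tangent[, 1L])
  outward <- rowSums(n1 * X) >= 0
  normals <- n1
  normals[!outward, ] <- -n1[!outward, , drop = FALSE]
  theta <- atan2(normals[, 2L], normals[, 1L]) %% (2 * pi)
  list(l = l, A_cell = A, centroid = ctr, theta = theta, normals = normals,
       dl = l / M, X = X, M = M)
}
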