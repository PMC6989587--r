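#' Contrast stretching of an 8-bit grayscale frame
#'
#' Linearly maps the intensity window `[a, b]` onto the full 8-bit range
#' `[0, 255]`, clamping values that fall outside. By default the window is
#' `[mu - sigma, mu]` where `mu` and `sigma` are the mean and standard
#' deviation of the frame histogram: in bright-field capillary recordings
#' the cell interior sits well below `mu - sigma` while the plasma
#' background sits at or above `mu`, so this window pushes the cell to 0
#' and the background to 255.
#'
#' Values are rounded half-away-from-zero back to integers so the output
#' remains a valid 8-bit frame.
#'
#' @param frame numeric matrix of intensities in `[0, 255]`.
#' @param a,b lower/upper window bound; `NULL` uses `mean(frame) - sd(frame)`
#'   and `mean(frame)`.
#' @return matrix of stretched intensities (integers in `[0, 255]`).
#' @export
#' @examples
#' f <- matrix(c(10, 100, 200, 255), 2, 2)
#' contrast_stretch(f, a = 100, b = 200)
contrast_stretch <- function(frame, a = NULL, b = NULL) {
  stopifnot(is.matrix(frame))
  if (is.null(a)) a <- mean(frame) - stats::sd(frame)
  if (is.null(b)) b <- mean(frame)
  if (a >= b) stop("contrast window requires a < b", call. = FALSE)
  s <- 255 * (frame - a) / (b - a)
  s <- pmin(pmax(s, 0), 255)
  floor(s + 0.5)
}

#' Gaussian smoothing kernel
#'
#' Builds the discrete Gaussian kernel
#' `G(x, y) = exp(-(x^2 + y^2) / (2 sigma^2)) / (2 pi sigma^2)`
#' sampled at integer offsets and normalised to unit sum, so smoothing
#' never changes the mean intensity.
#'
#' @param kernel_size odd kernel width in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @return `kernel_size x kernel_size` matrix summing to 1.
#' @export
gaussian_kernel <- function(kernel_size = 5L, sigma = 7) {
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("kernel_size must be a positive odd integer", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  h <- (kernel_size - 1L) / 2L
  off <- seq(-h, h)
  L <- outer(off, off, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  L / sum(L)
}

#' Gaussian smoothing of a frame
#'
#' Convolves the frame with the unit-sum kernel of [gaussian_kernel()].
#' The image border is reflect-padded, so a constant frame is returned
#' unchanged and no dark rim is introduced near region-of-interest edges
#' (which would otherwise corrupt the downstream threshold).
#'
#' @inheritParams contrast_stretch
#' @inheritParams gaussian_kernel
#' @return smoothed frame (real-valued; thresholding does not require
#'   re-quantisation).
#' @export
gaussian_smooth <- function(frame, kernel_size = 5L, sigma = 7) {
  K <- gaussian_kernel(kernel_size, sigma)
  h <- (kernel_size - 1L) / 2L
  nr <- nrow(frame); nc <- ncol(frame)
  ridx <- reflect_index(nr, h)
  cidx <- reflect_index(nc, h)
  P <- frame[ridx, cidx, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(kernel_size)) {
    for (j in seq_len(kernel_size)) {
      out <- out + K[i, j] * P[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
    }
  }
  out
}

# Reflected index vector for pad width h over n samples: (h..1, 1..n, n..n-h+1)
reflect_index <- function(n, h) {
  if (h == 0L) return(seq_len(n))
  c(pmin(rev(seq_len(h)), n), seq_len(n), pmax(n - seq_len(h) + 1L, 1L))
}

#' Binary thresholding
#'
#' Pixels with intensity at or above `beta_T` map to 1, all others to 0.
#' The default `beta_T = 68` is the empirically chosen working value for
#' contrast-stretched plug-flow frames.
#'
#' @inheritParams contrast_stretch
#' @param beta_T threshold intensity in `[0, 255]`.
#' @return integer matrix of 0/1 of the same shape.
#' @export
binary_threshold <- function(frame, beta_T = 68) {
  stopifnot(beta_T >= 0, beta_T <= 255)
  mask <- matrix(0L, nrow(frame), ncol(frame))
  mask[frame >= beta_T] <- 1L
  mask
}

# Erosion / dilation with an all-ones rectangular structuring element.
# Out-of-image pixels are background, so erosion strips the frame border.
morph_shift <- function(mask, se_size, op) {
  hr <- (se_size[1] - 1L) / 2L
  hc <- (se_size[2] - 1L) / 2L
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L * hr, nc + 2L * hc)
  pad[hr + seq_len(nr), hc + seq_len(nc)] <- mask
  acc <- NULL
  for (dr in seq(-hr, hr)) {
    for (dc in seq(-hc, hc)) {
      sub <- pad[hr + dr + seq_len(nr), hc + dc + seq_len(nc), drop = FALSE]
      acc <- if (is.null(acc)) sub else op(acc, sub)
    }
  }
  acc
}

#' Morphological opening
#'
#' Erosion followed by dilation with the same all-ones rectangular
#' structuring element (default 3x3). Opening removes thin bridges and
#' single-pixel artefacts -- in particular the shared boundaries between
#' touching cells -- without growing the remaining object.
#'
#' @param mask 0/1 integer matrix.
#' @param se_size structuring element size `c(rows, cols)`, both odd.
#' @return opened 0/1 matrix; always a subset of the input foreground.
#' @export
morphological_open <- function(mask, se_size = c(3L, 3L)) {
  se_size <- as.integer(se_size)
  if (length(se_size) == 1L) se_size <- rep(se_size, 2L)
  if (any(se_size < 1L) || any(se_size %% 2L == 0L))
    stop("structuring element dimensions must be odd", call. = FALSE)
  er <- morph_shift(mask, se_size, pmin)
  morph_shift(er, se_size, pmax)
}

#' Moore-neighbour boundary tracing
#'
#' Traces the outer boundary of the single 4-connected foreground
#' component of a binary mask. The trace starts at the first foreground
#' pixel in row-major order and walks the 8-neighbourhood clockwise,
#' terminating by Jacob's criterion (re-entering the start pixel from the
#' initial backtrack direction). Consecutive contour pixels are always
#' 8-adjacent and the sequence is closed.
#'
#' Contour points are returned in Cartesian pixel coordinates: `x` is the
#' 0-based column and `y` is the 0-based row counted from the *bottom* of
#' the mask, so that `+x` points along the flow axis and `+y` up.
#'
#' @param mask 0/1 integer matrix with exactly one 4-connected foreground
#'   component.
#' @return an object of class `rbc_contour`: list with `points` (n x 2
#'   matrix, columns `x`, `y`) and `M` (point count).
#' @export
trace_boundary <- function(mask) {
  fg <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    stop("no foreground object in mask", call. = FALSE)
  if (n_components4(mask) > 1L)
    stop("mask has multiple foreground components; tighten the ROI",
         call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  # row-major scan start: smallest row, then smallest column
  ord <- order(fg[, 1L], fg[, 2L])
  start <- fg[ord[1L], ]
  # clockwise Moore neighbourhood in image coordinates (row down):
  # W, NW, N, NE, E, SE, S, SW
  dirs <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  is_fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc &&
    mask[r, c] == 1L
  pts <- matrix(start, 1L, 2L)
  p <- start
  back_dir <- 1L # came from the W neighbour (background by scan order)
  init_back <- back_dir
  max_iter <- 4L * (nrow(fg) + 4L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("boundary trace failed to close", call. = FALSE)
    found <- FALSE
    for (k in seq_len(8L)) {
      d <- (back_dir + k - 1L) %% 8L + 1L
      r <- p[1L] + dirs[d, 1L]; c <- p[2L] + dirs[d, 2L]
      if (is_fg(r, c)) {
        # backtrack for the next step: the direction we examined just
        # before finding d, seen from the new pixel
        prev <- (back_dir + k - 2L) %% 8L + 1L
        pb <- p + dirs[prev, ]
        nb <- c(pb[1L] - r, pb[2L] - c)
        back_dir <- which(dirs[, 1L] == nb[1L] & dirs[, 2L] == nb[2L])
        if (r == start[1L] && c == start[2L] && back_dir == init_back) {
          found <- TRUE
          p <- NULL
        } else {
          pts <- rbind(pts, c(r, c))
          p <- c(r, c)
          found <- TRUE
        }
        break
      }
    }
    if (!found) break      # isolated pixel: contour is the single point
    if (is.null(p)) break  # Jacob's stopping criterion met
  }
  xy <- cbind(x = pts[, 2L] - 1, y = (nr - pts[, 1L]))
  new_contour(xy)
}

# Count 4-connected foreground components via flood fill.
n_components4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  idx <- which(mask == 1L)
  for (i0 in idx) {
    if (lab[i0] != 0L) next
    comp <- comp + 1L
    stack <- i0
    lab[i0] <- comp
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1L]; cc <- c + d[2L]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          j <- (cc - 1L) * nr + rr
          if (mask[j] == 1L && lab[j] == 0L) {
            lab[j] <- comp
            stack <- c(stack, j)
          }
        }
      }
    }
  }
  comp
}

#' Construct a membrane contour object
#'
#' @param points n x 2 matrix (columns `x`, `y`) of an ordered closed
#'   polygon; the closing edge from the last to the first point is
#'   implicit (the first point is not repeated).
#' @param frame_index frame number the contour belongs to.
#' @return object of class `rbc_contour`.
#' @export
new_contour <- function(points, frame_index = 0L) {
  points <- as.matrix(points)
  colnames(points) <- c("x", "y")
  # drop repeated consecutive points (and a repeated closing point)
  n <- nrow(points)
  if (n > 1L) {
    keep <- c(TRUE, rowSums(abs(points[-1L, , drop = FALSE] -
                                  points[-n, , drop = FALSE])) > 0)
    points <- points[keep, , drop = FALSE]
    n <- nrow(points)
    if (n > 1L && all(points[1L, ] == points[n, ]))
      points <- points[-n, , drop = FALSE]
  }
  structure(list(points = points, M = nrow(points),
                 frame_index = as.integer(frame_index)),
            class = "rbc_contour")
}

#' @export
print.rbc_contour <- function(x, ...) {
  cat(sprintf("<rbc_contour> %d points, frame %d\n", x$M, x$frame_index))
  invisible(x)
}

#' Resample a closed contour to M equally spaced points
#'
#' Redistributes the contour points at equal arc-length spacing along the
#' input polygon. The output starts at the input vertex whose direction
#' from the area centroid makes the smallest non-negative angle with the
#' `+x` (flow) axis, ties broken by smaller radius, and proceeds
#' counter-clockwise. Applying the same rule to every frame of a cell
#' gives an approximate point correspondence across frames; residual
#' correspondence error is absorbed by the large-cutoff cluster weighting
#' of the deformation-gradient estimator.
#'
#' @param contour an `rbc_contour`.
#' @param M number of output points (>= 4).
#' @return `rbc_contour` with exactly `M` points.
#' @export
resample_contour <- function(contour, M = 200L) {
  stopifnot(inherits(contour, "rbc_contour"), M >= 4L)
  P <- contour$points
  n <- nrow(P)
  if (n == 1L) stop("cannot resample a degenerate single-point contour",
                    call. = FALSE)
  # enforce counter-clockwise orientation (positive shoelace area)
  if (shoelace_area_signed(P) < 0) P <- P[rev(seq_len(n)), , drop = FALSE]
  ctr <- polygon_centroid(P)
  v <- sweep(P, 2L, ctr)
  ang <- atan2(v[, 2L], v[, 1L]) %% (2 * pi)
  ang[ang > 2 * pi - 1e-9] <- 0 # snap near-wraparound angles to zero
  rad <- sqrt(rowSums(v^2))
  start <- order(ang, rad)[1L]
  P <- P[c(start:n, seq_len(start - 1L)), , drop = FALSE]
  seg <- sqrt(rowSums((rbind(P[-1L, , drop = FALSE], P[1L, , drop = FALSE]) -
                         P)^2))
  L <- sum(seg)
  if (L <= 0) stop("zero-length contour cannot be resampled", call. = FALSE)
  cum <- c(0, cumsum(seg))
  t_out <- L * (seq_len(M) - 1L) / M
  i <- findInterval(t_out, cum, rightmost.closed = TRUE)
  i[i > n] <- n
  frac <- (t_out - cum[i]) / seg[i]
  frac[!is.finite(frac)] <- 0
  nxt <- c(seq_len(n)[-1L], 1L)
  out <- P[i, , drop = FALSE] +
    (P[nxt[i], , drop = FALSE] - P[i, , drop = FALSE]) * frac
  new_contour(out, contour$frame_index)
}

shoelace_area_signed <- function(P) {
  n <- nrow(P)
  j <- c(seq_len(n)[-1L], 1L)
  sum(P[, 1L] * P[j, 2L] - P[j, 1L] * P[, 2L]) / 2
}

polygon_centroid <- function(P) {
  n <- nrow(P)
  j <- c(seq_len(n)[-1L], 1L)
  cr <- P[, 1L] * P[j, 2L] - P[j, 1L] * P[, 2L]
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(colMeans(P))
  c(sum((P[, 1L] + P[j, 1L]) * cr) / (6 * A),
    sum((P[, 2L] + P[j, 2L]) * cr) / (6 * A))
}

#' Default image-processing parameters
#'
#' Working defaults for the segmentation front end: automatic contrast
#' window `[mu - sigma, mu]`, Gaussian smoothing with a 5x5 kernel and
#' `sigma = 7` px, binary threshold 68, 3x3 opening, and `M = 200`
#' resampled contour points (sub-pixel spacing for a cell tens of pixels
#' across).
#'
#' @param a,b contrast window (NULL = automatic per frame).
#' @param kernel_size,sigma Gaussian smoothing parameters.
#' @param beta_T binary threshold.
#' @param se_size opening structuring element size.
#' @param M resampled contour point count.
#' @param cell_is_dark if TRUE (transillumination recordings) the cell is
#'   darker than the threshold and the binary mask is complemented before
#'   opening and tracing.
#' @return named list of parameters.
#' @export
contour_params <- function(a = NULL, b = NULL, kernel_size = 5L, sigma = 7,
                           beta_T = 68, se_size = c(3L, 3L), M = 200L,
                           cell_is_dark = TRUE) {
  list(a = a, b = b, kernel_size = as.integer(kernel_size), sigma = sigma,
       beta_T = beta_T, se_size = as.integer(se_size), M = as.integer(M),
       cell_is_dark = isTRUE(cell_is_dark))
}

#' Extract the membrane contour sequence of one tracked cell
#'
#' Runs the full per-frame segmentation pipeline inside each tracked
#' region of interest: contrast stretch, Gaussian smoothing, binary
#' threshold (complemented for dark cells), morphological opening,
#' Moore-neighbour boundary tracing and equal-arc-length resampling to a
#' fixed point count `M`.
#'
#' @param frames list of intensity matrices (one per frame, 8-bit range).
#' @param roi_track data frame with columns `frame`, `x_min`, `y_min`,
#'   `x_max`, `y_max` (0-based inclusive pixel bounds, `y` counted from
#'   the bottom), and optionally `cell_id`. One row per frame.
#' @param params list from [contour_params()].
#' @param pixel_size_um micrometres per pixel.
#' @param dt_s inter-frame interval in seconds.
#' @param cell_id identifier stored on the result.
#' @return object of class `tracked_cell`: list with `contours` (one
#'   `rbc_contour` per frame, all sharing `M`), `M`, `pixel_size_um`,
#'   `dt_s`, `cell_id`.
#' @export
extract_cell_sequence <- function(frames, roi_track, params = contour_params(),
                                  pixel_size_um = 1, dt_s = 1e-3,
                                  cell_id = "cell") {
  stopifnot(is.list(frames), length(frames) >= 1L)
  roi_track <- roi_track[order(roi_track$frame), , drop = FALSE]
  contours <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fidx <- k - 1L
    row <- roi_track[roi_track$frame == fidx, , drop = FALSE]
    if (nrow(row) != 1L)
      stop(sprintf("frame %d: missing or duplicated ROI", fidx), call. = FALSE)
    frame <- frames[[k]]
    nr <- nrow(frame)
    # Cartesian y (from bottom) -> matrix rows (from top)
    rows <- (nr - row$y_max):(nr - row$y_min)
    cols <- (row$x_min + 1L):(row$x_max + 1L)
    rows <- rows[rows >= 1L & rows <= nr]
    cols <- cols[cols >= 1L & cols <= ncol(frame)]
    roi <- frame[rows, cols, drop = FALSE]
    cnt <- tryCatch({
      g <- contrast_stretch(roi, params$a, params$b)
      g <- gaussian_smooth(g, params$kernel_size, params$sigma)
      m <- binary_threshold(g, params$beta_T)
      if (params$cell_is_dark) m <- 1L - m
      m <- morphological_open(m, params$se_size)
      trace_boundary(m)
    }, error = function(e) {
      stop(sprintf("frame %d: %s", fidx, conditionMessage(e)), call. = FALSE)
    })
    # shift ROI-local coordinates back into the full frame
    pts <- cnt$points
    pts[, 1L] <- pts[, 1L] + (cols[1L] - 1L)
    pts[, 2L] <- pts[, 2L] + (nr - rows[length(rows)])
    contours[[k]] <- resample_contour(new_contour(pts, fidx), params$M)
  }
  new_tracked_cell(contours, pixel_size_um, dt_s, cell_id)
}

#' Construct a tracked cell from per-frame contours
#'
#' @param contours list of `rbc_contour`, all with identical point count.
#' @param pixel_size_um micrometres per pixel.
#' @param dt_s inter-frame interval (s).
#' @param cell_id identifier.
#' @return object of class `tracked_cell`.
#' @export
new_tracked_cell <- function(contours, pixel_size_um = 1, dt_s = 1e-3,
                             cell_id = "cell") {
  M <- unique(vapply(contours, function(c) c$M, integer(1)))
  if (length(M) != 1L)
    stop("all contours of a tracked cell must share the same M", call. = FALSE)
  structure(list(contours = contours, M = M, pixel_size_um = pixel_size_um,
                 dt_s = dt_s, cell_id = cell_id),
            class = "tracked_cell")
}

#' @export
print.tracked_cell <- function(x, ...) {
  cat(sprintf("<tracked_cell> '%s': %d frames, M = %d, %.3g um/px, dt = %g s\n",
              x$cell_id, length(x$contours), x$M, x$pixel_size_um, x$dt_s))
  invisible(x)
}

#' Write / read a contour table
#'
#' Contours are exchanged as CSV with columns
#' `cell_id,frame,point_index,x_px,y_px` (`x`/`y` in Cartesian pixel
#' coordinates, `y` up from the image bottom). A `# config_hash:` comment
#' line in the header carries the provenance fingerprint.
#'
#' @param cell a `tracked_cell`.
#' @param path output CSV path.
#' @param hash optional provenance hash to embed.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(cell, path, hash = NULL) {
  rows <- do.call(rbind, lapply(cell$contours, function(cnt) {
    data.frame(cell_id = cell$cell_id, frame = cnt$frame_index,
               point_index = seq_len(cnt$M) - 1L,
               x_px = cnt$points[, 1L], y_px = cnt$points[, 2L])
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @param pixel_size_um,dt_s physical scale to attach to the cell read back.
#' @export
read_contours_csv <- function(path, pixel_size_um = 1, dt_s = 1e-3) {
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("cell_id", "frame", "point_index", "x_px", "y_px")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("contour file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cid <- unique(d$cell_id)
  if (length(cid) != 1L)
    stop("one contour file per cell expected", call. = FALSE)
  contours <- lapply(sort(unique(d$frame)), function(f) {
    sub <- d[d$frame == f, , drop = FALSE]
    sub <- sub[order(sub$point_index), , drop = FALSE]
    new_contour(cbind(sub$x_px, sub$y_px), f)
  })
  new_tracked_cell(contours, pixel_size_um, dt_s, cid)
}
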