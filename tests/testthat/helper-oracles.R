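# Independent oracles used across the suite. These re-derive expected
# results from first principles (per-pixel definitions, unweighted normal
# equations, arc-length walks) and never call the implementation paths
# they check.

# --- brute-force morphology (per-pixel fit/hit definition) -------------
bf_erode <- function(mask, se = c(3L, 3L)) {
  hr <- (se[1] - 1L) / 2L; hc <- (se[2] - 1L) / 2L
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      fits <- TRUE
      for (di in -hr:hr) {
        for (dj in -hc:hc) {
          r <- i + di; c <- j + dj
          v <- if (r >= 1L && r <= nr && c >= 1L && c <= nc) mask[r, c] else 0L
          if (v != 1L) { fits <- FALSE; break }
        }
        if (!fits) break
      }
      out[i, j] <- as.integer(fits)
    }
  }
  out
}

bf_dilate <- function(mask, se = c(3L, 3L)) {
  hr <- (se[1] - 1L) / 2L; hc <- (se[2] - 1L) / 2L
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      hit <- FALSE
      for (di in -hr:hr) {
        for (dj in -hc:hc) {
          r <- i + di; c <- j + dj
          if (r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c] == 1L) {
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      out[i, j] <- as.integer(hit)
    }
  }
  out
}

bf_open <- function(mask, se = c(3L, 3L)) bf_dilate(bf_erode(mask, se), se)

# Vectorised-over-masks brute-force opening for the exhaustive 4x4
# enumeration: masks are rows of a 0/1 matrix, pixels column-major.
bf_open_all_4x4 <- function(masks) {
  nr <- 4L; nc <- 4L
  pix <- function(r, c) (c - 1L) * nr + r
  erode <- matrix(0L, nrow(masks), nr * nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      acc <- rep(1L, nrow(masks))
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        acc <- if (rr < 1L || rr > nr || cc < 1L || cc > nc) {
          0L * acc
        } else {
          pmin(acc, masks[, pix(rr, cc)])
        }
      }
      erode[, pix(r, c)] <- acc
    }
  }
  dil <- matrix(0L, nrow(masks), nr * nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      acc <- rep(0L, nrow(masks))
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc)
          acc <- pmax(acc, erode[, pix(rr, cc)])
      }
      dil[, pix(r, c)] <- acc
    }
  }
  dil
}

# --- unweighted normal-equations deformation gradient ------------------
# For affine motions the gradient is recovered exactly by the plain
# (weight-free) least squares F = (sum dx dX') (sum dX dX')^-1.
oracle_affine_F <- function(refP, curP, i) {
  dX <- sweep(refP[-i, , drop = FALSE], 2, refP[i, ])
  dx <- sweep(curP[-i, , drop = FALSE], 2, curP[i, ])
  unname(t(solve(crossprod(dX), crossprod(dX, dx))))
}

# --- geometry helpers --------------------------------------------------
polygon_perimeter <- function(P) {
  n <- nrow(P)
  j <- c(seq_len(n)[-1], 1)
  sum(sqrt(rowSums((P[j, , drop = FALSE] - P)^2)))
}

polygon_area <- function(P) {
  n <- nrow(P)
  j <- c(seq_len(n)[-1], 1)
  abs(sum(P[, 1] * P[j, 2] - P[j, 1] * P[, 2]) / 2)
}

# Random star-shaped smooth contour (for property sweeps).
random_contour <- function(M = 64L, radius = 10) {
  t <- 2 * pi * (seq_len(M) - 1L) / M
  r <- radius * (1 + 0.15 * sin(2 * t + stats::runif(1, 0, 2 * pi)) +
                   0.08 * cos(3 * t + stats::runif(1, 0, 2 * pi)))
  new_contour(cbind(r * cos(t), r * sin(t)))
}

# Rasterised disk mask: pixel centres within radius r of the centre.
disk_mask <- function(r, pad = 3L) {
  n <- 2L * (ceiling(r) + pad) + 1L
  ctr <- (n + 1) / 2
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 <= r^2) m[i, j] <- 1L
  m
}

# the six feature columns of the population model, in order
feature_columns_test <- function() {
  c("lambda_Pa", "mu_Pa", "E_Pa", "K_Pa", "wss_mean_Pa",
    "shear_strain_mean")
}

rotation_matrix <- function(phi) {
  matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
}
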