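# Internal numerical helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form inverse of a 2x2 matrix; returns NULL when the condition
# number (ratio of singular values) exceeds `cond_cutoff`.
solve_2x2 <- function(M, cond_cutoff = 1e8) {
  s <- svd(M, nu = 0, nv = 0)$d
  if (s[2] <= 0 || s[1] / s[2] > cond_cutoff) return(NULL)
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  matrix(c(M[2, 2], -M[2, 1], -M[1, 2], M[1, 1]), 2, 2) / det
}

cond_2x2 <- function(M) {
  s <- svd(M, nu = 0, nv = 0)$d
  if (s[2] <= 0) Inf else s[1] / s[2]
}

# Evaluate a bivariate polynomial given as a coefficient matrix C where
# C[p+1, q+1] multiplies x^p * y^q.
poly2d_eval <- function(C, x, y) {
  out <- numeric(length(x))
  for (p in seq_len(nrow(C)) - 1L) {
    for (q in seq_len(ncol(C)) - 1L) {
      cf <- C[p + 1L, q + 1L]
      if (cf != 0) out <- out + cf * x^p * y^q
    }
  }
  out
}

# Partial derivative of a poly2d coefficient matrix with respect to x
# (axis = 1) or y (axis = 2).
poly2d_deriv <- function(C, axis) {
  nr <- nrow(C); nc <- ncol(C)
  if (axis == 1L) {
    if (nr == 1L) return(matrix(0, 1, nc))
    D <- C[-1L, , drop = FALSE] * (seq_len(nr - 1L))
  } else {
    if (nc == 1L) return(matrix(0, nr, 1))
    D <- C[, -1L, drop = FALSE]
    D <- sweep(D, 2L, seq_len(nc - 1L), `*`)
  }
  D
}

# FNV-1a style 32-bit fingerprint of a configuration object, reported as
# 8 hex digits and stamped into every output file for provenance. The
# multiply is split into 16-bit halves so it is exact in doubles.
config_hash <- function(obj) {
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  for (b in bytes) {
    # XOR with one byte touches only the low 8 bits; keep h as a double
    # (bitwXor cannot take values beyond the signed 32-bit range)
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    lo <- h %% 65536; hi <- h %/% 65536
    # (hi*2^16 + lo) * 16777619 mod 2^32, pieces kept < 2^53
    h <- ((hi * 16777619) %% 65536) * 65536 + (lo * 16777619) %% 4294967296
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Evaluate with a locally-set RNG seed, restoring global state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  stats::sd(x) / sqrt(n)
}
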