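#' Cauchy stress from strain (isotropic Hooke's law)
#'
#' Treats the membrane as a two-dimensional Hookean isotropic solid:
#' `T = lambda tr(eps) I + 2 mu eps`.
#'
#' @param eps symmetric 2x2 strain matrix or 2 x 2 x M array.
#' @param lambda,mu Lame constants (Pa).
#' @return stress tensor(s) of the same shape (Pa), symmetric.
#' @export
cauchy_stress <- function(eps, lambda, mu) {
  if (is.matrix(eps)) {
    return(lambda * sum(diag(eps)) * diag(2) + 2 * mu * eps)
  }
  tr <- eps[1, 1, ] + eps[2, 2, ]
  out <- 2 * mu * eps
  out[1, 1, ] <- out[1, 1, ] + lambda * tr
  out[2, 2, ] <- out[2, 2, ] + lambda * tr
  out
}

#' Wall shear stress at a membrane point
#'
#' Resolves the flow-face traction components, net of the external
#' pressure, onto the local wall tangent:
#' `tau1 = T12 cos(theta) - (T11 - P_ext) sin(theta)`,
#' where `theta` is the outward-normal angle from the flow axis.
#'
#' @param T11,T12 stress components (Pa), vectorised.
#' @param theta outward-normal angle(s), radians.
#' @param P_ext external pressure (Pa) at the same point and frame.
#' @return wall shear stress (Pa).
#' @export
wall_shear_stress <- function(T11, T12, theta, P_ext = 0) {
  T12 * cos(theta) - (T11 - P_ext) * sin(theta)
}

#' Membrane tension from wall shear stress
#'
#' Integrating the (depth-constant) wall shear stress across the
#' membrane thickness gives the shear component of membrane tension,
#' `t1 = tau1 * w_n`, in N/m. The hemolysis literature places the
#' critical tension scale near 1e-4 N/m.
#'
#' @param tau1 wall shear stress (Pa).
#' @param w_n membrane thickness (m).
#' @return membrane tension (N/m).
#' @export
membrane_tension <- function(tau1, w_n = 5e-9) {
  if (w_n <= 0) stop("membrane thickness must be positive", call. = FALSE)
  tau1 * w_n
}

#' Temporal statistics of per-frame stress maps
#'
#' Collapses per-frame, per-point wall shear stress and membrane tension
#' into the reported summaries: the per-point temporal mean (for spatial
#' maps) and the per-cell average, maximum and minimum over all valid
#' points and frames.
#'
#' @param frames list of per-frame lists, each with numeric vectors
#'   `tau1` and `t1` and optionally a logical `valid`.
#' @return list with `per_point` (data frame: `point_index`,
#'   `tau1_mean`, `t1_mean`, `n_frames`) and `per_cell` (named list of
#'   `tau1_mean/max/min`, `t1_mean/max/min`).
#' @export
temporal_statistics <- function(frames) {
  if (length(frames) == 0L) stop("no stress frames supplied", call. = FALSE)
  M <- length(frames[[1L]]$tau1)
  tau <- sapply(frames, function(f) {
    v <- f$tau1
    if (!is.null(f$valid)) v[!f$valid] <- NA_real_
    v
  })
  tau <- matrix(tau, nrow = M)
  t1 <- sapply(frames, function(f) {
    v <- f$t1
    if (!is.null(f$valid)) v[!f$valid] <- NA_real_
    v
  })
  t1 <- matrix(t1, nrow = M)
  per_point <- data.frame(point_index = seq_len(M) - 1L,
                          tau1_mean = rowMeans(tau, na.rm = TRUE),
                          t1_mean = rowMeans(t1, na.rm = TRUE),
                          n_frames = rowSums(!is.na(tau)))
  all_tau <- tau[is.finite(tau)]
  all_t1 <- t1[is.finite(t1)]
  if (length(all_tau) == 0L)
    stop("all stress values invalid", call. = FALSE)
  list(per_point = per_point,
       per_cell = list(tau1_mean = mean(all_tau), tau1_max = max(all_tau),
                       tau1_min = min(all_tau), t1_mean = mean(all_t1),
                       t1_max = max(all_t1), t1_min = min(all_t1)))
}
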