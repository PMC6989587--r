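#' Flow environment: physical constants of the capillary plug-flow model
#'
#' Container for the constants entering the force balance. Defaults are
#' the working values for mammalian capillary plug flow: internal
#' pressure 8.5 Pa (85 dyn/cm^2), membrane density 1300 kg/m^3, blood
#' viscosity 2.63 mPa s (2.63 cP), membrane thickness 5 nm.
#'
#' @param P_int_Pa constant internal pressure acting along the outward
#'   membrane normal (Pa).
#' @param rho_kg_m3 membrane density (kg/m^3).
#' @param mu_blood_Pa_s plasma/blood viscosity (Pa s).
#' @param D_T_m capillary diameter (m).
#' @param L_T_m capillary length (m).
#' @param alpha_m_s cell-plasma displacement shift (m/s); 0 when the cell
#'   moves with the plasma.
#' @param w_n_m membrane thickness (m).
#' @return list of class `flow_environment`.
#' @export
flow_environment <- function(P_int_Pa = 8.5, rho_kg_m3 = 1300,
                             mu_blood_Pa_s = 2.63e-3, D_T_m = 8e-6,
                             L_T_m = 400e-6, alpha_m_s = 0, w_n_m = 5e-9) {
  env <- list(P_int_Pa = P_int_Pa, rho_kg_m3 = rho_kg_m3,
              mu_blood_Pa_s = mu_blood_Pa_s, D_T_m = D_T_m, L_T_m = L_T_m,
              alpha_m_s = alpha_m_s, w_n_m = w_n_m)
  pos <- c("P_int_Pa", "rho_kg_m3", "mu_blood_Pa_s", "D_T_m", "L_T_m",
           "w_n_m")
  for (f in pos) if (env[[f]] <= 0)
    stop(sprintf("%s must be positive", f), call. = FALSE)
  if (env$alpha_m_s < 0) stop("alpha_m_s must be >= 0", call. = FALSE)
  structure(env, class = "flow_environment")
}

#' External pressure on the upstream membrane half
#'
#' Lubrication-style external pressure for a cell occluding a capillary
#' of diameter `D_T` and length `L_T`, applied on the upstream half of
#' the membrane (axial coordinate `X1 <= 0`, origin at the cell
#' centroid) and zero downstream:
#' \deqn{P_{ext} = \tfrac{2}{3}\,\mu\,(V_C+\alpha)\,\frac{L_T}{D_T^2}
#'   \left(1 - 0.8\,\frac{D_T}{L_T}\,\frac{V_C}{V_C+\alpha}\right)}
#' `V_C` is the cell velocity along the capillary and `alpha` the
#' cell-plasma displacement shift.
#'
#' @param env a [flow_environment()].
#' @param V_C_m_s cell velocity (m/s).
#' @param X1 axial membrane coordinate(s) relative to the centroid (m).
#' @return external pressure (Pa), vectorised over `X1`.
#' @export
external_pressure <- function(env, V_C_m_s, X1) {
  Vtot <- V_C_m_s + env$alpha_m_s
  if (Vtot == 0) stop("V_C + alpha must be nonzero", call. = FALSE)
  base <- (2 / 3) * env$mu_blood_Pa_s * Vtot * env$L_T_m / env$D_T_m^2 *
    (1 - (env$D_T_m / env$L_T_m) * 0.8 * V_C_m_s / Vtot)
  ifelse(X1 > 0, 0, base)
}

#' Membrane body-force density from internal and external pressure
#'
#' Per-length force components acting on the membrane free body: the
#' internal pressure acts along the outward normal (angle `theta` from
#' the flow axis) and the external pressure pushes against the flow
#' direction on the upstream half. Returned as the pair
#' `(-(P_ext + P_int cos theta), -P_int sin theta)`; dividing by the
#' membrane thickness (done during system assembly) converts it to the
#' volumetric body-force term of the momentum balance.
#'
#' @param theta outward-normal angle(s), radians.
#' @param P_ext external pressure (Pa), scalar or per point.
#' @param env a [flow_environment()].
#' @return n x 2 matrix of force-per-length components.
#' @export
body_force <- function(theta, P_ext, env) {
  cbind(-(P_ext + env$P_int_Pa * cos(theta)),
        -env$P_int_Pa * sin(theta))
}

#' Spatial gradient of a quantity known only on the membrane curve
#'
#' Estimates per-point partial derivatives `(d/dX1, d/dX2)` of one or
#' more scalar fields sampled on the contour by a weighted local
#' quadratic fit: for each point, a full bivariate quadratic is fitted
#' over the spline-weighted cluster (same weighting as the
#' deformation-gradient estimator) and the linear coefficients give the
#' gradient. On a curve the six quadratic monomials may be linearly
#' dependent (e.g. `X1^2 + X2^2` is constant on a circle), so the fitted
#' coefficients are not unique. Dependent columns are therefore dropped
#' by a greedy rank-revealing sweep in *degree order* (constant, linear,
#' quadratic): signal is attributed to the lowest-order terms able to
#' carry it, which keeps the estimated gradient exact for fields that
#' are polynomials of degree <= 2, including on degenerate neighbourhoods
#' where the full quadratic basis is rank-deficient along the curve.
#'
#' @param values numeric vector (length M) or M x k matrix of sampled
#'   fields.
#' @param geom a [contour_geometry()] record (supplies the coordinates).
#' @param r_cut cluster cutoff radius; `NULL` uses half the contour
#'   diameter.
#' @return list with `d1`, `d2` (M x k matrices of partials) and `valid`
#'   (logical M-vector, `FALSE` where the local fit is rank-deficient in
#'   its linear part).
#' @export
gradient_on_contour <- function(values, geom, r_cut = NULL) {
  X <- geom$X
  M <- nrow(X)
  values <- as.matrix(values)
  if (nrow(values) != M)
    stop("values must have one row per contour point", call. = FALSE)
  k <- ncol(values)
  if (is.null(r_cut)) r_cut <- contour_diameter(X) / 2
  ok_rows <- rowSums(!is.finite(values)) == 0
  d1 <- matrix(NA_real_, M, k)
  d2 <- matrix(NA_real_, M, k)
  valid <- rep(FALSE, M)
  for (i in seq_len(M)) {
    dx <- sweep(X, 2L, X[i, ])
    d <- sqrt(rowSums(dx^2))
    d[i] <- Inf # exclude self from the radius rule, re-add below
    w <- cluster_weights(d, r_cut)
    w[i] <- 1
    keep <- which(w > 0 & ok_rows)
    if (length(keep) < 5L) next
    u1 <- dx[keep, 1L]; u2 <- dx[keep, 2L]
    sw <- sqrt(w[keep])
    Xd <- cbind(1, u1, u2, u1^2, u1 * u2, u2^2) * sw
    acc <- accept_columns_in_order(Xd, tol = 1e-8)
    # the linear terms must be identifiable for a gradient to exist
    if (!all(c(2L, 3L) %in% acc)) next
    qrd <- qr(Xd[, acc, drop = FALSE])
    cf_acc <- qr.coef(qrd, values[keep, , drop = FALSE] * sw)
    cf <- matrix(0, 6L, k)
    cf[acc, ] <- cf_acc
    d1[i, ] <- cf[2L, ]
    d2[i, ] <- cf[3L, ]
    valid[i] <- TRUE
  }
  list(d1 = d1, d2 = d2, valid = valid)
}

# Greedy order-respecting rank reveal: accept each column of X whose
# residual after orthogonalisation against the already-accepted columns
# retains more than `tol` of its norm (modified Gram-Schmidt with one
# re-orthogonalisation pass).
accept_columns_in_order <- function(X, tol = 1e-8) {
  acc <- integer(0)
  basis <- NULL
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    n0 <- sqrt(sum(v^2))
    if (n0 == 0) next
    if (!is.null(basis)) {
      for (pass in 1:2) v <- v - basis %*% crossprod(basis, v)
    }
    if (sqrt(sum(v^2)) > tol * n0) {
      acc <- c(acc, j)
      basis <- cbind(basis, v / sqrt(sum(v^2)))
    }
  }
  acc
}

#' Per-point membrane acceleration from a tracked contour sequence
#'
#' Second time derivative of corresponding point positions, by central
#' second differences in time; the first and last frames use one-sided
#' second-order four-point stencils (falling back to the adjacent
#' central value when only three frames exist). Exact for trajectories
#' quadratic in time.
#'
#' @param positions list of M x 2 point matrices (consistent units), one
#'   per frame, with point correspondence across frames.
#' @param dt inter-frame interval (s).
#' @return M x 2 x N array of accelerations.
#' @export
acceleration_field <- function(positions, dt) {
  N <- length(positions)
  if (N < 3L) stop("acceleration needs at least 3 frames", call. = FALSE)
  M <- nrow(positions[[1L]])
  P <- array(NA_real_, c(M, 2L, N))
  for (j in seq_len(N)) P[, , j] <- positions[[j]]
  acc <- array(NA_real_, c(M, 2L, N))
  for (j in 2:(N - 1L)) {
    acc[, , j] <- (P[, , j + 1L] - 2 * P[, , j] + P[, , j - 1L]) / dt^2
  }
  if (N >= 4L) {
    acc[, , 1L] <- (2 * P[, , 1L] - 5 * P[, , 2L] + 4 * P[, , 3L] -
                      P[, , 4L]) / dt^2
    acc[, , N] <- (2 * P[, , N] - 5 * P[, , N - 1L] + 4 * P[, , N - 2L] -
                     P[, , N - 3L]) / dt^2
  } else {
    acc[, , 1L] <- acc[, , 2L]
    acc[, , N] <- acc[, , N - 1L]
  }
  acc
}

#' Assemble the per-point 2x2 system for the Lame constants
#'
#' Rearranging the discretised Navier-Cauchy momentum balance on the
#' membrane collects the unknowns `(lambda, mu)` into `A x = b` at every
#' point:
#' \deqn{A = \begin{pmatrix}
#'   \partial_1 G_{11} + \partial_1 G_{22} &
#'   2\partial_1 G_{11} + \partial_1 G_{22} + \partial_2 G_{12}\\
#'   \partial_2 G_{22} + \partial_2 G_{11} &
#'   2\partial_2 G_{22} + \partial_2 G_{11} + \partial_1 G_{21}
#' \end{pmatrix}}
#' \deqn{b = \begin{pmatrix}
#'   \rho \ddot u + (P_{ext} + P_{int}\cos\theta)/w_n\\
#'   \rho \ddot v + P_{int}\sin\theta / w_n\end{pmatrix}}
#' where `G` is the displacement gradient and the common arc-length
#' factor `dl` has been cancelled from both sides.
#'
#' @param dG list with numeric entries `dG11_d1`, `dG11_d2`, `dG12_d2`,
#'   `dG21_d1`, `dG22_d1`, `dG22_d2` (each length-n, units 1/m).
#' @param accel n x 2 matrix of accelerations (m/s^2).
#' @param theta outward-normal angles (radians).
#' @param P_ext external pressure per point (Pa).
#' @param env a [flow_environment()].
#' @return list with `A` (2 x 2 x n) and `b` (n x 2).
#' @export
assemble_point_system <- function(dG, accel, theta, P_ext, env) {
  n <- length(dG$dG11_d1)
  A <- array(NA_real_, c(2L, 2L, n))
  A[1, 1, ] <- dG$dG11_d1 + dG$dG22_d1
  A[1, 2, ] <- 2 * dG$dG11_d1 + dG$dG22_d1 + dG$dG12_d2
  A[2, 1, ] <- dG$dG22_d2 + dG$dG11_d2
  A[2, 2, ] <- 2 * dG$dG22_d2 + dG$dG11_d2 + dG$dG21_d1
  rho <- env$rho_kg_m3
  b <- cbind(rho * accel[, 1L] +
               (P_ext + env$P_int_Pa * cos(theta)) / env$w_n_m,
             rho * accel[, 2L] + env$P_int_Pa * sin(theta) / env$w_n_m)
  list(A = A, b = b)
}

#' Solve the collected per-point systems for the Lame constants
#'
#' Each well-conditioned per-point system is solved with the
#' Moore-Penrose pseudoinverse, `x = A^+ b`, and the per-point solutions
#' are averaged over all valid points (and frames, when systems from
#' several frame pairs are pooled) to give the cell's mean `lambda` and
#' `mu` with their standard errors. Points whose `A` has condition
#' number above `cond_cutoff` are excluded: these are the degenerate,
#' nearly rank-deficient systems that arise where the strain-gradient
#' signal vanishes. Rank-deficient systems below the cutoff yield the
#' minimum-norm solution and are flagged.
#'
#' @param systems list of outputs of [assemble_point_system()] (one per
#'   frame pair), or a single such output.
#' @param cond_cutoff condition-number acceptance threshold.
#' @return object of class `lame_solution`: list with `lambda_Pa`,
#'   `mu_Pa`, `lambda_sem`, `mu_sem`, `n_valid`, `n_total`, per-point
#'   tables, and the derived moduli `E_Pa`, `K_Pa`, `nu` (reported
#'   algebraically with `moduli_defined = FALSE` when the estimated
#'   `lambda + mu` is not positive).
#' @export
solve_lame <- function(systems, cond_cutoff = 1e6) {
  if (!is.null(systems$A)) systems <- list(systems)
  lam <- numeric(0)
  mu <- numeric(0)
  rank_def <- logical(0)
  n_total <- 0L
  for (sys in systems) {
    n <- dim(sys$A)[3L]
    n_total <- n_total + n
    for (i in seq_len(n)) {
      A <- sys$A[, , i]
      if (any(!is.finite(A)) || any(!is.finite(sys$b[i, ]))) next
      sv <- svd(A)
      s <- sv$d
      if (s[1] <= 0) next
      cnd <- if (s[2] <= s[1] * .Machine$double.eps) Inf else s[1] / s[2]
      if (cnd > cond_cutoff) next
      dinv <- ifelse(s > s[1] * .Machine$double.eps, 1 / s, 0)
      x <- sv$v %*% (dinv * crossprod(sv$u, sys$b[i, ]))
      lam <- c(lam, x[1L])
      mu <- c(mu, x[2L])
      rank_def <- c(rank_def, is.infinite(cnd))
    }
  }
  if (length(lam) == 0L)
    stop("no well-conditioned point systems; Lame estimation failed",
         call. = FALSE)
  lambda_Pa <- mean(lam)
  mu_Pa <- mean(mu)
  # the isotropic relations applied algebraically; on noise-dominated
  # input the estimated lambda + mu can be non-positive, in which case
  # the moduli are reported as algebraic continuations and flagged
  denom <- lambda_Pa + mu_Pa
  mod <- list(E_Pa = if (denom != 0)
    mu_Pa * (3 * lambda_Pa + 2 * mu_Pa) / denom else NA_real_,
    K_Pa = lambda_Pa + 2 * mu_Pa / 3,
    nu = if (denom != 0) lambda_Pa / (2 * denom) else NA_real_)
  structure(list(lambda_Pa = lambda_Pa, mu_Pa = mu_Pa,
                 moduli_defined = denom > 0,
                 lambda_sem = sem(lam), mu_sem = sem(mu),
                 E_Pa = mod$E_Pa, K_Pa = mod$K_Pa, nu = mod$nu,
                 n_valid = length(lam), n_total = n_total,
                 per_point = data.frame(lambda_Pa = lam, mu_Pa = mu,
                                        rank_deficient = rank_def)),
            class = "lame_solution")
}

#' @export
print.lame_solution <- function(x, ...) {
  cat(sprintf(paste0("<lame_solution> lambda = %.4g +/- %.2g Pa, ",
                     "mu = %.4g +/- %.2g Pa\n  E = %.4g Pa, K = %.4g Pa, ",
                     "nu = %.3f  (%d/%d valid points)\n"),
              x$lambda_Pa, x$lambda_sem, x$mu_Pa, x$mu_sem,
              x$E_Pa, x$K_Pa, x$nu, x$n_valid, x$n_total))
  invisible(x)
}

#' Young's modulus, bulk modulus and Poisson ratio from Lame constants
#'
#' Standard isotropic-elasticity relations:
#' `E = mu (3 lambda + 2 mu) / (lambda + mu)`, `K = lambda + 2 mu / 3`,
#' `nu = lambda / (2 (lambda + mu))`.
#'
#' @param lambda,mu Lame's first and second parameters (Pa).
#' @return list with `E_Pa`, `K_Pa`, `nu`.
#' @export
#' @examples
#' derived_moduli(35e6, 1.1e6)
derived_moduli <- function(lambda, mu) {
  if (lambda + mu <= 0)
    stop("lambda + mu must be positive for the derived moduli",
         call. = FALSE)
  list(E_Pa = mu * (3 * lambda + 2 * mu) / (lambda + mu),
       K_Pa = lambda + 2 * mu / 3,
       nu = lambda / (2 * (lambda + mu)))
}
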