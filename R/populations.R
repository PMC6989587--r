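#' Mechanical feature columns used by the population model
#' @keywords internal
feature_columns <- c("lambda_Pa", "mu_Pa", "E_Pa", "K_Pa",
                     "wss_mean_Pa", "shear_strain_mean")

as_feature_matrix <- function(features) {
  miss <- setdiff(feature_columns, names(features))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(features[, feature_columns, drop = FALSE])
  if (any(!is.finite(m)))
    stop("feature table contains non-finite values", call. = FALSE)
  m
}

#' Build a baseline PCA model of cell mechanics
#'
#' Fits a two-component PCA to the six-feature mechanical profile of the
#' baseline (native-cell) population: the two Lame constants, Young's
#' and bulk moduli, mean wall shear stress and mean shear strain.
#' Features are z-scored with the baseline mean and standard deviation
#' before the decomposition, so the MPa-scale moduli cannot dominate the
#' Pa-scale stress features. The per-component score standard deviations
#' of the baseline population calibrate the outlier rule used by
#' [classify_cells()].
#'
#' @param baseline data frame with a `cell_id` column and the six
#'   feature columns `lambda_Pa`, `mu_Pa`, `E_Pa`, `K_Pa`,
#'   `wss_mean_Pa`, `shear_strain_mean`; at least 3 rows.
#' @return object of class `rbc_pca_model`: feature means/scales,
#'   orthonormal loading matrix (6 x 2) and baseline score SDs.
#' @export
build_pca_model <- function(baseline) {
  m <- as_feature_matrix(baseline)
  if (nrow(m) < 3L)
    stop("at least 3 baseline cells are required", call. = FALSE)
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  if (any(sdv <= 0))
    stop("zero-variance feature(s): ",
         paste(feature_columns[sdv <= 0], collapse = ", "), call. = FALSE)
  z <- scale(m, center = mu, scale = sdv)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  loadings <- pc$rotation[, 1:2, drop = FALSE]
  score_sd <- pc$sdev[1:2]
  if (any(score_sd <= 0))
    stop("degenerate baseline: leading principal components have zero ",
         "variance", call. = FALSE)
  structure(list(center = mu, scale = sdv, loadings = loadings,
                 score_sd = score_sd, n_baseline = nrow(m)),
            class = "rbc_pca_model")
}

#' @export
print.rbc_pca_model <- function(x, ...) {
  cat(sprintf("<rbc_pca_model> %d baseline cells; score SDs %.3g, %.3g\n",
              x$n_baseline, x$score_sd[1], x$score_sd[2]))
  invisible(x)
}

#' Project cells through a baseline PCA model
#'
#' @param model an `rbc_pca_model`.
#' @param cells feature data frame (same columns as the baseline).
#' @return n x 2 matrix of scores in baseline-SD units.
#' @export
pca_scores <- function(model, cells) {
  m <- as_feature_matrix(cells)
  z <- scale(m, center = model$center, scale = model$scale)
  s <- z %*% model$loadings
  sweep(s, 2L, model$score_sd, `/`)
}

#' Classify cells against the baseline PCA model
#'
#' Post-intervention cells are labelled `SC2` when *both* leading
#' principal-component scores lie more than `k_sd` baseline standard
#' deviations from the baseline mean (in absolute value), and `SC1`
#' otherwise; baseline cells are labelled `NC`. The default `k_sd = 3`
#' makes a false `SC2` call on a Gaussian baseline essentially
#' impossible (about 7e-6 per cell).
#'
#' @param model an `rbc_pca_model`.
#' @param cells feature data frame with `cell_id`.
#' @param baseline set `TRUE` when classifying the baseline cells
#'   themselves (labelled `NC`).
#' @param k_sd outlier threshold in baseline score SDs.
#' @return data frame `cell_id`, `label`, `pc1_sd_units`, `pc2_sd_units`.
#' @export
classify_cells <- function(model, cells, baseline = FALSE, k_sd = 3) {
  s <- pca_scores(model, cells)
  label <- if (baseline) {
    rep("NC", nrow(s))
  } else {
    ifelse(abs(s[, 1L]) > k_sd & abs(s[, 2L]) > k_sd, "SC2", "SC1")
  }
  data.frame(cell_id = cells$cell_id, label = label,
             pc1_sd_units = s[, 1L], pc2_sd_units = s[, 2L])
}

#' Per-group mean and standard error
#'
#' Summarises a per-cell scalar by population label as mean +/- SEM
#' (`SD / sqrt(n)` over cells). Empty groups are omitted with a warning;
#' single-cell groups report SEM 0 with a degenerate-group warning.
#'
#' @param values numeric per-cell values.
#' @param labels group label per cell.
#' @return data frame `label`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(values, labels) {
  labs <- unique(labels)
  out <- lapply(labs, function(g) {
    v <- values[labels == g]
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      warning(sprintf("group '%s' is empty; omitted", g), call. = FALSE)
      return(NULL)
    }
    if (length(v) == 1L)
      warning(sprintf("group '%s' has a single cell; SEM degenerate", g),
              call. = FALSE)
    data.frame(label = g, n = length(v), mean = mean(v), sem = sem(v))
  })
  do.call(rbind, out)
}
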