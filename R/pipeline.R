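#' Full run configuration
#'
#' Bundles every tunable of the pipeline with its default: the
#' image-processing settings of [contour_params()], the physical
#' constants of [flow_environment()], the numerical guards of the
#' kinematics and inverse solves, and the I/O paths. The configuration
#' hash of this list is embedded in every output file.
#'
#' @param stack path to the image stack (multi-page TIFF).
#' @param track path to the ROI track CSV
#'   (`frame,x_min,y_min,x_max,y_max,cell_id`).
#' @param out output directory.
#' @param pixel_size_um micrometres per pixel.
#' @param dt_s inter-frame interval (s).
#' @param params image-processing parameters ([contour_params()]).
#' @param env physical constants ([flow_environment()]).
#' @param r_cut_frac cluster cutoff radius as a fraction of the contour
#'   diameter.
#' @param cond_cutoff_D condition guard for the kinematics moment matrix.
#' @param cond_cutoff_A condition guard for accepting a point's Lame
#'   system.
#' @param beta_e elastic fraction of the Maxwell strain split.
#' @param exclude_edge_points drop points flagged by
#'   [edge_proximity_mask()].
#' @param seed RNG seed for any stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(stack = NULL, track = NULL, out = ".",
                       pixel_size_um = 1 / 15, dt_s = 1e-3,
                       params = contour_params(), env = flow_environment(),
                       r_cut_frac = 0.5, cond_cutoff_D = 1e8,
                       cond_cutoff_A = 1e6, beta_e = 0.1,
                       exclude_edge_points = TRUE, seed = 1L) {
  structure(list(stack = stack, track = track, out = out,
                 pixel_size_um = pixel_size_um, dt_s = dt_s, params = params,
                 env = env, r_cut_frac = r_cut_frac,
                 cond_cutoff_D = cond_cutoff_D, cond_cutoff_A = cond_cutoff_A,
                 beta_e = beta_e,
                 exclude_edge_points = isTRUE(exclude_edge_points),
                 seed = as.integer(seed)),
            class = "run_config")
}

# Fingerprint the analysis parameters only: I/O paths are deliberately
# excluded so identical analyses of the same data hash identically
# wherever they are run.
hashable_config <- function(config) {
  cfg <- unclass(config)
  cfg$env <- unclass(cfg$env)
  cfg <- cfg[setdiff(names(cfg), c("stack", "track", "out"))]
  cfg[!vapply(cfg, is.null, logical(1))]
}

#' Mechanical analysis of one tracked cell
#'
#' The core inverse-mechanics chain. For every consecutive frame pair it
#' estimates the per-point deformation gradient
#' ([deformation_gradient_field()]), differentiates the displacement
#' gradient along the membrane ([gradient_on_contour()]), evaluates
#' accelerations, internal and external pressure, assembles the
#' per-point Navier-Cauchy systems and pools them into one
#' pseudoinverse solve for the cell's Lame constants
#' ([solve_lame()]). The adjusted membrane strain then gives per-frame
#' Cauchy stress, wall shear stress and membrane tension, summarised by
#' [temporal_statistics()], and the six-feature mechanical profile used
#' by the population model.
#'
#' @param cell a `tracked_cell` with at least 3 frames.
#' @param config a [run_config()] (its `pixel_size_um`/`dt_s` are
#'   overridden by the cell's own values).
#' @return list of class `cell_mechanics` with elements `lame`
#'   (`lame_solution`), `stress` (temporal statistics), `stress_frames`
#'   (per-frame maps), `features` (one-row data frame), `V_C_m_s`,
#'   `geoms`, `cell_id`.
#' @export
analyze_cell <- function(cell, config = run_config()) {
  stopifnot(inherits(cell, "tracked_cell"))
  N <- length(cell$contours)
  if (N < 3L) stop("cell has fewer than 3 frames", call. = FALSE)
  px_m <- cell$pixel_size_um * 1e-6
  dt <- cell$dt_s
  env <- config$env
  geoms <- lapply(cell$contours, contour_geometry, pixel_size = px_m)
  # cell velocity along the capillary: centroid displacement per frame
  cents <- t(vapply(geoms, function(g) g$centroid, numeric(2)))
  V_C <- abs(mean(diff(cents[, 1L]))) / dt
  if (V_C == 0 && env$alpha_m_s == 0) V_C <- .Machine$double.eps
  positions <- lapply(cell$contours, function(cnt) cnt$points * px_m)
  accel <- acceleration_field(positions, dt)
  excl <- if (config$exclude_edge_points) {
    lapply(cell$contours, function(cnt) edge_proximity_mask(cnt))
  } else {
    lapply(cell$contours, function(cnt) rep(FALSE, cnt$M))
  }
  systems <- vector("list", N - 1L)
  stress_frames <- vector("list", N - 1L)
  eps_records <- vector("list", N - 1L)
  for (j in 2:N) {
    ref <- cell$contours[[j - 1L]]
    cur <- cell$contours[[j]]
    geom <- geoms[[j - 1L]]
    r_cut_m <- config$r_cut_frac * contour_diameter(geom$X)
    dfield <- deformation_gradient_field(
      scale_contour(ref, px_m), scale_contour(cur, px_m),
      r_cut = r_cut_m, cond_cutoff = config$cond_cutoff_D,
      exclude = excl[[j - 1L]])
    Gv <- cbind(dfield$G[1, 1, ], dfield$G[1, 2, ],
                dfield$G[2, 1, ], dfield$G[2, 2, ])
    gr <- gradient_on_contour(Gv, geom, r_cut = r_cut_m)
    dG <- list(dG11_d1 = gr$d1[, 1L], dG11_d2 = gr$d2[, 1L],
               dG12_d2 = gr$d2[, 2L], dG21_d1 = gr$d1[, 3L],
               dG22_d1 = gr$d1[, 4L], dG22_d2 = gr$d2[, 4L])
    P_ext <- external_pressure(env, V_C, geom$X[, 1L])
    sys <- assemble_point_system(dG, accel[, , j - 1L], geom$theta, P_ext,
                                 env)
    ok <- dfield$valid & gr$valid
    sys$A[, , !ok] <- NA_real_
    sys$b[!ok, ] <- NA_real_
    systems[[j - 1L]] <- sys
    eps_raw <- infinitesimal_strain(dfield$F)
    adj <- adjusted_strain(eps_raw, beta_e = config$beta_e,
                           w_n = env$w_n_m, l = geom$l,
                           A_cell = geom$A_cell)
    eps_records[[j - 1L]] <- list(eps = adj$eps, valid = dfield$valid,
                                  theta = geom$theta, P_ext = P_ext,
                                  frame = ref$frame_index,
                                  points = ref$points)
  }
  lame <- solve_lame(systems, cond_cutoff = config$cond_cutoff_A)
  for (k in seq_along(eps_records)) {
    er <- eps_records[[k]]
    T <- cauchy_stress(er$eps, lame$lambda_Pa, lame$mu_Pa)
    tau1 <- wall_shear_stress(T[1, 1, ], T[1, 2, ], er$theta, er$P_ext)
    stress_frames[[k]] <- list(frame = er$frame, T = T, tau1 = tau1,
                               t1 = membrane_tension(tau1, env$w_n_m),
                               valid = er$valid, points = er$points,
                               eps = er$eps)
  }
  stats <- temporal_statistics(stress_frames)
  shear_strain <- unlist(lapply(stress_frames, function(f) {
    abs(f$eps[1, 2, f$valid])
  }))
  features <- data.frame(cell_id = cell$cell_id,
                         lambda_Pa = lame$lambda_Pa, mu_Pa = lame$mu_Pa,
                         E_Pa = lame$E_Pa, K_Pa = lame$K_Pa,
                         wss_mean_Pa = stats$per_cell$tau1_mean,
                         shear_strain_mean = mean(shear_strain))
  structure(list(lame = lame, stress = stats, stress_frames = stress_frames,
                 features = features, V_C_m_s = V_C, geoms = geoms,
                 cell_id = cell$cell_id),
            class = "cell_mechanics")
}

scale_contour <- function(contour, f) {
  new_contour(contour$points * f, contour$frame_index)
}

#' @export
print.cell_mechanics <- function(x, ...) {
  cat(sprintf("<cell_mechanics> '%s': V_C = %.3g mm/s, mean WSS = %.3g Pa\n",
              x$cell_id, x$V_C_m_s * 1e3, x$stress$per_cell$tau1_mean))
  print(x$lame)
  invisible(x)
}

#' Run contour extraction over a stack and track file
#'
#' Reads the image stack and ROI track named in the configuration,
#' extracts the contour sequence of every tracked cell, and writes one
#' contour CSV per cell plus a processing log. Cells whose segmentation
#' fails on any frame are skipped with the reason logged.
#'
#' @param config a [run_config()] with `stack`, `track`, `out` set.
#' @return named character vector of written contour files.
#' @export
run_extract <- function(config) {
  if (is.null(config$stack) || !file.exists(config$stack))
    stop("image stack not found: ", config$stack %||% "<unset>",
         call. = FALSE)
  if (is.null(config$track) || !file.exists(config$track))
    stop("track file not found: ", config$track %||% "<unset>",
         call. = FALSE)
  frames <- read_video_tiff(config$stack)
  track <- utils::read.csv(config$track, comment.char = "#")
  need <- c("frame", "x_min", "y_min", "x_max", "y_max", "cell_id")
  miss <- setdiff(need, names(track))
  if (length(miss))
    stop("track file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(hashable_config(config))
  out <- character(0)
  log <- character(0)
  for (cid in unique(track$cell_id)) {
    sub <- track[track$cell_id == cid, , drop = FALSE]
    res <- tryCatch({
      cell <- extract_cell_sequence(frames, sub, config$params,
                                    config$pixel_size_um, config$dt_s,
                                    cell_id = cid)
      path <- file.path(config$out, sprintf("contours_%s.csv", cid))
      write_contours_csv(cell, path, hash = hash)
      log <- c(log, sprintf("cell %s: %d frames extracted", cid,
                            length(cell$contours)))
      path
    }, error = function(e) {
      log <<- c(log, sprintf("cell %s: EXCLUDED (%s)", cid,
                             conditionMessage(e)))
      NA_character_
    })
    if (!is.na(res)) out[cid] <- res
  }
  writeLines(c(sprintf("# config_hash: %s", hash), log),
             file.path(config$out, "extract_log.txt"))
  if (length(out) == 0L)
    stop("no cell could be extracted; see extract_log.txt", call. = FALSE)
  out
}

#' Run the mechanical analysis over extracted contour files
#'
#' @param config a [run_config()].
#' @param contour_files character vector of contour CSVs (defaults to
#'   every `contours_*.csv` under `config$out`).
#' @return list with `features` (data frame, also written to
#'   `features.csv`), `reports` (per-cell `cell_mechanics`), and paths.
#' @export
run_analyze <- function(config, contour_files = NULL) {
  if (is.null(contour_files))
    contour_files <- list.files(config$out, "^contours_.*\\.csv$",
                                full.names = TRUE)
  if (length(contour_files) == 0L)
    stop("no contour files to analyze", call. = FALSE)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(hashable_config(config))
  reports <- list()
  feats <- list()
  for (path in contour_files) {
    cell <- read_contours_csv(path, config$pixel_size_um, config$dt_s)
    if (length(cell$contours) < 3L) {
      message(sprintf("cell %s: fewer than 3 frames; skipped", cell$cell_id))
      next
    }
    mech <- analyze_cell(cell, config)
    reports[[cell$cell_id]] <- mech
    feats[[cell$cell_id]] <- mech$features
    write_mechanics_json(mech, config,
                         file.path(config$out,
                                   sprintf("mechanics_%s.json", cell$cell_id)),
                         hash)
    write_stress_csv(mech,
                     file.path(config$out,
                               sprintf("stressmap_%s.csv", cell$cell_id)),
                     hash)
  }
  if (length(feats) == 0L)
    stop("no cell had enough frames for analysis", call. = FALSE)
  features <- do.call(rbind, feats)
  fpath <- file.path(config$out, "features.csv")
  con <- file(fpath, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(features, con, row.names = FALSE)
  close(con)
  list(features = features, reports = reports, features_path = fpath)
}

write_mechanics_json <- function(mech, config, path, hash) {
  lame <- mech$lame
  rec <- list(cell_id = mech$cell_id, config_hash = hash,
              lambda_mean_Pa = lame$lambda_Pa, lambda_sem = lame$lambda_sem,
              mu_mean_Pa = lame$mu_Pa, mu_sem = lame$mu_sem,
              E_Pa = lame$E_Pa, K_Pa = lame$K_Pa, nu = lame$nu,
              n_valid_points = lame$n_valid,
              n_frames = length(mech$stress_frames) + 1L,
              V_C_m_s = mech$V_C_m_s,
              wss = mech$stress$per_cell,
              config = hashable_config(config))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_stress_csv <- function(mech, path, hash = NULL) {
  rows <- do.call(rbind, lapply(mech$stress_frames, function(f) {
    data.frame(cell_id = mech$cell_id, frame = f$frame,
               point_index = seq_along(f$tau1) - 1L,
               x_px = f$points[, 1L], y_px = f$points[, 2L],
               T11 = f$T[1, 1, ], T12 = f$T[1, 2, ], T22 = f$T[2, 2, ],
               tau1_Pa = f$tau1, t1_N_per_m = f$t1, valid = f$valid)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' Classify post-intervention cells against a baseline feature table
#'
#' @param config a [run_config()].
#' @param baseline_features,test_features paths to feature CSVs (columns
#'   `cell_id`, `lambda_Pa`, `mu_Pa`, `E_Pa`, `K_Pa`, `wss_mean_Pa`,
#'   `shear_strain_mean`).
#' @return list with `assignments`, `summary` data frames and paths.
#' @export
run_classify <- function(config, baseline_features, test_features) {
  for (p in c(baseline_features, test_features))
    if (!file.exists(p)) stop("feature file not found: ", p, call. = FALSE)
  base <- utils::read.csv(baseline_features, comment.char = "#",
                          check.names = FALSE)
  test <- utils::read.csv(test_features, comment.char = "#",
                          check.names = FALSE)
  model <- build_pca_model(base)
  asg <- rbind(classify_cells(model, base, baseline = TRUE),
               classify_cells(model, test))
  all_feat <- rbind(base[, c("cell_id", feature_columns)],
                    test[, c("cell_id", feature_columns)])
  all_feat$label <- asg$label[match(all_feat$cell_id, asg$cell_id)]
  summ <- do.call(rbind, lapply(feature_columns, function(fc) {
    s <- group_summary(all_feat[[fc]], all_feat$label)
    s$feature <- fc
    s
  }))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(hashable_config(config))
  apath <- file.path(config$out, "assignments.csv")
  spath <- file.path(config$out, "group_summary.csv")
  for (x in list(list(asg, apath), list(summ, spath))) {
    con <- file(x[[2L]], "w")
    writeLines(sprintf("# config_hash: %s", hash), con)
    utils::write.csv(x[[1L]], con, row.names = FALSE)
    close(con)
  }
  list(assignments = asg, summary = summ,
       assignments_path = apath, summary_path = spath)
}

#' Render a synthetic scene to disk (stack + track + truth)
#'
#' Convenience wrapper used by the command-line `simulate` step: renders
#' the scene, writes the multi-page TIFF, the ROI track CSV, and the
#' ground-truth contour CSV.
#'
#' @param scene a [synthetic_scene()].
#' @param out output directory.
#' @return named list of written paths plus the rendered video.
#' @export
run_simulate <- function(scene, out = ".") {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  video <- render_video(scene)
  stack <- file.path(out, "stack.tif")
  write_video_tiff(video, stack)
  track <- file.path(out, "track.csv")
  utils::write.csv(video$roi_track, track, row.names = FALSE)
  truth_cell <- new_tracked_cell(video$truth$contours,
                                 scene$pixel_size_um, scene$dt_s,
                                 "synthetic_truth")
  truth <- file.path(out, "truth_contours.csv")
  write_contours_csv(truth_cell, truth)
  list(stack = stack, track = track, truth = truth, video = video)
}
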