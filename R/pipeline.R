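# End-to-end pipeline: simulate -> (optional smoothing) -> subject GLMs ->
# per-ROI pattern component models -> similarity statistics -> sensitivity
# metrics -> somatotopy geometry -> group statistics.

#' Pipeline run configuration
#'
#' @param scenario Ground-truth scenario name, see [scenario_preset()].
#' @param n_subjects Number of simulated subjects.
#' @param grid_shape Simulation grid (voxels).
#' @param roi_dim ROI box size in voxels (z a multiple of 3).
#' @param seed Master seed; every random stage derives its stream from it.
#' @param smooth_fwhm Smoothing FWHM in mm; `0` disables, the string
#'   `"proportional"` uses 2 x voxel size per protocol.
#' @param alpha Uncorrected threshold for group activation maps.
#' @param q FDR level for similarity statistics.
#' @param out_dir Optional output directory for tables and summaries.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(scenario = "subcortical_protocol_dependent",
                       n_subjects = 6, grid_shape = c(30L, 38L, 30L),
                       roi_dim = c(5L, 5L, 6L), seed = 1L,
                       smooth_fwhm = 0, alpha = 0.05, q = 0.05,
                       out_dir = NULL) {
  stopifnot(n_subjects >= 2, alpha > 0, alpha < 1)
  if (!identical(smooth_fwhm, "proportional")) stopifnot(smooth_fwhm >= 0)
  structure(list(scenario = scenario, n_subjects = n_subjects,
                 grid_shape = as.integer(grid_shape),
                 roi_dim = as.integer(roi_dim), seed = as.integer(seed),
                 smooth_fwhm = smooth_fwhm, alpha = alpha, q = q,
                 out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  s <- paste(names(config), sapply(config, function(x)
    paste(format(x), collapse = ",")), collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 4294967296)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates `n_subjects` sessions under each of the three acquisition
#' protocols, fits subject-level GLMs, averages condition betas across
#' subjects per ROI (contralateral movements only), fits one pattern
#' component model per ROI, and derives similarity, sensitivity, geometry
#' and group statistics. With `out_dir` set, writes tidy tab-separated
#' tables, a JSON summary and a run log.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result` with elements `similarity`
#'   (per-ROI reports), `ios_table`, `sensitivity`, `motion`,
#'   `scaled_variance`, `geometry`, `group` (correlation/ANCOVA/MANOVA/
#'   ANOVA results) and `summary`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  protocols <- protocol_presets()
  paradigm <- paradigm_spec()
  truth <- scenario_preset(config$scenario)
  rois <- make_roi_masks(config$grid_shape, roi_dim = config$roi_dim)
  grid <- dim(rois$labels)
  n_roi <- length(rois$names)
  cells <- factorial_cells()

  # group-level pattern components, one 9 x v matrix per ROI, shared
  # across subjects (the pattern model is a group-level random effect)
  patterns <- with_seed(config$seed, {
    ps <- lapply(seq_len(n_roi), function(k) {
      g <- truth$g_by_class[[roi_info(rois$names[k])$class]]
      simulate_patterns(g, v = sum(rois$labels == k), sigma2 = 0,
                        seed = sample.int(2^30, 1))
    })
    names(ps) <- rois$names
    ps
  })

  conds <- condition_labels()
  # accumulators
  betas <- array(NA_real_, c(length(conds), prod(grid), length(protocols),
                             config$n_subjects))
  sens_rows <- motion_rows <- sv_rows <- NULL

  for (s in seq_len(config$n_subjects)) {
    for (ip in seq_along(protocols)) {
      prot <- protocols[[ip]]
      run_seed <- config$seed * 10000L + s * 100L + ip
      events <- make_paradigm(paradigm, seed = run_seed)
      sim <- simulate_timeseries(prot, events, rois, truth,
                                 seed = run_seed + 1L, patterns = patterns)
      img <- sim$image
      fwhm <- if (identical(config$smooth_fwhm, "proportional"))
        2 * prot$voxel_size else config$smooth_fwhm
      if (fwhm > 0) img <- gaussian_smooth(img, fwhm)
      X <- build_design(events, prot, motion = sim$motion)
      fit <- fit_glm(img, X)
      betas[, , ip, s] <- fit$betas[X$condition_columns[match(
        conds, colnames(X$X)[X$condition_columns])], , drop = FALSE]

      # sensitivity metrics
      tsnr <- tsnr_map(img, X)
      tsnr_roi <- roi_summary(tsnr, rois)
      phi <- residual_lag1(fit)
      cons <- differential_contrasts(X)
      tmaps <- lapply(cons, function(cv)
        array(contrast_tmap(fit, cv)$t, dim = grid))
      for (k in seq_len(n_roi)) {
        side <- roi_info(rois$names[k])$side
        contra <- conds[endsWith(conds, if (side == "L") "right" else "left")]
        top5 <- mean(sapply(tmaps[contra], function(tm)
          top5_tscores(tm, rois)[k]))
        w <- weighted_tsnr(tsnr_roi[k], prot, phi)
        sens_rows <- rbind(sens_rows, data.frame(
          subject = s, protocol = prot$name, roi = rois$names[k],
          tsnr = unname(tsnr_roi[k]), tsnr_per_sqrt_tr = w$per_sqrt_tr,
          tsnr_per_sqrt_n = w$per_sqrt_n, tsnr_scaled = w$scaled,
          t_top5 = top5, phi = phi))
      }
      mm <- motion_metrics(sim$motion)
      motion_rows <- rbind(motion_rows, data.frame(
        subject = s, protocol = prot$name,
        mean_translation = mm$mean_translation,
        max_translation = mm$max_translation,
        n_movements = mm$n_movements, rotation_deg = mm$rotation_deg))
      svc <- scaled_variance_by_condition(img, events, prot)
      sv_rows <- rbind(sv_rows, data.frame(
        subject = s, protocol = prot$name, condition = names(svc),
        scaled_variance = unname(svc)))
    }
  }

  # ---- pattern component models on subject-averaged contralateral betas
  beta_bar <- apply(betas, c(1, 2, 3), mean)  # cond x voxel x protocol
  roi_betas <- list()
  for (k in seq_len(n_roi)) {
    side <- roi_info(rois$names[k])$side
    vox <- which(rois$labels == k)
    Y <- matrix(NA_real_, 9, length(vox))
    for (ci in seq_len(9)) {
      cond <- paste0(cells$movement[ci],
                     "_", if (side == "L") "right" else "left")
      ip <- match(paste0(sub("^1\\.5$", "1.5", as.character(
        cells$resolution[ci])), "mm"), names(protocols))
      Y[ci, ] <- beta_bar[match(cond, conds), vox, ip]
    }
    roi_betas[[rois$names[k]]] <- beta_matrix(Y, roi = rois$names[k])
  }
  pcm_fits <- fit_per_roi(roi_betas)
  similarity <- lapply(names(pcm_fits), function(name)
    similarity_report(pcm_fits[[name]], n_eff = ncol(roi_betas[[name]]$y),
                      roi = name, q = config$q))
  names(similarity) <- names(pcm_fits)
  ios_values <- do.call(rbind, lapply(similarity, `[[`, "values"))
  ios_contrasts <- do.call(rbind, lapply(similarity, `[[`, "contrasts"))

  # ---- IoS ~ tSNR table: one row per (ROI, resolution)
  wr <- ios_values[ios_values$family == "within_resolution", ]
  ios_table <- stats::aggregate(ios ~ roi + group, wr, mean)
  names(ios_table)[names(ios_table) == "group"] <- "protocol"
  tsnr_mean <- stats::aggregate(
    cbind(tsnr, tsnr_per_sqrt_tr, tsnr_per_sqrt_n, tsnr_scaled, t_top5) ~
      roi + protocol, sens_rows, mean)
  ios_table <- merge(ios_table, tsnr_mean, by = c("roi", "protocol"))
  ios_table$resolution <- as.numeric(sub("mm$", "", ios_table$protocol))
  ios_table$class <- vapply(ios_table$roi,
                            function(r) roi_info(r)$class, character(1))

  # ---- group statistics
  corr <- correlate(ios_table$tsnr, ios_table$ios)
  ancova <- ancova_ios(ios_table$ios, ios_table$tsnr, ios_table$resolution)

  # ---- geometry from group one-sample t-maps per condition x protocol
  geom_rows <- NULL
  proj_list <- list()
  dof_group <- config$n_subjects - 1L
  com_store <- array(NA_real_, c(n_roi, 3, 3, 3),
                     dimnames = list(rois$names, MOVEMENTS, names(protocols),
                                     c("X", "Y", "Z")))
  for (ip in seq_along(protocols)) {
    prot <- protocols[[ip]]
    for (cond in conds) {
      eff <- betas[match(cond, conds), , ip, ]      # voxel x subject
      mu <- rowMeans(eff)
      se <- sqrt(apply(eff, 1, stats::var) / config$n_subjects)
      tmap <- array(ifelse(se > 0, mu / se, 0), dim = grid)
      mask <- threshold_tmap(tmap, dof_group, config$alpha)
      movement <- sub("_(left|right)$", "", cond)
      hemi <- if (endsWith(cond, "right")) "L" else "R"
      for (k in which(endsWith(rois$names, paste0("_", hemi)))) {
        roi_m <- rois$labels == k
        sub_mask <- mask & roi_m
        com <- suppressWarnings(center_of_mass(sub_mask, rois$affine))
        mx <- activation_maximum(tmap, roi_m, rois$affine)
        av <- adjusted_volume(mask, roi_m)
        com_store[k, movement, ip, ] <- com
        geom_rows <- rbind(geom_rows, data.frame(
          roi = rois$names[k], movement = movement, protocol = prot$name,
          resolution = prot$voxel_size,
          com_x = com[1], com_y = com[2], com_z = com[3],
          max_x = mx[1], max_y = mx[2], max_z = mx[3],
          adjusted_volume = av, n_voxels = sum(sub_mask)))
      }
    }
  }

  # betweenness / direction flags per ROI x protocol
  flag_rows <- NULL
  for (k in seq_len(n_roi)) for (ip in seq_along(protocols)) {
    coms <- lapply(MOVEMENTS, function(m) com_store[k, m, ip, ])
    names(coms) <- MOVEMENTS
    bw <- betweenness_check(coms$foot, coms$hand, coms$face)
    dir_ok <- tryCatch(direction_check(coms, rois$names[k]),
                       error = function(e) NA)
    flag_rows <- rbind(flag_rows, data.frame(
      roi = rois$names[k], protocol = names(protocols)[ip],
      between_any = bw$any_axis, between_x = bw$per_axis[["X"]],
      between_y = bw$per_axis[["Y"]], between_z = bw$per_axis[["Z"]],
      direction_expected = dir_ok))
  }

  # principal-axis projection per ROI, MANOVA across ROIs
  manova_rows <- NULL
  for (k in seq_len(n_roi)) {
    coms9 <- matrix(aperm(com_store[k, , , ], c(1, 2, 3)), 9, 3)
    labs <- expand.grid(movement = MOVEMENTS, protocol = names(protocols))
    ok <- stats::complete.cases(coms9)
    if (sum(ok) < 4) next
    pr <- principal_axis_projection(coms9[ok, , drop = FALSE])
    proj_list[[rois$names[k]]] <- pr
    manova_rows <- rbind(manova_rows, data.frame(
      roi = rois$names[k], movement = labs$movement[ok],
      protocol = labs$protocol[ok], pc1 = pr$projected[, 1],
      pc2 = pr$projected[, 2], pc3 = pr$projected[, 3]))
  }
  manova <- manova_coords(as.matrix(manova_rows[, c("pc1", "pc2", "pc3")]),
                          manova_rows$movement, manova_rows$protocol)

  # activation volumes ~ resolution, scaled variance ~ protocol x condition
  vol_anova <- anova_oneway_twoway(geom_rows$adjusted_volume,
                                   paste0(geom_rows$resolution, "mm"))
  sv_anova <- anova_oneway_twoway(sv_rows$scaled_variance, sv_rows$protocol,
                                  sv_rows$condition)

  # ---- summary
  by_class <- stats::aggregate(ios ~ class + protocol, ios_table, mean)
  least_seg <- vapply(split(by_class, by_class$class), function(d)
    d$protocol[which.max(d$ios)], character(1))
  summary <- list(
    scenario = config$scenario, seed = config$seed,
    config_hash = config_hash(config),
    n_subjects = config$n_subjects,
    mean_ios_by_class_protocol = by_class,
    least_segregated_protocol = as.list(least_seg),
    ios_tsnr_pearson_r = corr$pearson$r,
    ios_tsnr_spearman_rho = corr$spearman$rho,
    ancova_model_F = ancova$model_fit$F,
    manova_movement_pillai = manova$pillai[manova$term == "bp"],
    mean_adjusted_volume = stats::aggregate(
      adjusted_volume ~ resolution, geom_rows, mean),
    betweenness_rate = mean(flag_rows$between_any, na.rm = TRUE))

  result <- structure(list(
    config = config, rois = rois, pcm_fits = pcm_fits,
    similarity = similarity, ios_values = ios_values,
    ios_contrasts = ios_contrasts, ios_table = ios_table,
    sensitivity = sens_rows, motion = motion_rows,
    scaled_variance = sv_rows, geometry = geom_rows,
    geometry_flags = flag_rows, projections = proj_list,
    group = list(correlation = corr, ancova = ancova, manova = manova,
                 volume_anova = vol_anova, scaled_variance_anova = sv_anova),
    summary = summary), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  dir.create(result$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- result$config$out_dir
  hash <- config_hash(result$config)
  stamp <- paste0("# config_hash: ", hash, " seed: ", result$config$seed)
  wt <- function(df, name) {
    path <- file.path(out, paste0(name, ".tsv"))
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  wt(result$ios_values, "ios_values")
  wt(result$ios_contrasts, "ios_contrasts")
  wt(result$ios_table, "ios_tsnr")
  wt(result$sensitivity, "sensitivity")
  wt(result$motion, "motion")
  wt(result$scaled_variance, "scaled_variance")
  wt(result$geometry, "geometry")
  wt(result$geometry_flags, "geometry_flags")
  jsonlite::write_json(result$summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_config(unclass(result$config)[!vapply(unclass(result$config),
                                              is.null, logical(1))],
               file.path(out, "config.txt"))
  writeLines(c(paste("somatoseg", as.character(utils::packageVersion("somatoseg"))),
               paste("R", getRversion()), stamp,
               paste("completed", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(out, "run.log"))
  invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> scenario:", x$config$scenario,
      "| subjects:", x$config$n_subjects, "\n")
  cat("least segregated protocol (mean IoS):",
      paste(names(x$summary$least_segregated_protocol),
            unlist(x$summary$least_segregated_protocol),
            sep = "=", collapse = ", "), "\n")
  cat("IoS~tSNR r =", round(x$summary$ios_tsnr_pearson_r, 3),
      "| betweenness rate =", round(x$summary$betweenness_rate, 3), "\n")
  invisible(x)
}
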