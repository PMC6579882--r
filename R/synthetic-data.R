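# Synthetic study data: paradigm event tables, beta patterns with known
# pattern covariance, 4D block-design time series with AR(1) noise, box ROI
# masks and head-motion traces. All generators are pure functions of
# (parameters, seed).

#' Generate a pseudo-randomized block paradigm
#'
#' Builds the event table of one session: an initial rest block, then for
#' each active block a preparation cue, the active movement block and a rest
#' block of equal duration. Condition order is a seeded pseudo-random
#' permutation constrained so no condition occurs twice in a row (avoiding
#' learning/attention confounds tied to repeats).
#'
#' @param spec A [paradigm_spec()].
#' @param seed Integer seed for the condition ordering.
#' @return Data frame of class `event_table` with columns `onset` (s),
#'   `duration` (s), `condition`, `event_class` (`active`/`prep`/`rest`).
#' @export
make_paradigm <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "paradigm_spec"))
  n_active <- length(spec$conditions) * spec$blocks_per_condition
  if (n_active < 1) stop("paradigm has zero active blocks")
  order <- with_seed(seed, {
    draw <- function() sample(rep(spec$conditions, spec$blocks_per_condition))
    o <- draw()
    tries <- 0L
    while (any(o[-1] == o[-length(o)]) && tries < 1000L) {
      o <- draw(); tries <- tries + 1L
    }
    o
  })

  onset <- spec$rest_duration  # lead-in rest
  rows <- list(data.frame(onset = 0, duration = spec$rest_duration,
                          condition = "rest", event_class = "rest"))
  for (cond in order) {
    rows[[length(rows) + 1L]] <- data.frame(
      onset = onset, duration = spec$prep_duration,
      condition = cond, event_class = "prep")
    onset <- onset + spec$prep_duration
    rows[[length(rows) + 1L]] <- data.frame(
      onset = onset, duration = spec$block_duration,
      condition = cond, event_class = "active")
    onset <- onset + spec$block_duration
    rows[[length(rows) + 1L]] <- data.frame(
      onset = onset, duration = spec$rest_duration,
      condition = "rest", event_class = "rest")
    onset <- onset + spec$rest_duration
  }
  out <- do.call(rbind, rows)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Ground truth for a simulation scenario
#'
#' @param g_true p x p symmetric positive semi-definite pattern covariance
#'   on the correlation scale (unit diagonal).
#' @param sigma2_true Trial-noise variance added to the beta patterns.
#' @param amplitude_pct Mean response amplitude, percent of baseline.
#' @param pattern_pct Standard deviation of the voxelwise pattern component,
#'   percent of baseline.
#' @param ar1_phi Lag-1 autocorrelation of the voxel noise, in (-1, 1).
#' @param tsnr_target Named per-protocol baseline/noise-SD ratio.
#' @param g_by_class Optional named list of per-ROI-class pattern
#'   covariances (`cortical`, `subcortical`); defaults to `g_true` for both.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(g_true, sigma2_true = 0.5, amplitude_pct = 1.5,
                         pattern_pct = 0.75, ar1_phi = 0.3,
                         tsnr_target = c("1.5mm" = 20, "2mm" = 30, "3mm" = 40),
                         g_by_class = NULL) {
  check_psd(g_true, "g_true")
  stopifnot(abs(ar1_phi) < 1, all(tsnr_target > 0), sigma2_true >= 0)
  if (is.null(g_by_class))
    g_by_class <- list(cortical = g_true, subcortical = g_true)
  lapply(g_by_class, check_psd, name = "g_by_class")
  structure(list(g_true = g_true, sigma2_true = sigma2_true,
                 amplitude_pct = amplitude_pct, pattern_pct = pattern_pct,
                 ar1_phi = ar1_phi, tsnr_target = tsnr_target,
                 g_by_class = g_by_class),
            class = "ground_truth")
}

check_psd <- function(G, name = "G") {
  if (!isSymmetric(unname(G), tol = 1e-8)) stop(name, " must be symmetric")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop(name, " is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  invisible(TRUE)
}

# Correlation-scale pattern covariance for the 9 factorial cells from a
# latent-factor construction guaranteeing positive semi-definiteness:
# u_{m,r} = sqrt(c_r) h_m + sqrt(1 - c_r) e_{m,r}, with corr(h_m, h_m') =
# rho_mov. Within-resolution between-movement correlation is c_r * rho_mov;
# same-movement cross-resolution correlation is sqrt(c_r * c_r').
factorial_g <- function(r_between, rho_mov) {
  stopifnot(length(r_between) == 3, all(r_between >= 0),
            all(r_between <= rho_mov), rho_mov < 1)
  cells <- factorial_cells()
  c_r <- r_between / rho_mov
  G <- matrix(0, 9, 9)
  for (i in 1:9) for (j in 1:9) {
    ri <- match(cells$resolution[i], RESOLUTIONS)
    rj <- match(cells$resolution[j], RESOLUTIONS)
    same_mov <- cells$movement[i] == cells$movement[j]
    rho <- if (same_mov) 1 else rho_mov
    G[i, j] <- sqrt(c_r[ri] * c_r[rj]) * rho
    if (same_mov && ri == rj) G[i, j] <- 1
  }
  (G + t(G)) / 2
}

#' Scenario presets encoding the study's hypotheses as ground truth
#'
#' `cortical_invariant`: between-movement pattern correlation is identically
#' low at all three resolutions (segregation does not depend on protocol).
#' `subcortical_protocol_dependent`: between-movement correlation is low at
#' 1.5 mm and 3 mm but high at 2 mm, i.e. the intermediate resolution is the
#' least segregated. The protocol-dependent preset keeps the invariant
#' structure for cortical ROIs via `g_by_class`, so one run can carry both
#' behaviours.
#'
#' @param name Scenario name.
#' @return A [ground_truth()] object.
#' @export
scenario_preset <- function(name = c("cortical_invariant",
                                     "subcortical_protocol_dependent")) {
  name <- match.arg(name)
  g_cort <- factorial_g(r_between = c(0.2, 0.2, 0.2), rho_mov = 0.3)
  if (name == "cortical_invariant") {
    ground_truth(g_cort,
                 g_by_class = list(cortical = g_cort, subcortical = g_cort))
  } else {
    g_sub <- factorial_g(r_between = c(0.2, 0.55, 0.2), rho_mov = 0.6)
    ground_truth(g_sub,
                 g_by_class = list(cortical = g_cort, subcortical = g_sub))
  }
}

# symmetric matrix square root tolerating semi-definiteness
psd_sqrt <- function(G) {
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate condition-by-voxel beta patterns with known covariance
#'
#' Draws Y = Z U + E where the columns of U are iid zero-mean Gaussian with
#' covariance `g_true` and E is iid Gaussian noise with variance `sigma2`.
#'
#' @param g_true p x p PSD pattern covariance.
#' @param z n x p design matrix (default identity).
#' @param v Number of voxels.
#' @param sigma2 Noise variance.
#' @param seed Integer seed.
#' @return n x v numeric matrix.
#' @export
simulate_patterns <- function(g_true, z = diag(nrow(g_true)), v, sigma2 = 0,
                              seed = 1L) {
  check_psd(g_true, "g_true")
  stopifnot(v >= 1, ncol(z) == nrow(g_true), sigma2 >= 0)
  p <- nrow(g_true); n <- nrow(z)
  with_seed(seed, {
    U <- psd_sqrt(g_true) %*% matrix(stats::rnorm(p * v), p, v)
    z %*% U + sqrt(sigma2) * matrix(stats::rnorm(n * v), n, v)
  })
}

default_affine <- function(grid_shape, voxel = 1.5) {
  aff <- diag(c(rep(voxel, 3), 1))
  aff[1:3, 4] <- -voxel * (grid_shape - 1) / 2  # center the grid on 0 mm
  aff
}

# Box placements for 5 structures x 2 hemispheres. Structures stacked along
# y; hemispheres mirrored across the x midline. Sizes in voxels.
ROI_STRUCTURES <- c("M1", "SMA", "putamen", "pallidum", "thalamus")
ROI_CLASS <- c(M1 = "cortical", SMA = "cortical", putamen = "subcortical",
               pallidum = "subcortical", thalamus = "subcortical")

#' Synthetic box ROI masks
#'
#' Builds 10 disjoint axis-aligned box ROIs (M1, SMA, putamen, pallidum,
#' thalamus in each hemisphere) on a regular grid, mirrored across the
#' mid-sagittal plane. Boxes give exactly computable centers of mass for the
#' geometry checks. Each ROI's box is `roi_dim` voxels; its z extent is
#' split into three equal slabs that the time-series generator uses as the
#' foot (dorsal), hand (middle) and face (ventral) somatotopy fields.
#'
#' @param grid_shape Integer 3-vector of grid dimensions.
#' @param affine Voxel-to-world affine (default: isotropic 1.5 mm, centered).
#' @param roi_dim Integer 3-vector, box size per ROI in voxels; the z size
#'   must be a multiple of 3.
#' @return An [roi_set()]; ROI names are like `"putamen_L"`.
#' @export
make_roi_masks <- function(grid_shape = c(40L, 48L, 40L),
                           affine = default_affine(grid_shape),
                           roi_dim = c(5L, 5L, 6L)) {
  grid_shape <- as.integer(grid_shape)
  roi_dim <- as.integer(roi_dim)
  stopifnot(length(grid_shape) == 3, length(roi_dim) == 3,
            roi_dim[3] %% 3 == 0)
  n_struct <- length(ROI_STRUCTURES)
  gap <- 2L
  need_y <- n_struct * roi_dim[2] + (n_struct + 1L) * gap
  need_x <- 2L * roi_dim[1] + 3L * gap + 2L  # hemispheres + midline margin
  need_z <- roi_dim[3] + 2L * gap
  if (grid_shape[1] < need_x || grid_shape[2] < need_y || grid_shape[3] < need_z)
    stop("grid too small for 10 disjoint ROI boxes: need at least ",
         paste(c(need_x, need_y, need_z), collapse = " x "))
  labels <- array(0L, dim = grid_shape)
  names <- character(0)
  mid <- grid_shape[1] / 2
  z0 <- as.integer(floor((grid_shape[3] - roi_dim[3]) / 2)) + 1L
  k <- 0L
  for (s in seq_along(ROI_STRUCTURES)) {
    y0 <- gap + (s - 1L) * (roi_dim[2] + gap) + 1L
    for (side in c("L", "R")) {
      k <- k + 1L
      names[k] <- paste0(ROI_STRUCTURES[s], "_", side)
      # left hemisphere occupies low x indices, right mirrors it
      xl <- gap + 1L
      xs <- if (side == "L") xl:(xl + roi_dim[1] - 1L)
            else (grid_shape[1] + 1L) - (xl:(xl + roi_dim[1] - 1L))
      labels[xs, y0:(y0 + roi_dim[2] - 1L), z0:(z0 + roi_dim[3] - 1L)] <- k
    }
  }
  roi_set(labels, names, affine)
}

#' Hemisphere and tissue class of an ROI name
#' @param name ROI name such as `"putamen_L"`.
#' @return List with `structure`, `side` (`L`/`R`) and `class`
#'   (`cortical`/`subcortical`).
#' @export
roi_info <- function(name) {
  parts <- strsplit(name, "_")[[1]]
  side <- parts[length(parts)]
  structure_name <- paste(parts[-length(parts)], collapse = "_")
  list(structure = structure_name, side = side,
       class = unname(ROI_CLASS[structure_name]))
}

#' Somatotopy field of a movement inside an ROI
#'
#' The synthetic somatotopy splits each box ROI into three z slabs: foot in
#' the dorsal third, hand in the middle, face in the ventral third,
#' emulating a dorsal-to-ventral body-part gradient.
#'
#' @param rois An [roi_set()] from [make_roi_masks()].
#' @param name ROI name.
#' @param movement `"foot"`, `"hand"` or `"face"`.
#' @return Logical 3D array marking the movement's field within the ROI.
#' @export
roi_condition_mask <- function(rois, name, movement) {
  m <- roi_mask(rois, name)
  zs <- which(apply(m, 3, any))
  n <- length(zs)
  stopifnot(n %% 3 == 0)
  third <- n / 3
  band <- switch(movement,
                 face = zs[seq_len(third)],
                 hand = zs[third + seq_len(third)],
                 foot = zs[2 * third + seq_len(third)],
                 stop("unknown movement: ", movement))
  keep <- array(FALSE, dim(m))
  keep[, , band] <- TRUE
  m & keep
}

# AR(1) series matrix: n rows (time) x v columns, stationary unit variance
ar1_noise <- function(n, v, phi) {
  innov <- matrix(stats::rnorm(n * v), n, v)
  if (phi == 0) return(innov)
  innov <- innov * sqrt(1 - phi^2)
  innov[1, ] <- stats::rnorm(v)  # stationary start
  out <- apply(innov, 2, function(e) as.numeric(stats::filter(e, phi,
                                                              "recursive")))
  matrix(out, n, v)
}

#' Simulate one session's 4D BOLD time series and motion trace
#'
#' Voxel time series are baseline intensity plus condition responses (boxcar
#' convolved with the canonical HRF, applied inside the contralateral
#' somatotopy field of each ROI) plus stationary AR(1) Gaussian noise whose
#' SD is set so baseline/SD equals the protocol's tSNR target. The response
#' amplitude per voxel is `amplitude_pct` of baseline plus `pattern_pct`
#' times a voxelwise pattern component; pattern components are drawn from
#' the scenario's pattern covariance so the acquisition-dependent similarity
#' structure survives end-to-end. The motion trace is a seeded random walk.
#'
#' @param protocol A [protocol_spec()].
#' @param events Event table from [make_paradigm()].
#' @param rois ROI set from [make_roi_masks()].
#' @param truth A [ground_truth()] scenario.
#' @param seed Integer seed.
#' @param patterns Optional named list (per ROI) of 9 x v_roi pattern
#'   matrices to reuse across subjects (group-level patterns); if `NULL`,
#'   patterns are drawn fresh from the scenario covariance.
#' @param baseline Baseline intensity (arbitrary units).
#' @return List with `image` ([volume_image()] 4D), `motion` (n_volumes x 6
#'   matrix: translations mm, rotations rad) and `patterns` (the pattern
#'   list used).
#' @export
simulate_timeseries <- function(protocol, events, rois, truth, seed = 1L,
                                patterns = NULL, baseline = 100) {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(truth, "ground_truth"))
  tr_s <- protocol$volume_tr_ms / 1000
  scan_dur <- protocol$n_volumes * tr_s
  if (max(events$onset + events$duration) > scan_dur)
    stop("events exceed scan duration (", round(scan_dur, 1), " s)")

  grid <- dim(rois$labels)
  v_all <- prod(grid)
  n_vol <- protocol$n_volumes
  tsnr <- truth$tsnr_target[[protocol$name]]
  if (is.null(tsnr)) stop("no tSNR target for protocol ", protocol$name)
  noise_sd <- baseline / tsnr

  # condition regressors at volume times (unit-peak HRF response)
  reg <- condition_regressors(events, protocol)

  with_seed(seed, {
    # per-ROI voxelwise pattern components (shared across subjects if passed)
    if (is.null(patterns)) {
      patterns <- lapply(seq_along(rois$names), function(k) {
        g <- truth$g_by_class[[roi_info(rois$names[k])$class]]
        simulate_patterns(g, v = sum(rois$labels == k), sigma2 = 0,
                          seed = stats::runif(1, 1, 2^30))
      })
      names(patterns) <- rois$names
    }

    # amplitude map per condition (intensity units)
    res_mm <- protocol$voxel_size
    amp <- matrix(0, v_all, length(condition_labels()))
    colnames(amp) <- condition_labels()
    for (cond in condition_labels()) {
      parts <- strsplit(cond, "_")[[1]]
      movement <- parts[1]; side <- parts[2]
      hemi <- if (side == "right") "L" else "R"  # contralateral
      cell <- cell_index(movement, res_mm)
      for (name in rois$names[endsWith(rois$names, paste0("_", hemi))]) {
        # mean response confined to the movement's somatotopy field; the
        # voxelwise pattern component spans the whole ROI so the cell-by-
        # cell covariance structure of the patterns is realized in the
        # betas (disjoint supports would zero all between-movement
        # covariances)
        field <- which(roi_condition_mask(rois, name, movement))
        roi_vox <- which(rois$labels == match(name, rois$names))
        u <- patterns[[name]][cell, ]
        amp[roi_vox, cond] <- baseline * truth$pattern_pct * u / 100
        amp[field, cond] <- amp[field, cond] +
          baseline * truth$amplitude_pct / 100
      }
    }

    signal <- reg %*% t(amp)                       # n_vol x v_all
    noise <- noise_sd * ar1_noise(n_vol, v_all, truth$ar1_phi)
    dat <- baseline + signal + noise
    img <- volume_image(array(t(dat), dim = c(grid, n_vol)), rois$affine)

    motion <- apply(matrix(stats::rnorm(n_vol * 6), n_vol, 6), 2, cumsum) *
      rep(c(0.02, 0.02, 0.02, 2e-4, 2e-4, 2e-4), each = n_vol)
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

    list(image = img, motion = motion, patterns = patterns)
  })
}

# HRF-convolved unit-peak boxcar regressors for each condition, sampled at
# volume acquisition times. Shared by the simulator and the design builder.
condition_regressors <- function(events, protocol, dt = 0.1,
                                 event_class = "active",
                                 conditions = condition_labels()) {
  tr_s <- protocol$volume_tr_ms / 1000
  scan_dur <- protocol$n_volumes * tr_s
  tgrid <- seq(0, scan_dur, by = dt)
  h <- canonical_hrf(dt)
  vol_t <- (seq_len(protocol$n_volumes) - 1) * tr_s
  sel <- events$event_class == event_class
  out <- sapply(conditions, function(cond) {
    box <- numeric(length(tgrid))
    ev <- events[sel & events$condition == cond, , drop = FALSE]
    for (i in seq_len(nrow(ev)))
      box[tgrid >= ev$onset[i] & tgrid < ev$onset[i] + ev$duration[i]] <- 1
    conv <- stats::convolve(box, rev(h), type = "open")[seq_along(tgrid)]
    stats::approx(tgrid, conv, xout = vol_t, rule = 2)$y
  })
  matrix(out, nrow = protocol$n_volumes,
         dimnames = list(NULL, conditions))
}
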