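# BOLD-sensitivity and data-quality metrics: residual tSNR, acquisition-
# weighted tSNR variants, top-5% t-scores, head-motion summaries and the
# scaled-variance image-quality metric.

#' Temporal signal-to-noise map after removing modeled effects
#'
#' tSNR per voxel = mean of the raw time series divided by the SD of the
#' residuals after regressing out the design (SD uses dof = n - rank(X)).
#' Voxels with zero residual SD get `NaN`; their count is reported via a
#' message.
#'
#' @param image4d 4D [volume_image()] or n x v matrix.
#' @param design A [build_design()] result or design matrix.
#' @return [volume_image()] (or vector for matrix input) of tSNR values.
#' @export
tsnr_map <- function(image4d, design) {
  Y <- as_data_matrix(image4d)
  fit <- fit_glm(Y, design)
  sd_res <- sqrt(fit$sigma2_hat)
  mu <- colMeans(Y)
  tsnr <- mu / sd_res
  bad <- sd_res <= 1e-10 * (abs(mu) + 1)  # numerically constant series
  if (any(bad)) {
    tsnr[bad] <- NaN
    message(sum(bad), " voxel(s) with zero residual SD set to NaN")
  }
  if (inherits(image4d, "volume_image")) {
    d <- dim(image4d$data)
    volume_image(array(tsnr, dim = d[1:3]), image4d$affine)
  } else tsnr
}

#' NaN-aware per-ROI means of a 3D map
#'
#' @param map 3D [volume_image()] or array.
#' @param rois An [roi_set()] on the same grid.
#' @return Named numeric vector of ROI means.
#' @export
roi_summary <- function(map, rois) {
  dat <- if (inherits(map, "volume_image")) map$data else map
  stopifnot(all(dim(dat) == dim(rois$labels)))
  out <- vapply(seq_along(rois$names), function(k) {
    vals <- dat[rois$labels == k]
    if (all(is.na(vals))) {
      warning("ROI ", rois$names[k], " is all-NaN")
      NaN
    } else mean(vals, na.rm = TRUE)
  }, numeric(1))
  names(out) <- rois$names
  out
}

#' Acquisition-weighted tSNR variants
#'
#' Comparing protocols with different volume TRs and volume counts requires
#' weighting: returns tSNR/sqrt(TR_volume in s), tSNR/sqrt(N), and the
#' autocorrelation-adjusted tSNR_s = tSNR * sqrt(N (1 - phi)/(1 + phi)),
#' the AR(1) effective-sample-size scaling.
#'
#' @param tsnr tSNR value(s).
#' @param protocol A [protocol_spec()].
#' @param phi Lag-1 residual autocorrelation, |phi| < 1.
#' @return List with `per_sqrt_tr`, `per_sqrt_n`, `scaled`.
#' @export
weighted_tsnr <- function(tsnr, protocol, phi = 0) {
  if (abs(phi) >= 1) stop("|phi| must be < 1")
  tr_s <- protocol$volume_tr_ms / 1000
  n <- protocol$n_volumes
  list(per_sqrt_tr = tsnr / sqrt(tr_s),
       per_sqrt_n = tsnr / sqrt(n),
       scaled = tsnr * sqrt(n * (1 - phi) / (1 + phi)))
}

#' Mean of the top 5% t-scores per ROI
#'
#' @param t_map 3D [volume_image()] or array of t-values.
#' @param rois An [roi_set()].
#' @param top Fraction of voxels to keep (default 0.05).
#' @return Named vector: mean of the ceiling(top * |ROI|) largest t-values
#'   per ROI.
#' @export
top5_tscores <- function(t_map, rois, top = 0.05) {
  dat <- if (inherits(t_map, "volume_image")) t_map$data else t_map
  out <- vapply(seq_along(rois$names), function(k) {
    vals <- dat[rois$labels == k]
    vals <- vals[is.finite(vals)]
    m <- ceiling(top * length(vals))
    if (m < 1) {
      warning("ROI ", rois$names[k], ": empty top-", top * 100, "% set")
      return(NaN)
    }
    mean(sort(vals, decreasing = TRUE)[seq_len(m)])
  }, numeric(1))
  names(out) <- rois$names
  out
}

#' Head-motion summary metrics
#'
#' Frame-to-frame translation displacement is the Euclidean norm of the
#' difference of consecutive translation triples; rotations are summarized
#' as the mean frame-to-frame rotation-vector magnitude in degrees.
#'
#' @param trace n_volumes x 6 matrix: 3 translations (mm), 3 rotations
#'   (rad).
#' @param threshold_mm Displacement threshold for the movement count.
#' @return List of class `motion_metrics`: `mean_translation`,
#'   `max_translation` (mm), `n_movements` (displacements above the
#'   threshold), `rotation_deg`.
#' @export
motion_metrics <- function(trace, threshold_mm = 0.5) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6) stop("motion trace must have 6 columns")
  if (nrow(trace) < 2) stop("motion trace needs at least 2 volumes")
  dtr <- diff(trace[, 1:3, drop = FALSE])
  drot <- diff(trace[, 4:6, drop = FALSE])
  disp <- sqrt(rowSums(dtr^2))
  rot <- sqrt(rowSums(drot^2)) * 180 / pi
  structure(list(mean_translation = mean(disp),
                 max_translation = max(disp),
                 n_movements = sum(disp > threshold_mm),
                 rotation_deg = mean(rot)),
            class = "motion_metrics")
}

#' Scaled signal variance between consecutive volumes
#'
#' Image-quality metric: for each consecutive volume pair, the mean squared
#' intensity difference divided by the squared global mean intensity;
#' invariant to global intensity rescaling.
#'
#' @param image4d 4D [volume_image()] or n x v matrix.
#' @return List with `series` (one value per volume pair) and `mean`.
#' @export
scaled_variance <- function(image4d) {
  Y <- as_data_matrix(image4d)
  if (nrow(Y) < 2) stop("need at least 2 volumes")
  g <- mean(Y)
  if (g == 0) stop("zero global mean intensity")
  d <- diff(Y)
  series <- rowMeans(d^2) / g^2
  list(series = series, mean = mean(series))
}

#' Scaled variance restricted to each condition's active blocks
#'
#' Assigns each volume pair to the condition whose active block contains
#' both acquisition times, and averages the scaled-variance series within
#' condition, giving one image-quality value per condition.
#'
#' @param image4d 4D [volume_image()] or n x v matrix.
#' @param events Event table.
#' @param protocol A [protocol_spec()].
#' @return Named vector of per-condition mean scaled variance.
#' @export
scaled_variance_by_condition <- function(image4d, events, protocol) {
  sv <- scaled_variance(image4d)
  tr_s <- protocol$volume_tr_ms / 1000
  t_pair <- (seq_along(sv$series) - 0.5) * tr_s  # midpoint of each pair
  act <- events[events$event_class == "active", , drop = FALSE]
  conds <- sort(unique(act$condition))
  out <- vapply(conds, function(cond) {
    ev <- act[act$condition == cond, , drop = FALSE]
    sel <- rep(FALSE, length(t_pair))
    for (i in seq_len(nrow(ev)))
      sel <- sel | (t_pair >= ev$onset[i] &
                      t_pair <= ev$onset[i] + ev$duration[i])
    if (!any(sel)) return(NaN)
    mean(sv$series[sel])
  }, numeric(1))
  names(out) <- conds
  out
}

#' Lag-1 autocorrelation of GLM residuals, averaged over voxels
#'
#' @param fit A [fit_glm()] result.
#' @return Scalar mean lag-1 autocorrelation.
#' @export
residual_lag1 <- function(fit) {
  R <- fit$residuals
  n <- nrow(R)
  num <- colSums(R[-1, , drop = FALSE] * R[-n, , drop = FALSE])
  den <- colSums(R^2)
  mean((num / den)[den > 0])
}
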