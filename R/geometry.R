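# Somatotopy geometry from statistical maps: thresholding, centers of
# mass, activation maxima, ROI-adjusted activation volumes, ordering
# checks and SVD projection onto ROI-specific principal axes.
#
# Axis semantics follow MNI convention: +X lateral-right, +Y anterior,
# +Z dorsal. "More dorsal" means larger Z; "more medial" means smaller |X|.
# All ordering checks use strict inequalities; ties fail.

voxel_to_world <- function(idx, affine) {
  # idx: m x 3 one-based array indices -> world mm (0-based voxel indices)
  idx <- matrix(idx, ncol = 3)
  t(affine %*% rbind(t(idx) - 1, 1))[, 1:3, drop = FALSE]
}

#' Threshold a t-map at an uncorrected one-sided level
#'
#' Keeps voxels with one-sided p(t; dof) < alpha, i.e. t above the
#' one-sided critical value (activation contrasts test positive BOLD
#' responses).
#'
#' @param t_map 3D [volume_image()] or array of t-values.
#' @param dof Degrees of freedom of the t statistics.
#' @param alpha Uncorrected significance level.
#' @return Logical array (or [volume_image()] of 0/1 for image input).
#' @export
threshold_tmap <- function(t_map, dof, alpha = 0.05) {
  stopifnot(dof >= 1)
  dat <- if (inherits(t_map, "volume_image")) t_map$data else t_map
  crit <- stats::qt(1 - alpha, df = dof)
  mask <- dat > crit
  mask[is.na(mask)] <- FALSE
  if (inherits(t_map, "volume_image"))
    volume_image(array(mask, dim(dat)), t_map$affine)
  else mask
}

#' Center of mass of a binary mask in world coordinates
#'
#' Unweighted mean of the suprathreshold voxels' world coordinates;
#' optionally weighted by a statistic map.
#'
#' @param mask Logical 3D array or [volume_image()].
#' @param affine Voxel-to-world affine (taken from the image if present).
#' @param weights Optional 3D array of voxel weights (e.g. t-values).
#' @return Length-3 world coordinate (mm); `NaN` triple with a warning for
#'   an empty mask.
#' @export
center_of_mass <- function(mask, affine = NULL, weights = NULL) {
  if (inherits(mask, "volume_image")) {
    if (is.null(affine)) affine <- mask$affine
    mask <- mask$data != 0
  }
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("empty mask: center of mass undefined")
    return(c(NaN, NaN, NaN))
  }
  if (is.null(affine)) affine <- diag(4)
  w <- if (is.null(weights)) rep(1, nrow(idx)) else weights[mask]
  xyz <- voxel_to_world(idx, affine)
  colSums(xyz * w) / sum(w)
}

#' World coordinate of the largest t-value within an ROI
#'
#' Ties are broken deterministically by the lowest linear voxel index.
#'
#' @param t_map 3D array or [volume_image()].
#' @param roi 3D logical ROI mask.
#' @param affine Voxel-to-world affine.
#' @return Length-3 world coordinate (mm).
#' @export
activation_maximum <- function(t_map, roi, affine = NULL) {
  if (inherits(t_map, "volume_image")) {
    if (is.null(affine)) affine <- t_map$affine
    t_map <- t_map$data
  }
  if (is.null(affine)) affine <- diag(4)
  lin <- which(roi)
  if (length(lin) == 0) stop("empty ROI")
  best <- lin[which.max(t_map[lin])]  # which.max: first (lowest) index wins
  idx <- arrayInd(best, dim(t_map))
  drop(voxel_to_world(idx, affine))
}

#' Activation volume adjusted for ROI size
#'
#' @param mask Suprathreshold logical array.
#' @param roi ROI logical array.
#' @return |mask intersect ROI| / |ROI|, in [0, 1].
#' @export
adjusted_volume <- function(mask, roi) {
  if (inherits(mask, "volume_image")) mask <- mask$data != 0
  n_roi <- sum(roi)
  if (n_roi == 0) stop("empty ROI")
  sum(mask & roi) / n_roi
}

#' Is the hand representation between foot and face?
#'
#' Per axis, flags strict betweenness of the hand coordinate; the any-axis
#' flag is their OR ("in between ... in at least one spatial dimension").
#'
#' @param com_foot,com_hand,com_face Length-3 world coordinates.
#' @return List with `per_axis` (named logical, X/Y/Z) and `any_axis`;
#'   `NA`s when any input coordinate is missing.
#' @export
betweenness_check <- function(com_foot, com_hand, com_face) {
  if (anyNA(c(com_foot, com_hand, com_face)) ||
      any(!is.finite(c(com_foot, com_hand, com_face)))) {
    per <- c(X = NA, Y = NA, Z = NA)
    return(list(per_axis = per, any_axis = NA))
  }
  per <- vapply(1:3, function(a) {
    lo <- min(com_foot[a], com_face[a]); hi <- max(com_foot[a], com_face[a])
    lo < com_hand[a] && com_hand[a] < hi
  }, logical(1))
  names(per) <- c("X", "Y", "Z")
  list(per_axis = per, any_axis = any(per))
}

#' Expected somatotopic gradient per structure
#'
#' Editable table mapping each structure to the axis and sign of the
#' expected foot-minus-face difference: dorsal-to-ventral body-part
#' gradients in M1, putamen and pallidum (foot more dorsal: positive Z),
#' posterior-to-anterior in the SMA (foot more posterior: negative Y), and
#' lateral-to-medial in the thalamus (foot more lateral: larger |X|, axis
#' `absX`).
#'
#' @return Data frame with columns `structure`, `axis` (`X`, `Y`, `Z`,
#'   `absX`), `sign` (+1/-1 expected sign of foot - face).
#' @export
somatotopy_expectations <- function() {
  data.frame(structure = c("M1", "SMA", "putamen", "pallidum", "thalamus"),
             axis = c("Z", "Y", "Z", "Z", "absX"),
             sign = c(1, -1, 1, 1, 1))
}

#' Check the expected direction of the foot-face gradient
#'
#' @param coms Named list of length-3 world coordinates with entries
#'   `foot` and `face`.
#' @param roi_name ROI name (hemisphere suffix allowed, e.g.
#'   `"putamen_L"`).
#' @param expectations Expectation table, see [somatotopy_expectations()].
#' @return `TRUE` iff the foot-minus-face difference on the expected axis
#'   has the expected sign (strict).
#' @export
direction_check <- function(coms, roi_name,
                            expectations = somatotopy_expectations()) {
  struct <- roi_info(roi_name)$structure
  row <- expectations[expectations$structure == struct, , drop = FALSE]
  if (nrow(row) == 0) stop("no expectation for structure ", struct)
  ax <- row$axis[1]
  val <- function(v) switch(ax, X = v[1], Y = v[2], Z = v[3],
                            absX = abs(v[1]))
  diff <- val(coms$foot) - val(coms$face)
  is.finite(diff) && (diff * row$sign[1] > 0)
}

#' Project centers of mass onto ROI-specific principal axes
#'
#' Centers the coordinate rows, takes the SVD of the centered matrix and
#' projects onto the right-singular vectors ordered by singular value; the
#' somatotopic gradient then lives in a scale- and direction-normalized
#' frame per ROI. Sign convention: each axis is flipped so its largest-
#' magnitude loading is positive.
#'
#' @param coms m x 3 matrix of world coordinates (typically 9 rows: body
#'   part x resolution).
#' @return List with `projected` (m x 3), `axes` (3 x 3 orthonormal, one
#'   axis per column), `singular_values`, `center`.
#' @export
principal_axis_projection <- function(coms) {
  coms <- as.matrix(coms)
  stopifnot(ncol(coms) == 3)
  if (nrow(unique(coms)) < 2) stop("need at least 2 distinct points")
  ctr <- colMeans(coms)
  Xc <- sweep(coms, 2, ctr)
  sv <- svd(Xc)
  V <- sv$v
  for (j in 1:3) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(projected = Xc %*% V, axes = V, singular_values = sv$d, center = ctr)
}
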