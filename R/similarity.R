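# Index of Similarity: pattern correlations from the fitted covariance,
# IoS = |atanh(r)|, Z-tests on the Fisher-z scale and per-family FDR.

#' Normalize a pattern covariance to a correlation matrix
#'
#' r_ij = G_ij / sqrt(G_ii G_jj), making variance and covariance estimates
#' comparable across body parts, resolutions and ROIs. Off-diagonal values
#' are clipped to +/-(1 - 1e-12) so the Fisher transform stays finite.
#'
#' @param g p x p covariance with strictly positive diagonal.
#' @return p x p correlation matrix with unit diagonal.
#' @export
normalize_covariance <- function(g) {
  d <- diag(g)
  if (any(d <= 0))
    stop("zero/negative variance for cell(s): ",
         paste(which(d <= 0), collapse = ", "))
  r <- g / sqrt(outer(d, d))
  clip <- 1 - 1e-12
  off <- row(r) != col(r)
  r[off] <- pmin(pmax(r[off], -clip), clip)
  diag(r) <- 1
  r
}

#' Index of Similarity
#'
#' IoS = |atanh(r)| = |0.5 log((1+r)/(1-r))|: the absolute Fisher
#' z-transformed pattern correlation. Low IoS means high segregation
#' between representations; high IoS means high similarity. |r| >= 1 is
#' clipped with a warning.
#'
#' @param r Correlation value(s).
#' @return Non-negative IoS value(s).
#' @export
ios <- function(r) {
  clip <- 1 - 1e-12
  if (any(abs(r) >= 1)) {
    warning("|r| >= 1 clipped to ", format(clip))
    r <- pmin(pmax(r, -clip), clip)
  }
  abs(atanh(r))
}

#' Z-test for the difference of two Fisher-z similarities
#'
#' Tests z_a - z_b on the signed Fisher-z scale with the large-sample
#' standard error sqrt(2/(n_eff - 3)); two-sided p from the standard
#' normal. Absolute values (IoS) are applied only for reporting, since a
#' difference of absolute values has no standard null distribution.
#'
#' @param z_a,z_b Signed Fisher-z values.
#' @param n_eff Effective sample size (> 3); by convention the ROI voxel
#'   count, a documented approximation since smoothing correlates voxels.
#' @return List with `z` and `p`.
#' @export
z_test_pair_difference <- function(z_a, z_b, n_eff) {
  if (n_eff <= 3) stop("n_eff must exceed 3")
  z <- (z_a - z_b) / sqrt(2 / (n_eff - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' One-sample Z-test of a Fisher-z similarity against zero
#'
#' @inheritParams z_test_pair_difference
#' @param z_val Signed Fisher-z value.
#' @return List with `z` and `p`.
#' @export
z_test_value <- function(z_val, n_eff) {
  if (n_eff <= 3) stop("n_eff must exceed 3")
  z <- z_val / sqrt(1 / (n_eff - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: reject all p <= p_(k*) with k* = max{k : p_(k) <=
#' k q / m}. Adjusted q-values come from the cumulative-minimum
#' construction (equivalently `p.adjust(method = "BH")`).
#'
#' @param p_values Vector of p-values in [0, 1].
#' @param q Target FDR level.
#' @return List with `reject` (logical) and `q_values`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p_values, method = "BH")
  list(reject = !is.na(qv) & qv <= q, q_values = qv)
}

#' Similarity report for one fitted pattern component model
#'
#' Emits the two IoS families of the movement-by-resolution factorial:
#' (i) the 9 within-resolution movement pairs and (ii) the 9
#' within-movement cross-resolution pairs. Each family carries per-pair
#' one-sample Z-tests of the similarity against zero, Z-tests of all
#' pairwise differences between same-`pair`/same-`group` members within the
#' family, and FDR correction applied to each family separately.
#'
#' @param fit A `pcm_fit` for the 9-cell factorial.
#' @param n_eff Effective sample size for Z-tests (ROI voxel count).
#' @param cells Cell metadata, default [factorial_cells()].
#' @param roi ROI label carried into the output tables.
#' @param q FDR level.
#' @return List of class `similarity_result`: `r` (9 x 9 correlations),
#'   `values` (18-row data frame: one row per pair with `r`, `ios`, `z`,
#'   `p`, `q_value`, `significant`), `contrasts` (difference tests between
#'   pairs within each family).
#' @export
similarity_report <- function(fit, n_eff, cells = factorial_cells(),
                              roi = NA_character_, q = 0.05) {
  stopifnot(inherits(fit, "pcm_fit"))
  if (!isTRUE(fit$converged))
    warning("similarity report from a non-converged fit")
  r <- normalize_covariance(fit$g_hat)

  fam_values <- function(family) {
    pr <- cell_pairs(family)
    rv <- r[cbind(pr$cell_a, pr$cell_b)]
    zt <- z_test_value(atanh(rv), n_eff)
    data.frame(roi = roi, family = family, group = pr$group, pair = pr$pair,
               cell_a = pr$cell_a, cell_b = pr$cell_b,
               r = rv, fisher_z = atanh(rv), ios = ios(rv),
               z = zt$z, p = zt$p)
  }
  values <- rbind(fam_values("within_resolution"),
                  fam_values("within_movement"))
  values$q_value <- NA_real_
  values$significant <- NA
  for (fam in unique(values$family)) {
    i <- values$family == fam
    bh <- fdr_bh(values$p[i], q)
    values$q_value[i] <- bh$q_values
    values$significant[i] <- bh$reject
  }

  # difference tests: within each family, compare the same movement pair
  # across resolutions (family i) or the same resolution pair across
  # movements (family ii)
  contrasts <- NULL
  for (fam in unique(values$family)) {
    vf <- values[values$family == fam, ]
    for (pr in unique(vf$pair)) {
      sub <- vf[vf$pair == pr, ]
      if (nrow(sub) < 2) next
      cmb <- utils::combn(nrow(sub), 2)
      for (j in seq_len(ncol(cmb))) {
        a <- sub[cmb[1, j], ]; b <- sub[cmb[2, j], ]
        zt <- z_test_pair_difference(a$fisher_z, b$fisher_z, n_eff)
        contrasts <- rbind(contrasts, data.frame(
          roi = roi, family = fam, pair = pr,
          group_a = a$group, group_b = b$group,
          ios_a = a$ios, ios_b = b$ios, z = zt$z, p = zt$p))
      }
    }
  }
  contrasts$q_value <- NA_real_
  contrasts$significant <- NA
  for (fam in unique(contrasts$family)) {
    i <- contrasts$family == fam
    bh <- fdr_bh(contrasts$p[i], q)
    contrasts$q_value[i] <- bh$q_values
    contrasts$significant[i] <- bh$reject
  }
  structure(list(r = r, values = values, contrasts = contrasts,
                 n_eff = n_eff, converged = fit$converged),
            class = "similarity_result")
}
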