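# Subject-level general linear model: canonical-HRF design construction,
# per-voxel ordinary least squares, differential contrasts and t-maps.

#' Canonical double-gamma haemodynamic response function
#'
#' The conventional double-gamma HRF (response delay 6 s, undershoot delay
#' 16 s, dispersions 1, undershoot ratio 1/6, 32 s support), sampled at
#' `dt` and scaled to unit peak. Peak lands near 5 s.
#'
#' @param dt Sampling interval in seconds.
#' @param duration Kernel support in seconds.
#' @return Numeric vector of kernel samples starting at t = 0.
#' @export
canonical_hrf <- function(dt = 0.1, duration = 32) {
  stopifnot(dt > 0)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build a GLM design matrix for one session
#'
#' One HRF-convolved boxcar regressor per movement condition (6), a single
#' pooled preparation-period regressor, six motion covariates and an
#' intercept: k = 14 columns under the default paradigm. Condition
#' regressors are built on a fine time grid and sampled at volume
#' acquisition times. Rank deficiency is reported with the names of the
#' collinear columns.
#'
#' @param events Event table from [make_paradigm()].
#' @param protocol A [protocol_spec()].
#' @param motion Optional n_volumes x 6 motion-parameter matrix.
#' @param drift Number of cosine drift columns to append (0 = none).
#' @return An object of class `design_matrix`: list with `X`,
#'   `condition_columns`, `nuisance_columns`.
#' @export
build_design <- function(events, protocol, motion = NULL, drift = 0L) {
  tr_s <- protocol$volume_tr_ms / 1000
  if (max(events$onset + events$duration) > protocol$n_volumes * tr_s)
    stop("events exceed scan duration")
  conds <- sort(unique(events$condition[events$event_class == "active"]))
  X <- condition_regressors(events, protocol, conditions = conds)

  # pooled preparation regressor
  ev_prep <- events
  ev_prep$condition[ev_prep$event_class == "prep"] <- "prep"
  prep <- condition_regressors(ev_prep, protocol, event_class = "prep",
                               conditions = "prep")
  X <- cbind(X, prep = prep[, 1])

  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != protocol$n_volumes)
      stop("motion trace length does not match n_volumes")
    colnames(motion) <- paste0("motion", 1:6)
    X <- cbind(X, motion)
  }
  if (drift > 0) {
    n <- protocol$n_volumes
    dr <- sapply(seq_len(drift), function(j)
      cos(pi * j * (seq_len(n) - 0.5) / n))
    colnames(dr) <- paste0("drift", seq_len(drift))
    X <- cbind(X, dr)
  }
  X <- cbind(X, intercept = 1)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("design matrix is rank deficient; collinear columns: ",
            paste(dropped, collapse = ", "))
  }
  structure(list(X = X,
                 condition_columns = match(conds, colnames(X)),
                 nuisance_columns = setdiff(seq_len(ncol(X)),
                                            match(conds, colnames(X)))),
            class = "design_matrix")
}

as_data_matrix <- function(image4d) {
  if (inherits(image4d, "volume_image")) {
    d <- dim(image4d$data)
    stopifnot(length(d) == 4L)
    t(matrix(image4d$data, prod(d[1:3]), d[4]))
  } else {
    as.matrix(image4d)
  }
}

#' Fit the GLM per voxel by ordinary least squares
#'
#' @param image4d A 4D [volume_image()] or an n_volumes x v data matrix.
#' @param design A [build_design()] result or a plain design matrix.
#' @return An object of class `glm_fit`: `betas` (k x v), `residuals`
#'   (n x v), `dof`, `sigma2_hat` (per-voxel residual variance), `design`.
#' @export
fit_glm <- function(image4d, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as_data_matrix(image4d)
  if (nrow(Y) != nrow(X))
    stop("volume count mismatch: data has ", nrow(Y), ", design has ", nrow(X))
  fit <- stats::lm.fit(X, Y)
  betas <- fit$coefficients
  if (is.null(dim(betas))) betas <- matrix(betas, ncol = 1)
  betas[is.na(betas)] <- 0
  res <- as.matrix(fit$residuals)
  dof <- nrow(X) - fit$rank
  structure(list(betas = betas, residuals = res, dof = dof,
                 sigma2_hat = colSums(res^2) / dof,
                 rank = fit$rank,
                 design = if (inherits(design, "design_matrix")) design
                          else structure(list(X = X), class = "design_matrix")),
            class = "glm_fit")
}

#' The six differential movement contrasts
#'
#' One contrast per (body part x side) condition, weighting its regressor
#' +1 against the implicit resting baseline (all other columns 0).
#'
#' @param design A [build_design()] result.
#' @return Named list of length-k contrast vectors.
#' @export
differential_contrasts <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  k <- ncol(design$X)
  conds <- colnames(design$X)[design$condition_columns]
  missing <- setdiff(condition_labels(), conds)
  if (length(missing))
    stop("missing condition column(s): ", paste(missing, collapse = ", "))
  out <- lapply(conds, function(cn) {
    cvec <- numeric(k)
    cvec[match(cn, colnames(design$X))] <- 1
    names(cvec) <- colnames(design$X)
    cvec
  })
  names(out) <- conds
  out
}

#' Contrast effect and t statistic per voxel
#'
#' t = c'beta / sqrt(sigma2_hat * c'(X'X)^-1 c).
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Length-k contrast vector.
#' @param grid_shape Optional 3-vector to reshape the maps to volumes.
#' @param affine Affine for reshaped output.
#' @return List with `effect`, `t` (vectors, or [volume_image()]s when
#'   `grid_shape` is given) and `dof`.
#' @export
contrast_tmap <- function(fit, contrast, grid_shape = NULL, affine = diag(4)) {
  stopifnot(inherits(fit, "glm_fit"))
  X <- fit$design$X
  cvec <- as.numeric(contrast)
  stopifnot(length(cvec) == ncol(X))
  effect <- drop(crossprod(cvec, fit$betas))
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(fit$sigma2_hat * drop(crossprod(cvec, xtx_inv %*% cvec)))
  tval <- effect / se
  if (!is.null(grid_shape)) {
    effect <- volume_image(array(effect, dim = grid_shape), affine)
    tval <- volume_image(array(tval, dim = grid_shape), affine)
  }
  list(effect = effect, t = tval, dof = fit$dof)
}
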