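# Pattern component model Y = Z U + E. Columns of U (one per voxel) are
# zero-mean Gaussian with p x p covariance G; E is iid Gaussian noise with
# shared variance sigma2. Marginally each voxel's profile y_j ~ N(0, V),
# V = Z G Z' + sigma2 I. G and sigma2 are estimated by EM on the marginal
# likelihood; a direct numerical maximizer serves as an independent check.

#' Construct a condition-by-voxel beta matrix for pattern analysis
#'
#' @param y n x v matrix of regression coefficients (rows = factorial
#'   cells/trials, columns = voxels). Columns that are entirely `NaN`/`NA`
#'   (masked voxels) are dropped.
#' @param cells Row metadata, default [factorial_cells()].
#' @param roi ROI label.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(y, cells = factorial_cells(), roi = NA_character_) {
  y <- as.matrix(y)
  all_na <- colSums(!is.na(y)) == 0
  if (any(all_na)) y <- y[, !all_na, drop = FALSE]
  if (anyNA(y)) stop("beta matrix contains partially missing voxels")
  if (ncol(y) < nrow(y))
    warning("fewer voxels (", ncol(y), ") than rows (", nrow(y),
            "); covariance estimates will be rank deficient")
  structure(list(y = y, cells = cells, roi = roi), class = "beta_matrix")
}

as_beta <- function(y) if (inherits(y, "beta_matrix")) y$y else as.matrix(y)

#' Marginal log-likelihood of a pattern model
#'
#' Sum over voxels of log N(y_j; 0, V) with V = Z G Z' + sigma2 I, computed
#' as -(v/2) (n log 2 pi + log|V| + tr(V^-1 S)) where S = Y Y'/v.
#'
#' @param y Beta matrix (n x v) or [beta_matrix()].
#' @param z n x p design matrix.
#' @param g p x p pattern covariance.
#' @param sigma2 Noise variance.
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(y, z, g, sigma2) {
  Y <- as_beta(y)
  n <- nrow(Y); v <- ncol(Y)
  V <- z %*% g %*% t(z) + sigma2 * diag(n)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("V = ZGZ' + sigma2*I is singular (min eigenvalue ",
         signif(min(ev), 3), ")")
  S <- tcrossprod(Y) / v
  cV <- chol(V)
  logdet <- 2 * sum(log(diag(cV)))
  tr_vis <- sum(diag(chol2inv(cV) %*% S))
  -(v / 2) * (n * log(2 * pi) + logdet + tr_vis)
}

pcm_init <- function(Y, z) {
  v <- ncol(Y)
  S <- tcrossprod(Y) / v
  # project Y onto the column space of Z; residual variance seeds sigma2
  zp <- solve(crossprod(z), t(z))
  R <- Y - z %*% (zp %*% Y)
  rv <- sum(R^2) / (nrow(Y) * v)
  Su <- zp %*% S %*% t(zp)
  if (rv > 1e-8 * mean(Y^2)) {
    sigma2 <- rv / 2
    g0 <- diag(pmax(diag(Su), 1e-6), nrow(Su))
  } else {
    # saturated design (Z spans the row space): sigma2 and diag(G) are
    # confounded along the flat ridge ZGZ' + sigma2 I = S, and EM stays
    # near its starting point on it. Break the tie toward the maximal-
    # noise solution: attribute the smallest marginal eigenvalue to iid
    # noise, the parsimonious reading of "patterns plus iid error".
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    sigma2 <- max(min(ev), 1e-6)
    g0 <- diag(pmax(diag(Su) - sigma2, 1e-6), nrow(Su))
  }
  list(g = g0, sigma2 = sigma2)
}

#' Fit the pattern component model by expectation-maximization
#'
#' E-step: conditional mean and covariance of U given Y under the current
#' (G, sigma2). M-step: G becomes the voxel-average conditional second
#' moment of U; sigma2 the average conditional residual second moment.
#' Iterates until the relative log-likelihood increment falls below `tol`.
#' At exit G is projected onto the PSD cone by eigenvalue clipping (never
#' inside the iteration, which would break the ascent property).
#'
#' @param y Beta matrix (n x v) or [beta_matrix()].
#' @param z n x p design matrix, full column rank (default identity).
#' @param init Optional list with `g`, `sigma2` starting values.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @param sigma2_fixed If non-`NULL`, the noise variance is held at this
#'   value instead of being estimated.
#' @return An object of class `pcm_fit`: `g_hat`, `sigma2_hat`,
#'   `loglik_trace`, `n_iter`, `converged`.
#' @export
fit_pcm_em <- function(y, z = NULL, init = NULL, tol = 1e-6,
                       max_iter = 1000L, sigma2_fixed = NULL) {
  Y <- as_beta(y)
  n <- nrow(Y); v <- ncol(Y)
  if (v < 2) stop("need at least 2 voxels")
  if (is.null(z)) z <- diag(n)
  p <- ncol(z)
  if (qr(z)$rank < p) stop("Z must have full column rank")
  if (is.null(init)) init <- pcm_init(Y, z)
  G <- init$g
  sigma2 <- if (is.null(sigma2_fixed)) init$sigma2 else sigma2_fixed

  trace <- numeric(0)
  converged <- FALSE
  In <- diag(n)
  for (it in seq_len(max_iter)) {
    V <- z %*% G %*% t(z) + sigma2 * In
    cV <- tryCatch(chol(V), error = function(e)
      stop("V became singular at iteration ", it))
    Vi <- chol2inv(cV)
    ll <- {
      S <- tcrossprod(Y) / v
      -(v / 2) * (n * log(2 * pi) + 2 * sum(log(diag(cV))) + sum(Vi * S))
    }
    if (!is.finite(ll)) stop("non-finite log-likelihood at iteration ", it)
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - trace[it - 1]) <
        tol * (abs(trace[it - 1]) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    # E-step
    GZt <- G %*% t(z)
    W <- GZt %*% Vi                      # p x n
    U_hat <- W %*% Y                     # conditional means, p x v
    Sig_u <- G - W %*% t(GZt)            # conditional covariance, p x p
    # M-step
    G <- tcrossprod(U_hat) / v + Sig_u
    G <- (G + t(G)) / 2
    if (is.null(sigma2_fixed)) {
      R <- Y - z %*% U_hat
      sigma2 <- (sum(R^2) / v + sum(diag(z %*% Sig_u %*% t(z)))) / n
      sigma2 <- max(sigma2, 1e-12)
    }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")
  # PSD repair at exit only
  e <- eigen(G, symmetric = TRUE)
  if (min(e$values) < 0)
    G <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  structure(list(g_hat = (G + t(G)) / 2, sigma2_hat = sigma2,
                 loglik_trace = trace, n_iter = length(trace),
                 converged = converged),
            class = "pcm_fit")
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat("<pcm_fit> p =", nrow(x$g_hat), "| sigma2 =", signif(x$sigma2_hat, 4),
      "| loglik =", signif(utils::tail(x$loglik_trace, 1), 8),
      "|", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Fit the pattern component model by direct numerical maximization
#'
#' Independent check on the EM estimator: maximizes the same marginal
#' log-likelihood by quasi-Newton optimization over a Cholesky
#' parameterization of G and log sigma2. Practical for small p (the
#' parameter count grows as p(p+1)/2 + 1).
#'
#' @inheritParams fit_pcm_em
#' @return A `pcm_fit` (with a length-1 `loglik_trace`).
#' @export
fit_pcm_direct <- function(y, z = NULL, init = NULL) {
  Y <- as_beta(y)
  n <- nrow(Y); v <- ncol(Y)
  if (is.null(z)) z <- diag(n)
  p <- ncol(z)
  if (is.null(init)) init <- pcm_init(Y, z)
  S <- tcrossprod(Y) / v
  In <- diag(n)
  ltri <- lower.tri(matrix(0, p, p), diag = TRUE)

  theta_to_L <- function(theta) {
    L <- matrix(0, p, p)
    L[ltri] <- theta[seq_len(sum(ltri))]
    diag(L) <- exp(diag(L))  # positive diagonal via log parameterization
    L
  }
  negll <- function(theta) {
    L <- theta_to_L(theta)
    sigma2 <- exp(theta[length(theta)])
    V <- z %*% tcrossprod(L) %*% t(z) + sigma2 * In
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(1e12)
    ll <- -(v / 2) * (n * log(2 * pi) + 2 * sum(log(diag(cV))) +
                        sum(chol2inv(cV) * S))
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  make_theta <- function(g, sigma2) {
    L0 <- t(chol(g + 1e-8 * diag(p)))
    start <- L0
    diag(start) <- log(diag(L0))
    c(start[ltri], log(sigma2))
  }
  # method-of-moments second start: projected sample second moment of U
  # (independent of the EM path), minus the residual-variance guess
  zp <- solve(crossprod(z), t(z))
  Su <- zp %*% S %*% t(zp)
  e <- eigen((Su + t(Su)) / 2, symmetric = TRUE)
  Su_pd <- e$vectors %*% (pmax(e$values, 1e-4) * t(e$vectors))
  starts <- list(make_theta(init$g, init$sigma2),
                 make_theta(Su_pd, max(init$sigma2, 1e-3)))
  # the log-diagonal Cholesky parameterization can trap quasi-Newton runs
  # at a rank-deficient boundary; jittered restarts guard against it
  jit <- with_seed(131 * n + p, lapply(1:3, function(j)
    stats::rnorm(length(starts[[1]]), sd = 0.3)))
  for (j in 1:3) starts[[2 + j]] <- starts[[1]] + jit[[j]]
  opt <- NULL
  for (theta0 in starts) {
    o <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (o$convergence %in% c(0L, 1L)) {
      # one polishing restart resets the Hessian approximation
      o2 <- stats::optim(o$par, negll, method = "BFGS",
                         control = list(maxit = 2000, reltol = 1e-12))
      if (o2$value <= o$value) o <- o2
      if (is.null(opt) || o$value < opt$value) opt <- o
    }
  }
  if (is.null(opt))
    stop("direct optimizer failed on all starts")
  L <- theta_to_L(opt$par)
  G <- tcrossprod(L)
  degenerate <- sum(diag(G)) < 1e-8 * max(1, sum(diag(S)))
  structure(list(g_hat = G, sigma2_hat = exp(opt$par[length(opt$par)]),
                 loglik_trace = -opt$value, n_iter = opt$counts[["function"]],
                 converged = opt$convergence == 0L, degenerate = degenerate),
            class = "pcm_fit")
}

#' Fit one pattern component model per ROI
#'
#' @param betas Named list of [beta_matrix()] objects (or plain matrices).
#' @param z Shared design matrix (default identity).
#' @param ... Passed to [fit_pcm_em()].
#' @return Named list of `pcm_fit` objects; empty ROIs are skipped with a
#'   warning.
#' @export
fit_per_roi <- function(betas, z = NULL, ...) {
  stopifnot(length(betas) >= 1)
  out <- list()
  for (name in names(betas)) {
    Y <- as_beta(betas[[name]])
    if (is.null(Y) || ncol(Y) == 0) {
      warning("ROI ", name, " is empty; skipped")
      next
    }
    out[[name]] <- fit_pcm_em(Y, z = z, ...)
  }
  out
}
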