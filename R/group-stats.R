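# Group-level statistics relating segregation (IoS), BOLD sensitivity
# (tSNR) and geometry: correlations, ANCOVA with interaction and nested
# model comparison, MANOVA with Pillai's trace, and 1-/2-way ANOVAs with
# Bonferroni-Holm post hocs. Factorial sums of squares are Type II (the
# car convention); the resolution factor uses treatment coding with the
# 1.5 mm level as reference.

#' Pearson and Spearman correlation with tests
#'
#' @param x,y Paired numeric vectors (n >= 4, finite, non-constant).
#' @return List with `pearson` (`r`, `p`) and `spearman` (`rho`, `p`);
#'   Spearman p-values use the t-approximation.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  pe <- stats::cor.test(x, y, method = "pearson")
  # rank transform then Pearson machinery = Spearman with t-approximation
  sp <- stats::cor.test(rank(x), rank(y), method = "pearson")
  list(pearson = list(r = unname(pe$estimate), p = pe$p.value),
       spearman = list(rho = unname(sp$estimate), p = sp$p.value))
}

resolution_factor <- function(resolution) {
  f <- factor(paste0(as.character(resolution), "mm"),
              levels = paste0(as.character(sort(unique(resolution))), "mm"))
  stats::relevel(f, ref = levels(f)[1])
}

#' ANCOVA of segregation on BOLD sensitivity and resolution
#'
#' Fits IoS ~ tSNR + resolution + tSNR:resolution by least squares with
#' treatment coding, reports Type-II F tests per term, the nested model
#' comparison against IoS ~ tSNR (does resolution add anything beyond
#' sensitivity?), and per-level simple-slope F tests of the tSNR effect
#' (the planned post hocs), all on the full model's error.
#'
#' @param ios Numeric response (Index of Similarity per observation unit).
#' @param tsnr Numeric covariate.
#' @param resolution Resolution labels (3-level factor after coding).
#' @return List of class `ancova_result`: `terms` (data frame with F, df,
#'   p per term), `model_comparison` (`F`, `df1`, `df2`, `p`),
#'   `simple_slopes`, `r_squared`, `adj_r_squared`, `model`.
#' @export
ancova_ios <- function(ios, tsnr, resolution) {
  res <- resolution_factor(resolution)
  if (any(table(res) < 2)) stop("need >= 2 observations per level")
  dat <- data.frame(ios = ios, tsnr = tsnr, resolution = res)
  full <- stats::lm(ios ~ tsnr * resolution, data = dat)
  if (any(is.na(stats::coef(full))))
    stop("singular design; aliased terms: ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "))
  av <- car::Anova(full, type = 2)
  terms_df <- data.frame(term = rownames(av), sum_sq = av$`Sum Sq`,
                         df = av$Df, F = av$`F value`, p = av$`Pr(>F)`)
  reduced <- stats::lm(ios ~ tsnr, data = dat)
  cmp <- stats::anova(reduced, full)
  # overall model fit against the intercept-only model
  fit_f <- summary(full)$fstatistic
  slopes <- simple_slopes(full, dat)
  structure(list(
    terms = terms_df,
    model_comparison = list(F = cmp$F[2], df1 = cmp$Df[2],
                            df2 = cmp$Res.Df[2], p = cmp$`Pr(>F)`[2]),
    model_fit = list(F = unname(fit_f[1]), df1 = unname(fit_f[2]),
                     df2 = unname(fit_f[3]),
                     p = stats::pf(fit_f[1], fit_f[2], fit_f[3],
                                   lower.tail = FALSE)),
    simple_slopes = slopes,
    r_squared = summary(full)$r.squared,
    adj_r_squared = summary(full)$adj.r.squared,
    reduced_r_squared = summary(reduced)$r.squared,
    model = full), class = "ancova_result")
}

simple_slopes <- function(full, dat) {
  levs <- levels(dat$resolution)
  out <- NULL
  for (lev in levs) {
    hyp <- if (lev == levs[1]) "tsnr = 0"
           else paste0("tsnr + tsnr:resolution", lev, " = 0")
    lh <- car::linearHypothesis(full, hyp)
    out <- rbind(out, data.frame(level = lev, F = lh$F[2], df1 = lh$Df[2],
                                 df2 = lh$Res.Df[2], p = lh$`Pr(>F)`[2]))
  }
  out
}

#' MANOVA on center-of-mass coordinates
#'
#' Multivariate test of body part and resolution effects (and their
#' interaction) on 3D coordinates, with Pillai's trace
#' tr(H (H + E)^-1) per term and its standard F approximation.
#'
#' @param coords m x 3 matrix of coordinates (world mm or projected).
#' @param body_part Factor of body-part labels.
#' @param resolution Factor/levels of resolution.
#' @return Data frame with one row per term: `pillai`, `approx_F`, `df1`,
#'   `df2`, `p`.
#' @export
manova_coords <- function(coords, body_part, resolution) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(body_part),
            length(body_part) == length(resolution))
  dat <- data.frame(bp = factor(body_part), res = factor(resolution))
  mod <- stats::lm(coords ~ bp * res, data = dat)
  av <- tryCatch(car::Anova(mod, type = 2, test.statistic = "Pillai"),
                 error = function(e) stop("MANOVA failed: ",
                                          conditionMessage(e)))
  s <- summary(av)$multivariate.tests
  out <- NULL
  for (term in names(s)) {
    st <- s[[term]]
    H <- st$SSPH; E <- st$SSPE
    pillai <- sum(diag(H %*% solve(H + E)))
    # Pillai-to-F approximation
    p_dim <- ncol(coords); q <- st$df
    df_res <- st$df.residual
    ss <- min(p_dim, q)
    m <- (abs(p_dim - q) - 1) / 2
    nn <- (df_res - p_dim - 1) / 2
    df1 <- ss * (2 * m + ss + 1)
    df2 <- ss * (2 * nn + ss + 1)
    Fval <- (pillai / (ss - pillai)) * (df2 / df1)
    out <- rbind(out, data.frame(
      term = term, pillai = pillai, approx_F = Fval, df1 = df1, df2 = df2,
      p = stats::pf(Fval, df1, df2, lower.tail = FALSE)))
  }
  out
}

#' One- or two-way ANOVA with Bonferroni-Holm post hocs
#'
#' One factor: standard decomposition. Two factors: Type-II sums of
#' squares with interaction. Post hocs are pairwise single-df F contrasts
#' between levels of each factor, tested on the full model's error and
#' Holm-adjusted within factor.
#'
#' @param y Numeric response.
#' @param f1 First factor.
#' @param f2 Optional second factor.
#' @return List of class `anova_result`: `terms`, `posthoc` (per factor:
#'   pairwise F, raw and Holm-adjusted p), `r_squared`, `adj_r_squared`,
#'   `model`.
#' @export
anova_oneway_twoway <- function(y, f1, f2 = NULL) {
  f1 <- factor(f1)
  if (nlevels(f1) < 2) stop("factor must have >= 2 levels")
  # F tests are invariant to affine rescaling of the response; standardize
  # so responses on extreme scales do not trip numerical-tolerance checks
  if (stats::sd(y) > 0) y <- (y - mean(y)) / stats::sd(y)
  if (is.null(f2)) {
    dat <- data.frame(y = y, f1 = f1)
    mod <- stats::lm(y ~ f1, data = dat)
    av <- stats::anova(mod)
    terms_df <- data.frame(term = rownames(av), sum_sq = av$`Sum Sq`,
                           df = av$Df, F = av$`F value`, p = av$`Pr(>F)`)
    ph <- list(f1 = pairwise_f(mod, "f1", f1, NULL, NULL))
  } else {
    f2 <- factor(f2)
    if (nlevels(f2) < 2) stop("factor must have >= 2 levels")
    dat <- data.frame(y = y, f1 = f1, f2 = f2)
    mod <- stats::lm(y ~ f1 * f2, data = dat)
    av <- car::Anova(mod, type = 2)
    terms_df <- data.frame(term = rownames(av), sum_sq = av$`Sum Sq`,
                           df = av$Df, F = av$`F value`, p = av$`Pr(>F)`)
    ph <- list(f1 = pairwise_f(mod, "f1", f1, "f2", f2),
               f2 = pairwise_f(mod, "f2", f2, "f1", f1))
  }
  structure(list(terms = terms_df, posthoc = ph,
                 r_squared = summary(mod)$r.squared,
                 adj_r_squared = summary(mod)$adj.r.squared,
                 model = mod), class = "anova_result")
}

# Pairwise marginal-mean contrast of two levels of `fname`, averaging over
# the other factor's levels when an interaction is present.
pairwise_f <- function(mod, fname, f, other_name, other) {
  cn <- names(stats::coef(mod))
  level_weights <- function(level) {
    w <- stats::setNames(numeric(length(cn)), cn)
    nm <- paste0(fname, level)
    if (nm %in% cn) w[nm] <- 1
    if (!is.null(other)) {
      for (ol in levels(other)) {
        cand <- c(paste0(fname, level, ":", other_name, ol),
                  paste0(other_name, ol, ":", fname, level))
        hit <- cand[cand %in% cn]
        if (length(hit)) w[hit[1]] <- 1 / nlevels(other)
      }
    }
    w
  }
  cmb <- utils::combn(levels(f), 2)
  out <- NULL
  for (j in seq_len(ncol(cmb))) {
    a <- cmb[1, j]; b <- cmb[2, j]
    vec <- level_weights(a) - level_weights(b)
    lh <- car::linearHypothesis(mod, matrix(vec, nrow = 1), rhs = 0)
    out <- rbind(out, data.frame(level_a = a, level_b = b, F = lh$F[2],
                                 df1 = lh$Df[2], df2 = lh$Res.Df[2],
                                 p = lh$`Pr(>F)`[2]))
  }
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}
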