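# explicit residual-sum-of-squares oracle for F statistics
rss <- function(formula, data) sum(resid(lm(formula, data))^2)

test_that("correlation measures behave on canonical inputs", {
  x <- 1:10
  out <- correlate(x, x)
  expect_equal(out$pearson$r, 1)
  expect_equal(out$spearman$rho, 1)
  expect_equal(correlate(x, -x)$pearson$r, -1)
  x3 <- seq(-3, 3)
  out3 <- correlate(x3, x3^3)
  expect_equal(out3$spearman$rho, 1)
  expect_lt(out3$pearson$r, 1)
  expect_error(correlate(x, rep(2, 10)), "zero variance")
  expect_error(correlate(c(1, 2, NA, 4, 5), c(1, 2, 3, 4, 5)), "finite")
})

make_ancova_data <- function(seed = 30, interaction = 0) {
  set.seed(seed)
  res <- rep(c(1.5, 2, 3), each = 10)
  tsnr <- rnorm(30, mean = 25, sd = 5)
  slope <- 0.02 + interaction * (res == 2)
  ios <- 0.3 + slope * tsnr + rnorm(30, sd = 0.03)
  data.frame(ios = ios, tsnr = tsnr, res = res)
}

test_that("ANCOVA F statistics reproduce the Type-II RSS oracle", {
  d <- make_ancova_data()
  out <- ancova_ios(d$ios, d$tsnr, d$res)
  d$resolution <- factor(paste0(d$res, "mm"))
  rss_full <- rss(ios ~ tsnr * resolution, d)
  df_full <- 30 - 6
  # Type II: each term against the model with all others except those
  # containing it, on the full model's error
  f_oracle <- function(r_without, r_with, df) {
    ((r_without - r_with) / df) / (rss_full / df_full)
  }
  f_tsnr <- f_oracle(rss(ios ~ resolution, d),
                     rss(ios ~ tsnr + resolution, d), 1)
  f_res <- f_oracle(rss(ios ~ tsnr, d), rss(ios ~ tsnr + resolution, d), 2)
  f_int <- f_oracle(rss(ios ~ tsnr + resolution, d), rss_full, 2)
  terms <- out$terms
  expect_equal(terms$F[terms$term == "tsnr"], f_tsnr, tolerance = 1e-8)
  expect_equal(terms$F[terms$term == "resolution"], f_res, tolerance = 1e-8)
  expect_equal(terms$F[terms$term == "tsnr:resolution"], f_int,
               tolerance = 1e-8)
  # nested model comparison against the tSNR-only regression
  f_cmp <- ((rss(ios ~ tsnr, d) - rss_full) / 4) / (rss_full / df_full)
  expect_equal(out$model_comparison$F, f_cmp, tolerance = 1e-8)
  expect_equal(out$model_comparison$df1, 4)
  expect_equal(out$model_comparison$df2, 24)
})

test_that("ANCOVA is shift invariant and detects a programmed interaction", {
  d <- make_ancova_data(seed = 31)
  a <- ancova_ios(d$ios, d$tsnr, d$res)
  b <- ancova_ios(d$ios + 5, d$tsnr, d$res)
  expect_equal(a$terms$F, b$terms$F, tolerance = 1e-10)
  di <- make_ancova_data(seed = 32, interaction = 0.08)
  ai <- ancova_ios(di$ios, di$tsnr, di$res)
  f_int <- ai$terms$F[ai$terms$term == "tsnr:resolution"]
  expect_gt(f_int, qf(0.95, 2, 24))
  # simple slopes: the boosted level has the strongest slope test
  ss <- ai$simple_slopes
  expect_equal(ss$level[which.max(ss$F)], "2mm")
})

test_that("MANOVA separates constructed groups and is coordinate-order invariant", {
  set.seed(33)
  bp <- rep(c("foot", "hand", "face"), times = 12)
  res <- rep(rep(c("1.5", "2", "3"), each = 3), times = 4)
  base <- matrix(rnorm(36 * 3, sd = 0.5), 36, 3)
  off <- rbind(foot = c(5, 0, 0), hand = c(0, 5, 0), face = c(0, 0, 5))
  coords <- base + off[bp, ]
  out <- manova_coords(coords, bp, res)
  row_bp <- out[out$term == "bp", ]
  expect_gt(row_bp$pillai, 1.5)  # near its maximum of 2 for s = 2
  expect_lt(row_bp$p, 1e-10)
  perm <- manova_coords(coords[, c(3, 1, 2)], bp, res)
  expect_equal(perm$pillai, out$pillai, tolerance = 1e-10)
  # null factor: resolution has no effect here
  expect_gt(out$p[out$term == "res"], 0.01)
})

test_that("MANOVA Pillai matches the base-R reference on a fixture", {
  set.seed(34)
  bp <- factor(rep(c("a", "b", "c"), each = 12))
  res <- factor(rep(rep(c("x", "y", "z"), each = 4), times = 3))
  coords <- matrix(rnorm(108), 36, 3) + 2 * (bp == "a")
  out <- manova_coords(coords, bp, res)
  ref <- summary(manova(coords ~ bp * res), test = "Pillai")$stats
  # balanced design: Type II equals sequential sums of squares
  expect_equal(out$pillai[out$term == "bp"], ref["bp", "Pillai"],
               tolerance = 1e-8)
  expect_equal(out$approx_F[out$term == "bp"], ref["bp", "approx F"],
               tolerance = 1e-8)
})

test_that("one-way ANOVA matches the RSS oracle and rejects a 5-sigma gap", {
  set.seed(35)
  y <- c(rnorm(12), rnorm(12, mean = 5))
  g <- rep(c("a", "b"), each = 12)
  out <- anova_oneway_twoway(y, g)
  d <- data.frame(y = scale(y)[, 1], g = g)
  f_oracle <- ((rss(y ~ 1, d) - rss(y ~ g, d)) / 1) / (rss(y ~ g, d) / 22)
  expect_equal(out$terms$F[1], f_oracle, tolerance = 1e-8)
  expect_lt(out$posthoc$f1$p_holm[1], 1e-6)
  expect_error(anova_oneway_twoway(y, rep("a", 24)), "levels")
})

test_that("two-way ANOVA uses Type-II sums of squares with Holm post hocs", {
  set.seed(36)
  f1 <- rep(c("p1", "p2", "p3"), each = 12)
  f2 <- rep(rep(c("u", "v"), each = 6), times = 3)
  y <- rnorm(36) + 2 * (f1 == "p1")
  out <- anova_oneway_twoway(y, f1, f2)
  d <- data.frame(y = scale(y)[, 1], f1 = f1, f2 = f2)
  rss_add <- rss(y ~ f1 + f2, d)
  rss_full <- rss(y ~ f1 * f2, d)
  f_f1 <- ((rss(y ~ f2, d) - rss_add) / 2) / (rss_full / 30)
  expect_equal(out$terms$F[out$terms$term == "f1"], f_f1, tolerance = 1e-8)
  ph <- out$posthoc$f1
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_holm >= ph$p))
  sig <- ph[ph$level_a == "p1" | ph$level_b == "p1", ]
  expect_true(all(sig$p_holm < 0.01))
})
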