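test_that("default paradigm has 18 active blocks, 3 per condition", {
  ev <- make_paradigm(paradigm_spec(), seed = 7)
  act <- ev[ev$event_class == "active", ]
  expect_equal(nrow(act), 18)
  expect_equal(unname(table(act$condition)), rep(3L, 6), ignore_attr = TRUE)
  # every active block is directly preceded by a prep event of the same
  # condition
  for (i in which(ev$event_class == "active")) {
    expect_equal(ev$event_class[i - 1], "prep")
    expect_equal(ev$condition[i - 1], ev$condition[i])
  }
  expect_true(all(diff(ev$onset) >= 0))
})

test_that("condition order is seeded and avoids immediate repeats", {
  a <- make_paradigm(paradigm_spec(), seed = 3)
  b <- make_paradigm(paradigm_spec(), seed = 3)
  c <- make_paradigm(paradigm_spec(), seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$condition, c$condition))
  act <- a$condition[a$event_class == "active"]
  expect_true(all(act[-1] != act[-length(act)]))
})

test_that("paradigm fits inside every preset's scan duration", {
  ev <- make_paradigm(paradigm_spec(), seed = 1)
  horizon <- max(ev$onset + ev$duration)
  for (p in protocol_presets())
    expect_lte(horizon, p$n_volumes * p$volume_tr_ms / 1000)
})

test_that("simulated pattern second moment matches the target covariance", {
  G <- scenario_preset("subcortical_protocol_dependent")$g_true
  v <- 1e5
  Y <- simulate_patterns(G, v = v, sigma2 = 0, seed = 11)
  S <- tcrossprod(Y) / v
  # entrywise within 3 Monte-Carlo standard errors:
  # var(u_i u_j) = G_ii G_jj + G_ij^2 for Gaussian draws
  se <- sqrt((outer(diag(G), diag(G)) + G^2) / v)
  expect_true(all(abs(S - G) < 3.5 * se + 1e-12))
})

test_that("pattern generation handles degenerate inputs and is seeded", {
  Y0 <- simulate_patterns(matrix(0, 3, 3), v = 10, sigma2 = 0, seed = 1)
  expect_true(all(Y0 == 0))
  a <- simulate_patterns(diag(4), v = 20, sigma2 = 0.5, seed = 5)
  b <- simulate_patterns(diag(4), v = 20, sigma2 = 0.5, seed = 5)
  expect_identical(a, b)
  bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(simulate_patterns(bad, v = 5), "positive semi-definite")
})

test_that("ROI masks are ten disjoint mirrored boxes", {
  rois <- make_roi_masks()
  counts <- tabulate(rois$labels[rois$labels > 0], nbins = 10)
  expect_length(rois$names, 10)
  expect_true(all(counts >= 27))
  # mirror across the x midline: flipping x maps L labels onto R labels
  flipped <- rois$labels[dim(rois$labels)[1]:1, , ]
  for (s in c("M1", "SMA", "putamen", "pallidum", "thalamus")) {
    l <- match(paste0(s, "_L"), rois$names)
    r <- match(paste0(s, "_R"), rois$names)
    expect_identical(which(flipped == l), which(rois$labels == r))
  }
  expect_error(make_roi_masks(c(5L, 5L, 5L)), "too small")
})

test_that("somatotopy fields tile each ROI along z, foot most dorsal", {
  rois <- make_roi_masks()
  name <- "putamen_L"
  parts <- lapply(c("foot", "hand", "face"), function(m)
    roi_condition_mask(rois, name, m))
  expect_equal(Reduce(`+`, lapply(parts, sum)), sum(roi_mask(rois, name)))
  zmean <- vapply(parts, function(m) mean(which(m, arr.ind = TRUE)[, 3]),
                  numeric(1))
  expect_true(zmean[1] > zmean[2] && zmean[2] > zmean[3])
})

test_that("scenario presets encode the programmed segregation structure", {
  cells <- factorial_cells()
  within_r <- function(G, res) {
    idx <- cells$cell[cells$resolution == res]
    G[cbind(utils::combn(idx, 2)[1, ], utils::combn(idx, 2)[2, ])]
  }
  inv <- scenario_preset("cortical_invariant")$g_true
  expect_true(all(abs(within_r(inv, 1.5) - within_r(inv, 2)) < 1e-12))
  expect_true(all(abs(within_r(inv, 1.5) - within_r(inv, 3)) < 1e-12))
  dep <- scenario_preset("subcortical_protocol_dependent")
  expect_true(min(within_r(dep$g_true, 2)) > max(within_r(dep$g_true, 1.5)))
  expect_true(min(within_r(dep$g_true, 2)) > max(within_r(dep$g_true, 3)))
  for (g in dep$g_by_class) {
    ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  expect_error(scenario_preset("unknown_scenario"))
})

test_that("simulated time series hit the programmed tSNR", {
  prot <- tiny_protocol(n_volumes = 150)
  rois <- tiny_rois()
  ev <- make_paradigm(paradigm_spec(block_duration = 8, rest_duration = 8,
                                    prep_duration = 2, blocks_per_condition = 1),
                      seed = 2)
  sim <- simulate_timeseries(prot, ev, rois, tiny_truth(tsnr = 20), seed = 9)
  dat <- sim$image$data
  v <- dim(dat)
  mat <- t(matrix(dat, prod(v[1:3]), v[4]))
  tsnr_vox <- colMeans(mat) / apply(mat, 2, sd)
  expect_gt(ncol(mat), 500)
  expect_lt(abs(mean(tsnr_vox) - 20) / 20, 0.10)
})

test_that("AR(1) control of the noise autocorrelation works", {
  prot <- tiny_protocol(n_volumes = 200)
  rois <- tiny_rois()
  ev <- make_paradigm(paradigm_spec(block_duration = 4, rest_duration = 4,
                                    prep_duration = 1, blocks_per_condition = 1),
                      seed = 2)
  lag1 <- function(phi) {
    sim <- simulate_timeseries(prot, ev, rois, tiny_truth(ar1_phi = phi),
                               seed = 21)
    mat <- t(matrix(sim$image$data, , prot$n_volumes))
    d <- sweep(mat, 2, colMeans(mat))
    mean(colSums(d[-1, ] * d[-nrow(d), ]) / colSums(d^2))
  }
  expect_lt(abs(lag1(0)), 0.03)
  expect_gt(lag1(0.5), 0.35)
})

test_that("zero-noise, zero-amplitude series are constant and events are checked", {
  prot <- tiny_protocol(n_volumes = 40)
  rois <- tiny_rois()
  ev <- make_paradigm(paradigm_spec(block_duration = 2, rest_duration = 2,
                                    prep_duration = 0.5,
                                    blocks_per_condition = 1), seed = 2)
  truth <- tiny_truth(tsnr = Inf)
  sim <- simulate_timeseries(prot, ev, rois, truth, seed = 3)
  expect_equal(max(sim$image$data) - min(sim$image$data), 0)
  long <- make_paradigm(paradigm_spec(), seed = 1)  # 646 s > 80 s scan
  expect_error(simulate_timeseries(prot, long, rois, truth, seed = 3),
               "exceed")
})
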