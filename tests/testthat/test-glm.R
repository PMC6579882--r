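test_that("canonical HRF has the expected double-gamma shape", {
  dt <- 0.05
  h <- canonical_hrf(dt)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # mode of the positive gamma lobe (shape 6, rate 1) is at t = 5 s
  expect_lt(abs((which.max(h) - 1) * dt - 5), 0.2)
  expect_gt(sum(h) * dt, 0)
  expect_error(canonical_hrf(dt = 0))
})

make_session <- function(n_volumes = 150, tsnr = Inf, amplitude_pct = 2,
                         seed = 5, ar1_phi = 0) {
  prot <- tiny_protocol(n_volumes = n_volumes)
  rois <- tiny_rois()
  ev <- make_paradigm(paradigm_spec(block_duration = 8, rest_duration = 8,
                                    prep_duration = 2,
                                    blocks_per_condition = 1), seed = 2)
  truth <- tiny_truth(tsnr = tsnr, amplitude_pct = amplitude_pct,
                      ar1_phi = ar1_phi)
  sim <- simulate_timeseries(prot, ev, rois, truth, seed = seed)
  list(prot = prot, rois = rois, ev = ev, sim = sim, truth = truth)
}

test_that("design matrix has 6 condition + prep + 6 motion + intercept columns", {
  s <- make_session()
  X <- build_design(s$ev, s$prot, motion = s$sim$motion)
  expect_equal(ncol(X$X), 14)
  expect_length(X$condition_columns, 6)
  expect_setequal(colnames(X$X)[X$condition_columns], condition_labels())
  expect_true("intercept" %in% colnames(X$X))
  expect_equal(qr(X$X)$rank, 14)
})

test_that("all-zero motion columns are flagged collinear", {
  s <- make_session()
  expect_warning(build_design(s$ev, s$prot,
                              motion = matrix(0, s$prot$n_volumes, 6)),
                 "rank deficient.*motion")
})

test_that("noiseless fits recover programmed amplitudes to machine precision", {
  s <- make_session(tsnr = Inf, amplitude_pct = 2)
  X <- build_design(s$ev, s$prot, motion = s$sim$motion)
  fit <- fit_glm(s$sim$image, X)
  # field voxels of foot_left: contralateral right-hemisphere foot slab
  field <- which(roi_condition_mask(s$rois, "M1_R", "foot"))
  b <- fit$betas[match("foot_left", colnames(X$X)), field]
  expect_equal(unname(b), rep(2, length(field)), tolerance = 1e-8)
  # residuals orthogonal to the design
  expect_lt(max(abs(crossprod(X$X, fit$residuals))),
            1e-8 * sqrt(sum(s$sim$image$data^2)))
})

test_that("doubling the amplitude doubles the fitted beta", {
  s1 <- make_session(tsnr = Inf, amplitude_pct = 1)
  s2 <- make_session(tsnr = Inf, amplitude_pct = 2)
  X <- build_design(s1$ev, s1$prot)
  b1 <- fit_glm(s1$sim$image, X)$betas
  b2 <- fit_glm(s2$sim$image, X)$betas
  cc <- match(condition_labels(), colnames(X$X))
  expect_equal(2 * b1[cc, ], b2[cc, ], tolerance = 1e-8)
})

test_that("fit_glm validates volume counts and is voxel-independent", {
  X <- matrix(rnorm(40), 20, 2)
  Y <- matrix(rnorm(20 * 6), 20, 6)
  expect_error(fit_glm(Y[1:10, ], X), "mismatch")
  f <- fit_glm(Y, X)
  perm <- c(3, 1, 2, 6, 5, 4)
  fp <- fit_glm(Y[, perm], X)
  expect_equal(fp$betas, f$betas[, perm])
})

test_that("there are exactly six single-column differential contrasts", {
  s <- make_session()
  X <- build_design(s$ev, s$prot, motion = s$sim$motion)
  cons <- differential_contrasts(X)
  expect_length(cons, 6)
  for (cv in cons) expect_equal(sum(cv != 0), 1)
  # missing condition errors
  ev2 <- s$ev[s$ev$condition != "face_left", ]
  X2 <- suppressWarnings(build_design(ev2, s$prot))
  expect_error(differential_contrasts(X2), "face_left")
})

test_that("contrast t-map peaks inside the stimulated field", {
  s <- make_session(tsnr = 60, amplitude_pct = 3, seed = 8)
  X <- build_design(s$ev, s$prot, motion = s$sim$motion)
  fit <- fit_glm(s$sim$image, X)
  cons <- differential_contrasts(X)
  tm <- contrast_tmap(fit, cons[["hand_right"]])
  grid <- dim(s$rois$labels)
  peak <- arrayInd(which.max(array(tm$t, grid)), grid)
  field <- which(roi_condition_mask(s$rois, "M1_L", "hand"), arr.ind = TRUE)
  hit <- any(apply(field, 1, function(r) all(r == peak)))
  # peak may land in any contralateral hand field; check it is one of them
  if (!hit) {
    all_fields <- do.call(rbind, lapply(
      s$rois$names[endsWith(s$rois$names, "_L")],
      function(nm) which(roi_condition_mask(s$rois, nm, "hand"),
                         arr.ind = TRUE)))
    hit <- any(apply(all_fields, 1, function(r) all(r == peak)))
  }
  expect_true(hit)
})

test_that("pure-noise t-maps reject at the nominal rate", {
  set.seed(31)
  n <- 100; v <- 4000
  X <- cbind(task = rep(c(0, 1), each = n / 2), intercept = 1)
  Y <- matrix(rnorm(n * v), n, v)
  fit <- fit_glm(Y, X)
  tm <- contrast_tmap(fit, c(1, 0))
  crit <- qt(0.975, fit$dof)
  rate <- mean(abs(tm$t) > crit)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / v) + 0.005)
})

test_that("OLS betas are unbiased under AR(1) noise", {
  prot <- tiny_protocol(n_volumes = 100)
  ev <- make_paradigm(paradigm_spec(block_duration = 8, rest_duration = 8,
                                    prep_duration = 2,
                                    blocks_per_condition = 1), seed = 2)
  rois <- tiny_rois()
  field <- which(roi_condition_mask(rois, "M1_R", "foot"))[1:5]
  X <- build_design(ev, prot)
  cc <- match("foot_left", colnames(X$X))
  set.seed(77)
  b <- replicate(60, {
    sim <- simulate_timeseries(prot, ev, rois,
                               tiny_truth(tsnr = 30, amplitude_pct = 2,
                                          ar1_phi = 0.4),
                               seed = sample.int(1e6, 1))
    mean(fit_glm(sim$image, X)$betas[cc, field])
  })
  se <- sd(b) / sqrt(length(b))
  expect_lt(abs(mean(b) - 2), 3 * se + 0.02)
})
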