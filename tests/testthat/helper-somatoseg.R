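# Shared fixtures built in code.

# small acquisition protocol for fast simulations
tiny_protocol <- function(n_volumes = 120, voxel = 3, tr_ms = 2000) {
  protocol_spec("tiny", voxel, tr_ms, n_volumes, "2D",
                retained_slices = 30, slice_thickness = 3)
}

# ground truth with a configurable tSNR target keyed to the tiny protocol
tiny_truth <- function(tsnr = 20, amplitude_pct = 0, pattern_pct = 0,
                       ar1_phi = 0, sigma2 = 0) {
  ground_truth(diag(9), sigma2_true = sigma2, amplitude_pct = amplitude_pct,
               pattern_pct = pattern_pct, ar1_phi = ar1_phi,
               tsnr_target = c(tiny = tsnr))
}

# smallest grid that holds the ten ROI boxes
tiny_rois <- function() make_roi_masks(c(18L, 37L, 10L), roi_dim = c(3L, 3L, 3L))

# reduced design mapping the 9 factorial rows onto 3 movement patterns
movement_design <- function() kronecker(rep(1, 3), diag(3))

expect_all_true <- function(x) expect_true(all(x))
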