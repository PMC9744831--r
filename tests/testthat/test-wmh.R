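test_that("reference statistics use the sample-SD convention and guard degeneracy", {
  atl <- small_atlas()
  dims <- dim(atl$labels)
  mcp <- atl$labels == atl$label_table[["mcp"]]
  vol <- brain_volume(array(0, dims), atl$spacing, atl$slice_thickness)
  # three distinct values cycled over the MCP: mean 100, sample SD 10
  vol$data[mcp] <- rep(c(90, 100, 110), length.out = sum(mcp))
  ref <- estimate_reference_stats(vol, atl, min_voxels = 3)
  expect_equal(ref$mu_ref, 100)
  expect_equal(ref$sigma_ref, sd(rep(c(90, 100, 110),
                                     length.out = sum(mcp))))
  # constant MCP: stats are (c, 0) and standardization must refuse them
  vol$data[mcp] <- 250
  ref0 <- estimate_reference_stats(vol, atl, min_voxels = 3)
  expect_equal(ref0$sigma_ref, 0)
  expect_error(normalization_params(ref0$mu_ref, ref0$sigma_ref), "sigma_ref")
  expect_error(standardize_intensities(vol, ref0), "sigma_ref")
  expect_error(estimate_reference_stats(vol, atl, min_voxels = 1e6),
               "unusable reference")
})

test_that("noisy reference estimates land within standard error of the truth", {
  atl <- make_atlas(c(96, 96, 27))
  sim <- simulate_flair(atl, noise_sd = 50, seed = 21)
  n_mcp <- sum(atl$labels == atl$label_table[["mcp"]])
  expect_gte(n_mcp, 1000)
  ref <- estimate_reference_stats(sim$volume, atl)
  expect_lt(abs(ref$mu_ref - 500), 3 * 50 / sqrt(n_mcp))
  expect_lt(abs(ref$sigma_ref - 50), 3 * 50 / sqrt(2 * (n_mcp - 1)))
})

test_that("standardization maps the reference to mean 1000 / SD 100 and is affine-invariant", {
  params <- normalization_params(mu_ref = 500, sigma_ref = 50)
  v <- brain_volume(array(c(500, 675, 325, 550), c(4, 1, 1)))
  out <- standardize_intensities(v, params)
  expect_equal(out$data[1], 1000)               # fixed point
  expect_equal(out$data[2], 1350)               # exactly the 3.5-SD threshold
  expect_equal(wmh_threshold(params), 1350)

  atl <- small_atlas()
  sim <- simulate_flair(atl, noise_sd = 12, seed = 3)
  std1 <- standardize_intensities(sim$volume,
                                  estimate_reference_stats(sim$volume, atl))
  rescaled <- brain_volume(3.2 * sim$volume$data + 40, atl$spacing,
                           atl$slice_thickness)
  std2 <- standardize_intensities(rescaled,
                                  estimate_reference_stats(rescaled, atl))
  expect_equal(std1$data, std2$data, tolerance = 1e-9)
  # and the standardized MCP has exactly the target moments
  mcp <- atl$labels == atl$label_table[["mcp"]]
  expect_equal(mean(std1$data[mcp]), 1000, tolerance = 1e-9)
  expect_equal(sd(std1$data[mcp]), 100, tolerance = 1e-9)
})

test_that("noise-free segmentation recovers the truth mask exactly", {
  atl <- small_atlas()
  les <- lesion_spec("wm_occipital", lobe_center(atl, "wm_occipital", 9),
                     radius = 2.5, contrast = 6)
  sim <- simulate_flair(atl, list(les), bias_amplitude = 0, noise_sd = 0)
  params <- normalization_params(500, 50)
  std <- standardize_intensities(sim$volume, params)
  mask <- segment_wmh(std, atl, cutoff_sd = 3.5)
  expect_identical(mask, sim$truth$mask)

  # threshold monotonicity: the 3.5-SD mask nests inside the 2-SD mask
  noisy <- simulate_flair(atl, list(les), noise_sd = 20, seed = 8)
  stdn <- standardize_intensities(noisy$volume,
                                  estimate_reference_stats(noisy$volume, atl))
  m35 <- segment_wmh(stdn, atl, 3.5)
  m20 <- segment_wmh(stdn, atl, 2.0)
  expect_true(all(m20[m35]))

  # a 1-SD lesion sits far below a 3.5-SD cutoff: with noise at the WM SD,
  # lesion voxels clear the threshold only via a P(Z > 2.5) noise excursion
  weak <- simulate_flair(atl, list(lesion_spec("wm_occipital",
                                               lobe_center(atl, "wm_occipital", 9),
                                               2.5, contrast = 1)),
                         noise_sd = 50, seed = 8)
  stdw <- standardize_intensities(weak$volume,
                                  estimate_reference_stats(weak$volume, atl))
  mw <- segment_wmh(stdw, atl, 3.5)
  expect_lte(sum(mw), 6)
})

test_that("the minimum-component-size filter drops speckle but keeps lesions", {
  atl <- small_atlas()
  les <- lesion_spec("wm_parietal", lobe_center(atl, "wm_parietal", 8),
                     radius = 2.8, contrast = 8)
  sim <- simulate_flair(atl, list(les), noise_sd = 20, seed = 13)
  seg_all <- quantify_wmh(sim$volume, atl, bias_order = NULL)
  seg_filt <- quantify_wmh(sim$volume, atl, bias_order = NULL,
                           min_component_size = 5)
  expect_lte(sum(seg_filt$mask), sum(seg_all$mask))
  expect_gte(sum(seg_filt$mask & sim$truth$mask), 0.9 * sum(sim$truth$mask))
})

test_that("parcellation converts voxel counts to ml with PV/lobe accounting", {
  atl <- make_atlas(c(64, 64, 27), spacing = c(0.9375, 0.9375),
                    slice_thickness = 5)
  mask <- array(FALSE, dim(atl$labels))
  frontal <- which(atl$labels == atl$label_table[["wm_frontal"]])
  mask[frontal[1:100]] <- TRUE
  seg <- parcellate_and_quantify(mask, atl)
  expect_equal(unname(seg$volumes_ml["frontal"]), 100 * 4.394531e-3,
               tolerance = 1e-6)
  expect_equal(unname(seg$volumes_ml["total"]), 0.4394531, tolerance = 1e-6)

  empty <- parcellate_and_quantify(array(FALSE, dim(atl$labels)), atl)
  expect_true(all(empty$volumes_ml == 0))

  # a pure parietal lesion lands in the parietal compartment only
  les <- lesion_spec("wm_parietal", lobe_center(atl, "wm_parietal", 14),
                     radius = 3.2, contrast = 7)
  sim <- simulate_flair(atl, list(les), bias_amplitude = 0, noise_sd = 0)
  params <- normalization_params(500, 50)
  std <- standardize_intensities(sim$volume, params)
  seg2 <- parcellate_and_quantify(segment_wmh(std, atl), atl, params)
  expect_equal(unname(seg2$volumes_ml["parietal"]),
               unname(sim$truth$volumes_ml["total"]))
  others <- seg2$volumes_ml[c("frontal", "temporal", "occipital",
                              "periventricular")]
  expect_true(all(others == 0))
})

test_that("regional additivity holds for every segmentation", {
  atl <- small_atlas()
  set.seed(31)
  for (i in 1:5) {
    mask <- array(runif(length(atl$labels)) < 0.02, dim(atl$labels))
    seg <- parcellate_and_quantify(mask, atl)
    expect_equal(unname(seg$volumes_ml["total"]),
                 sum(seg$volumes_ml[c("frontal", "temporal", "parietal",
                                      "occipital", "periventricular")]),
                 tolerance = 1e-12)
  }
})
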