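# shared small cohort pieces for technique-level checks (no smoothing so the
# tiny grid stays cheap; component count picked automatically)
tech_opts <- list(smooth = FALSE)

test_that("technique names validate and alias to canonical labels", {
  expect_equal(rsdenoise:::normalize_technique("aggr_aroma"), "aggressive_aroma")
  expect_equal(rsdenoise:::normalize_technique("sock"), "sock_style")
  expect_error(rsdenoise:::normalize_technique("magic"), "unknown technique")
})

test_that("censoring on a clean, motion-free subject reduces to the bandpass", {
  atlas <- tiny_atlas()
  cfg <- tiny_config(motion_artifact_amplitude = 0, physio_amplitude = 0,
                     drift_amplitude = 0, thermal_sd = 0, physio_leak = 0)
  s <- simulate_subject(atlas, cfg, 13L, "smooth")
  s$motion <- motion_trace(matrix(0, cfg$n_timepoints, 6), cfg$tr)
  s$fwd <- rep(0, cfg$n_timepoints)
  res <- apply_technique(s, "censoring", atlas, tech_opts)
  bp <- bandpass_volume(s$volume, 0.009, 0.08)
  # compare voxel fluctuations inside a network (means differ by contract)
  vox <- which(atlas$reference_networks[[1]], arr.ind = TRUE)[1, ]
  a <- res$volume$data[vox[1], vox[2], vox[3], ]
  b <- bp$data[vox[1], vox[2], vox[3], ]
  # detrending additionally removes drift-shaped in-band variance, so the
  # match is close but not exact
  expect_gt(cor(a - mean(a), b - mean(b)), 0.95)
  expect_equal(res$tdof$n_lost, 0L)
})

test_that("component techniques suppress the FWD-coupled edge artifact", {
  atlas <- tiny_atlas()
  cfg <- tiny_config()
  s <- simulate_subject(atlas, cfg, 29L, "hf_tremor")
  base_r <- mean(abs(cor(s$fwd, rsdenoise:::mask_matrix(s$volume,
                                                        atlas$edge_mask))))
  res <- apply_technique(s, "aggressive_aroma", atlas, tech_opts)
  Y <- rsdenoise:::mask_matrix(res$volume, atlas$edge_mask)
  ok <- apply(Y, 2, sd) > 1e-12
  clean_r <- mean(abs(cor(s$fwd, Y[, ok])))
  expect_lt(clean_r, base_r / 2)
})

test_that("tdof sources follow the technique family", {
  atlas <- tiny_atlas()
  cfg <- tiny_config()
  s <- simulate_subject(atlas, cfg, 37L, "hf_tremor")
  # short run: skip the frequency regressors so the censoring design fits
  topt <- c(tech_opts, list(bandpass = FALSE))
  cens <- apply_technique(s, "censoring", atlas, topt)
  expect_equal(cens$tdof$source, "censoring")
  expect_equal(cens$tdof$n_lost, sum(s$fwd >= 0.5))
  aroma <- apply_technique(s, "nonaggr_aroma", atlas, topt)
  expect_equal(aroma$tdof$source, "components")
  expect_equal(aroma$tdof$n_lost, sum(aroma$decomposition$noise_label))
  sock <- apply_technique(s, "sock", atlas, topt)
  expect_equal(sock$tdof$source, "components")
})

test_that("a precomputed decomposition gives identical results", {
  atlas <- tiny_atlas()
  cfg <- tiny_config()
  s <- simulate_subject(atlas, cfg, 41L, "hf_tremor")
  r1 <- apply_technique(s, "aggr_aroma", atlas, tech_opts)
  dec <- decompose_spatial_ica(s$volume, atlas$brain_mask, rng_seed = s$seed)
  r2 <- apply_technique(s, "aggr_aroma", atlas,
                        c(tech_opts, list(decomposition = dec)))
  expect_equal(r1$volume$data, r2$volume$data, tolerance = 1e-10)
})

test_that("explicit label files drive the component selection", {
  atlas <- tiny_atlas()
  cfg <- tiny_config()
  s <- simulate_subject(atlas, cfg, 43L, "hf_tremor")
  dec <- decompose_spatial_ica(s$volume, atlas$brain_mask, rng_seed = 1)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "3"), f)
  res <- apply_technique(s, "aggr_aroma", atlas,
                         c(tech_opts, list(decomposition = dec, labels = f)))
  expect_equal(res$tdof$n_lost, 2L)
})
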