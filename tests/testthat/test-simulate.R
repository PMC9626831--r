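test_that("noise-free subjects are an exact sum of baseline and network signal", {
  atlas <- tiny_atlas()
  cfg <- tiny_config(motion_artifact_amplitude = 0, physio_amplitude = 0,
                     drift_amplitude = 0, thermal_sd = 0, physio_leak = 0,
                     network_amplitude = 3, baseline = 500)
  s <- simulate_subject(atlas, cfg, 21L, "smooth")
  for (k in seq_along(atlas$reference_networks)) {
    vox <- which(atlas$reference_networks[[k]], arr.ind = TRUE)[1, ]
    ts <- s$volume$data[vox[1], vox[2], vox[3], ]
    expect_equal(ts, 500 + 3 * s$truth_network_timecourses[, k],
                 tolerance = 1e-10)
  }
  # outside any network, inside brain: flat baseline
  bg <- atlas$brain_mask & !Reduce(`|`, atlas$reference_networks) &
    !atlas$wm_mask & !atlas$csf_mask
  vox <- which(bg, arr.ind = TRUE)[5, ]
  expect_equal(s$volume$data[vox[1], vox[2], vox[3], ], rep(500, cfg$n_timepoints))
})

test_that("network time courses are band-limited to the passband", {
  atlas <- tiny_atlas()
  cfg <- tiny_config(n_timepoints = 144)
  s <- simulate_subject(atlas, cfg, 9L, "smooth")
  freqs <- rsdenoise:::dft_frequencies(144, cfg$tr)
  for (k in seq_len(ncol(s$truth_network_timecourses))) {
    pw <- Mod(fft(s$truth_network_timecourses[, k]))^2
    in_band <- freqs >= cfg$passband[1] - 1e-9 & freqs <= cfg$passband[2] + 1e-9
    expect_lt(sum(pw[!in_band]) / sum(pw), 0.05)
  }
})

test_that("edge time series track framewise displacement under tremor", {
  atlas <- tiny_atlas()
  cfg <- tiny_config()
  s <- simulate_subject(atlas, cfg, 33L, "hf_tremor")
  edge_ts <- mask_mean_ts(s$volume, atlas$edge_mask)
  expect_gt(cor(edge_ts, s$fwd), 0.5)
})

test_that("regressing the planted noise removes the FWD coupling at the edge", {
  atlas <- tiny_atlas()
  cfg <- tiny_config()
  s <- simulate_subject(atlas, cfg, 55L, "hf_tremor")
  X <- cbind(s$truth_noise_timecourses, s$truth_drift)
  clean <- regress_full(s$volume, X)
  Y <- rsdenoise:::mask_matrix(clean, atlas$edge_mask)
  ok <- apply(Y, 2, sd) > 1e-12
  r <- as.numeric(cor(s$fwd, Y[, ok]))
  expect_lt(mean(abs(r)), 0.1)
})

test_that("seed maps of simulated subjects light up the planted network", {
  atlas <- tiny_atlas()
  cfg <- tiny_config()
  s <- simulate_subject(atlas, cfg, 77L, "smooth")
  for (k in c(1L, 2L)) {
    map <- seed_correlation_map(s$volume, atlas$seed_masks[[k]],
                                atlas$brain_mask, k)
    net <- atlas$reference_networks[[atlas$seed_to_network[k]]]
    inside <- mean(abs(map$zmap[net]))
    outside <- mean(abs(map$zmap[atlas$brain_mask & !net]))
    expect_gt(inside, outside)
  }
})

test_that("cohorts are deterministic and respect the tremor fraction", {
  atlas <- tiny_atlas()
  cfg <- tiny_config(n_subjects = 10, n_timepoints = 48,
                     hf_motion_fraction = 0.5)
  c1 <- simulate_cohort(atlas, cfg)
  c2 <- simulate_cohort(atlas, cfg)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$subjects[[3]]$volume$data, c2$subjects[[3]]$volume$data)
  expect_equal(sum(c1$manifest$motion_mode == "hf_tremor"), 5)
})

test_that("cohort files round-trip and the manifest lists them", {
  atlas <- tiny_atlas()
  cfg <- tiny_config(n_subjects = 2, n_timepoints = 20)
  dir <- withr::local_tempdir()
  out <- simulate_cohort(atlas, cfg, out_dir = dir, keep_in_memory = TRUE)
  expect_true(all(file.exists(out$manifest$volume_path)))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  v <- read_volume(out$manifest$volume_path[1], tr = cfg$tr)
  expect_equal(dim(v$data), dim(out$subjects[[1]]$volume$data))
  expect_equal(as.numeric(v$data), as.numeric(out$subjects[[1]]$volume$data),
               tolerance = 1e-6)
  m <- read_motion(out$manifest$motion_path[1], tr = cfg$tr)
  expect_equal(rsdenoise:::motion_params(m),
               rsdenoise:::motion_params(out$subjects[[1]]$motion),
               tolerance = 1e-8)
})
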