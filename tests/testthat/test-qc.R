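test_that("identifiability is the inside/outside mean |z| ratio", {
  dims <- c(12, 12, 8)
  brain <- full_mask(dims)
  ref <- array(FALSE, dims); ref[4:6, 4:6, 3:5] <- TRUE
  z <- array(0.1, dims); z[ref] <- 1
  expect_equal(identifiability(z, ref, brain), 10)
  expect_equal(identifiability(array(0.7, dims), ref, brain), 1)
})

test_that("identifiability of standard-normal maps is 1 within sampling error", {
  dims <- c(25, 25, 20)  # 12500 voxels
  brain <- full_mask(dims)
  ref <- array(FALSE, dims); ref[5:15, 5:15, 5:12] <- TRUE
  z <- rsdenoise:::with_seed(71, array(rnorm(prod(dims)), dims))
  expect_equal(identifiability(z, ref, brain), 1, tolerance = 0.05)
})

test_that("identifiability is 1 under label permutation of a shared distribution", {
  dims <- c(20, 20, 10)
  n <- prod(dims)
  vals <- rsdenoise:::with_seed(72, sample(rep(c(0.2, 0.7, 1.3), length.out = n)))
  z <- array(vals, dims)
  scores <- rsdenoise:::with_seed(73, replicate(10, {
    ref <- array(FALSE, dims)
    ref[sample(n, 1000)] <- TRUE   # random reference region
    identifiability(z, ref, full_mask(dims))
  }))
  # same value multiset inside and out on average; ratios centred on 1
  expect_true(all(abs(scores - 1) < 0.1))
  expect_lt(abs(mean(scores) - 1), 0.03)
})

test_that("edge activity counts suprathreshold voxels within the edge shell", {
  dims <- c(8, 8, 8)
  edge <- array(FALSE, dims); edge[1, , ] <- TRUE
  active <- array(FALSE, dims)
  expect_equal(edge_activity(active, edge), 0)
  active[1, , ] <- TRUE
  expect_equal(edge_activity(active, edge), 100)
  active2 <- array(FALSE, dims); active2[1, 1:4, 1] <- TRUE
  expect_equal(edge_activity(active2, edge), 100 * 4 / 64)
  # background voxels outside the edge never change the score
  active3 <- active2; active3[5, 5, 5] <- TRUE
  expect_equal(edge_activity(active3, edge), edge_activity(active2, edge))
})

test_that("Gaussian smoothing raises the spatial smoothness statistic", {
  dims <- c(16, 16, 16)
  higher <- 0
  for (rep in 1:20) {
    z <- rsdenoise:::with_seed(rep + 400, array(rnorm(prod(dims)), dims))
    zs <- rsdenoise:::gaussian_smooth_3d(z, fwhm_mm = 3, voxel_size = c(1, 1, 1))
    if (spatial_smoothness(zs) > spatial_smoothness(z)) higher <- higher + 1
  }
  expect_equal(higher, 20)
})

test_that("smoothness is scale-invariant and elevated for low-frequency blobs", {
  dims <- c(16, 16, 16)
  z <- rsdenoise:::with_seed(81, array(rnorm(prod(dims)), dims))
  expect_equal(spatial_smoothness(5 * z), spatial_smoothness(z), tolerance = 1e-10)

  ax <- seq(-1, 1, length.out = 16)
  blob <- exp(-outer(outer(ax^2, ax^2, `+`), ax^2, `+`) / 0.1)
  expect_gt(spatial_smoothness(blob), spatial_smoothness(z))
})

test_that("connectivity sub-scores read the correct compartments", {
  atlas <- tiny_atlas()
  ref <- atlas$reference_networks[[1]]
  z <- array(0, atlas$grid_shape)
  z[ref] <- atanh(0.3)
  map <- structure(list(zmap = z, brain_mask = atlas$brain_mask),
                   class = "rsn_map")
  sc <- connectivity_subscores(map, atlas, ref)
  expect_equal(sc$tp_conn_r, 0.3, tolerance = 1e-10)
  expect_equal(sc$fp_conn_r, 0)
  expect_equal(sc$wm_conn_r, 0)
  expect_equal(sc$csf_conn_r, 0)
})

test_that("WM connectivity rises with the physiological amplitude", {
  atlas <- tiny_atlas()
  wm_r <- sapply(c(0, 8, 20), function(a) {
    cfg <- tiny_config(physio_amplitude = a, motion_artifact_amplitude = 0,
                       thermal_sd = 2)
    s <- simulate_subject(atlas, cfg, 91L, "smooth")
    map <- seed_correlation_map(s$volume, atlas$seed_masks[[1]],
                                atlas$brain_mask, 1)
    connectivity_subscores(map, atlas,
                           atlas$reference_networks[[1]])$wm_conn_r
  })
  expect_true(all(diff(wm_r) > 0))
})

test_that("split-half reproducibility separates shared maps from pure noise", {
  V <- 600; n_sub <- 12; n_seed <- 4
  # identical, mutually orthogonal (here: independent random) maps per seed
  base <- rsdenoise:::with_seed(55, matrix(rnorm(n_seed * V), n_seed, V))
  A <- array(NA_real_, c(n_sub, n_seed, V))
  for (i in seq_len(n_sub)) A[i, , ] <- base
  rp <- split_half_reproducibility(A, n_permutations = 50, rng_seed = 2)
  expect_true(all(abs(attr(rp, "diag") - 1) < 1e-12))
  expect_true(all(rp$pseudo_z > 5))

  noise <- rsdenoise:::with_seed(56,
    array(rnorm(n_sub * n_seed * V), c(n_sub, n_seed, V)))
  rp0 <- split_half_reproducibility(noise, n_permutations = 100, rng_seed = 3)
  expect_true(mean(abs(rp0$pseudo_z) <= 2) >= 0.75)
})

test_that("reproducibility grows with the planted signal-to-noise ratio", {
  V <- 500; n_sub <- 10; n_seed <- 4
  base <- rsdenoise:::with_seed(57, matrix(rnorm(n_seed * V), n_seed, V))
  make_A <- function(amp) {
    A <- array(NA_real_, c(n_sub, n_seed, V))
    rsdenoise:::with_seed(58, {
      for (i in seq_len(n_sub)) {
        A[i, , ] <- amp * base + matrix(rnorm(n_seed * V), n_seed, V)
      }
    })
    A
  }
  z1 <- split_half_reproducibility(make_A(0.3), 60, rng_seed = 4)$pseudo_z
  z3 <- split_half_reproducibility(make_A(0.9), 60, rng_seed = 4)$pseudo_z
  expect_gt(median(z3), median(z1))
})

test_that("collect_metrics aggregates seeds and reports missing cells", {
  rec <- tidyr::expand_grid(subject_id = c("a", "b"),
                            technique = c("t1", "t2"), seed = 1:3)
  rec$identifiability_z <- 2
  rec$edge_activity_pct <- rep(c(1, 2, 3), 4)
  out <- collect_metrics(rec)
  expect_equal(nrow(out), 4)
  expect_true(all(out$identifiability_z == 2))
  expect_true(all(out$edge_activity_pct == 2))  # mean across seeds

  expect_error(collect_metrics(rec[rec$subject_id != "a" | rec$technique != "t2", ]),
               "missing")
})

test_that("the metric table round-trips through TSV unchanged", {
  rec <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:3),
                            technique = c("t1", "t2"))
  rsdenoise:::with_seed(61, {
    rec$identifiability_z <- runif(6, 1, 20)
    rec$edge_activity_pct <- runif(6, 0, 100)
    rec$tdof_fraction <- runif(6)
  })
  tab <- collect_metrics(rec)
  f <- withr::local_tempfile(fileext = ".tsv")
  rsdenoise:::write_tsv_stable(tab, f)
  back <- utils::read.delim(f)
  expect_equal(back$identifiability_z, tab$identifiability_z, tolerance = 1e-9)
  expect_equal(back$subject_id, tab$subject_id)
})
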