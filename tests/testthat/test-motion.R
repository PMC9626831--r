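test_that("framewise displacement matches the hand-computed example", {
  p <- rbind(c(0, 0, 0, 0, 0, 0),
             c(0.001, 0, 0.002, 0.1, 0.2, 0.1))
  fwd <- framewise_displacement(motion_trace(p, tr = 2.5), head_radius_mm = 50)
  expect_equal(fwd, c(0, 0.55))
})

test_that("FWD is zero for constant traces and invariant to offsets", {
  p <- matrix(rep(c(0.01, -0.02, 0.005, 1, -2, 0.5), each = 10), ncol = 6)
  expect_equal(framewise_displacement(motion_trace(p, 2)), rep(0, 10))

  q <- rsdenoise:::with_seed(1, matrix(rnorm(60), ncol = 6))
  off <- q + matrix(rep(c(5, -3, 2, 10, -7, 1), each = 10), ncol = 6)
  expect_equal(framewise_displacement(motion_trace(q, 2)),
               framewise_displacement(motion_trace(off, 2)))
})

test_that("censor mask thresholds FWD and is monotone in the cutoff", {
  cm <- censor_mask(c(0, 0.6, 0.3), 0.5)
  expect_equal(cm$keep, c(TRUE, FALSE, TRUE))
  expect_equal(cm$n_dropped, 1L)
  expect_true(all(censor_mask(rep(0, 5), 0.2)$keep))

  fwd <- rsdenoise:::with_seed(3, abs(rnorm(200, 0.3, 0.2)))
  cuts <- c(0.1, 0.2, 0.3, 0.5, 1)
  drops <- sapply(cuts, function(ct) censor_mask(fwd, ct)$n_dropped)
  expect_true(all(diff(drops) <= 0))
})

test_that("24-parameter expansion has the Friston structure", {
  tr <- simulate_motion_trace(50, 2.5, "hf_tremor", rng_seed = 2)
  X <- expand_motion_24(tr)
  expect_equal(dim(X), c(50, 24))
  p <- as.matrix(tibble::as_tibble(tr)[, -1])
  expect_equal(unname(X[, 13:18]), unname(p^2))          # squares
  expect_equal(unname(X[, 7:12]), unname(rbind(0, p[-50, ])))  # lags
  expect_equal(unname(X[, 19:24]), unname(rbind(0, p[-50, ])^2))
  expect_error(expand_motion_24(p[1, , drop = FALSE]), "2 timepoints")
})

test_that("tdof accounting returns exact fractions", {
  cm <- censor_mask(c(rep(1, 20), rep(0, 268)), 0.5)
  td <- tdof_loss(cm, 288)
  expect_equal(td$n_lost, 20L)
  expect_equal(td$fraction_lost, 20 / 288)
  expect_equal(td$source, "censoring")

  td2 <- tdof_loss(43, 288)
  expect_equal(td2$fraction_lost, 43 / 288)

  expect_equal(tdof_loss(censor_mask(rep(0, 10), 0.5), 10)$fraction_lost, 0)
})

test_that("tremor traces show the many-spikes-above-0.2 pattern", {
  for (seed in c(7, 19, 101)) {
    tr <- simulate_motion_trace(288, 2.5, "hf_tremor", rng_seed = seed)
    fwd <- framewise_displacement(tr)
    expect_gte(sum(fwd > 0.2), 144)
    expect_lte(sum(fwd > 0.5), 28)
  }
  smooth <- simulate_motion_trace(288, 2.5, "smooth", rng_seed = 7)
  expect_lt(median(framewise_displacement(smooth)), 0.2)
})

test_that("censoring at 0.2 mm loses far more frames than at 0.5 mm on tremor traces", {
  tr <- simulate_motion_trace(288, 2.5, "hf_tremor", rng_seed = 11)
  fwd <- framewise_displacement(tr)
  d02 <- censor_mask(fwd, 0.2)$n_dropped
  d05 <- censor_mask(fwd, 0.5)$n_dropped
  expect_gte(d02, 0.5 * 288)
  expect_gte(d02, 3 * d05)
})

test_that("motion files round-trip through the 6-column text format", {
  tr <- simulate_motion_trace(40, 2.5, "hf_tremor", rng_seed = 5)
  f <- withr::local_tempfile(fileext = ".txt")
  write_motion(tr, f)
  back <- read_motion(f, tr = 2.5)
  expect_equal(rsdenoise:::motion_params(back), rsdenoise:::motion_params(tr),
               tolerance = 1e-8)
  # degree-dialect import converts rotations
  m <- rsdenoise:::motion_params(tr)
  m[, 1:3] <- m[, 1:3] * 180 / pi
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_motion(motion_trace(m, 2.5), f2)
  back2 <- read_motion(f2, tr = 2.5, units = "degrees")
  expect_equal(rsdenoise:::motion_params(back2)[, 1:3],
               rsdenoise:::motion_params(tr)[, 1:3], tolerance = 1e-8)
})
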