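# exhaustive-enumeration Mann-Whitney oracle: U and exact two-sided p
enumeration_mwu <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  pooled <- c(x, y)
  n <- length(x)
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mu <- length(x) * length(y) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}

test_that("Kruskal-Wallis H matches hand-ranked arithmetic and degenerates to 0", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0,
               tolerance = 1e-12)
  kw <- kruskal_wallis(list(c(1, 2, 3), c(7, 8, 9)))
  # ranks 1..6, R1=6, R2=15: H = 12/(6*7)*(12+75) - 21 = 27/7
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-10)
  expect_equal(kw$df, 1)

  same <- kruskal_wallis(list(rep(2, 4), rep(2, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("Kruskal-Wallis p-values are calibrated under the null", {
  set.seed(90)
  p <- replicate(400, {
    v <- rnorm(15)
    kruskal_wallis(split(v, rep(1:3, each = 5)))$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pairwise Mann-Whitney matches the enumeration oracle for small groups", {
  cases <- list(
    list(x = c(1, 2), y = c(3, 4)),
    list(x = c(1, 5, 9), y = c(2, 3, 4)),
    list(x = c(10, 11, 12, 13), y = c(1, 2, 3, 14)),
    list(x = c(0.5, 2.5, 7), y = c(1, 2, 3, 4, 5))
  )
  for (cs in cases) {
    got <- pairwise_mannwhitney_bonferroni(list(a = cs$x, b = cs$y))
    want <- enumeration_mwu(cs$x, cs$y)
    expect_equal(got$statistic, want$U)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
  # [1,2] vs [3,4]: all first-group values smaller -> U = 0
  expect_equal(pairwise_mannwhitney_bonferroni(list(c(1, 2), c(3, 4)))$statistic, 0)
})

test_that("Bonferroni correction uses the pairwise family and caps at 1", {
  groups <- rsdenoise:::with_seed(91, lapply(1:5, function(i) rnorm(6, mean = i / 4)))
  out <- pairwise_mannwhitney_bonferroni(groups)
  expect_equal(nrow(out), 10)
  expect_true(all(out$n_comparisons == 10))
  expect_true(all(out$p_corrected >= out$p_value - 1e-15))
  expect_true(all(out$p_corrected <= 1))
  expect_equal(out$p_corrected, pmin(1, out$p_value * 10))

  same <- pairwise_mannwhitney_bonferroni(list(rep(1, 3), rep(1, 3)))
  expect_equal(same$p_corrected, 1)
})

test_that("rank_techniques flags best and worst by each metric's direction", {
  tab <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:4),
                            technique = c("alpha", "beta", "gamma"))
  tab$identifiability_z <- rep(c(10, 5, 7), each = 4) + rep(c(0, .1, .2, .3), 3)
  tab$edge_activity_pct <- rep(c(3, 9, 1), each = 4) + rep(c(0, .1, .2, .3), 3)
  cmp <- rank_techniques(tab)
  gl <- glance(cmp)
  ident <- gl[gl$metric == "identifiability_z", ]
  expect_equal(ident$best, "alpha")   # higher better
  expect_equal(ident$worst, "beta")
  edge <- gl[gl$metric == "edge_activity_pct", ]
  expect_equal(edge$best, "gamma")    # lower better
  expect_equal(edge$worst, "beta")
  expect_equal(nrow(tidy(cmp)), 2 * 3)  # 2 metrics x 3 pairs

  # ties flag both techniques
  tab2 <- tab
  tab2$identifiability_z <- rep(c(10, 10, 7), each = 4) + rep(c(0, .1, .2, .3), 3)
  g2 <- glance(rank_techniques(tab2[, c("subject_id", "technique",
                                        "identifiability_z")]))
  expect_equal(g2$best, "alpha,beta")
})

test_that("single-technique tables yield summaries without tests", {
  tab <- tibble::tibble(subject_id = sprintf("s%d", 1:4), technique = "only",
                        identifiability_z = c(1, 2, 3, 4))
  cmp <- rank_techniques(tab)
  expect_true(is.na(glance(cmp)$kruskal_H))
  expect_equal(nrow(tidy(cmp)), 0)
})

test_that("metrics without a defined direction of goodness are rejected", {
  tab <- tibble::tibble(subject_id = c("a", "b"), technique = "t",
                        made_up_metric = c(1, 2))
  expect_error(rank_techniques(tab, metrics = "made_up_metric"),
               "direction undefined")
})
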