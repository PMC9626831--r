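#' Seed-based connectivity map
#'
#' Correlates every brain voxel's time series with the mean time course of a
#' seed region, then Fisher-z transforms the correlations. r values are
#' clipped to ±(1 − 1e−7) before `atanh` so z stays finite.
#'
#' @param volume A [volume4d()].
#' @param seed_mask Logical 3D seed region (non-empty, inside the brain).
#' @param brain_mask Logical 3D analysis mask.
#' @param seed_index Optional seed identifier carried into the result.
#' @return An `rsn_map`: `zmap` (3D array, 0 outside the brain), `rmap`,
#'   `brain_mask`, optional `seed_index`.
#' @export
seed_correlation_map <- function(volume, seed_mask, brain_mask,
                                 seed_index = NA_integer_) {
  fail_if(!any(seed_mask), "seed mask is empty")
  fail_if(any(seed_mask & !brain_mask), "seed mask extends outside the brain mask")
  seed_ts <- mask_mean_ts(volume, seed_mask)
  fail_if(stats::sd(seed_ts) < 1e-12, "seed mean time course has zero variance")
  Y <- mask_matrix(volume, brain_mask)       # T x V
  sds <- apply(Y, 2, stats::sd)
  r <- rep(0, ncol(Y))
  ok <- sds > 1e-12
  if (any(ok)) {
    r[ok] <- as.numeric(stats::cor(seed_ts, Y[, ok, drop = FALSE]))
  }
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  zmap <- array(0, dim = dim(brain_mask))
  zmap[brain_mask] <- z
  rmap <- array(0, dim = dim(brain_mask))
  rmap[brain_mask] <- r
  structure(list(zmap = zmap, rmap = rmap, brain_mask = brain_mask,
                 seed_index = seed_index, thresholded = NULL),
            class = "rsn_map")
}

#' @export
print.rsn_map <- function(x, ...) {
  z <- x$zmap[x$brain_mask]
  cat(sprintf("<rsn_map> seed %s | %d brain voxels | z range [%.3g, %.3g]%s\n",
              ifelse(is.na(x$seed_index), "?", x$seed_index), length(z),
              min(z), max(z),
              if (!is.null(x$thresholded)) {
                sprintf(" | threshold %.3g (%d active)",
                        x$thresholded$threshold, sum(x$thresholded$mask))
              } else ""))
  invisible(x)
}

#' Gaussian-mixture thresholding of a z-map
#'
#' Fits a two-component Gaussian mixture (null + active) to the in-mask z
#' values by EM with deterministic initialisation (means at the 25th/75th
#' percentiles, pooled sd, equal weights) and thresholds at the smallest z
#' above the lower component's mean where the posterior probability of the
#' higher-mean component exceeds 0.5. Degenerate fits (a vanishing component
#' or near-zero spread) fall back to a single component with no
#' suprathreshold voxels.
#'
#' @param zmap 3D array of z values (or an `rsn_map`).
#' @param brain_mask Logical 3D mask (ignored for `rsn_map` input).
#' @param rng_seed Unused (the fit is deterministic); kept for interface
#'   stability.
#' @param max_iter,tol EM controls.
#' @return A list of class `gmm_threshold`: `threshold`, `mask` (3D logical,
#'   `zmap >= threshold`), `fit` (mixture parameters), `degenerate`.
#' @export
gmm_threshold <- function(zmap, brain_mask = NULL, rng_seed = NULL,
                          max_iter = 500, tol = 1e-8) {
  if (inherits(zmap, "rsn_map")) {
    brain_mask <- zmap$brain_mask
    zmap <- zmap$zmap
  }
  fail_if(is.null(brain_mask), "brain_mask required for array input")
  z <- zmap[brain_mask]
  fail_if(length(z) < 100, "need at least 100 in-mask voxels, got %d", length(z))

  fit <- fit_gmm2(z, max_iter = max_iter, tol = tol)
  if (fit$degenerate) {
    return(structure(list(threshold = Inf,
                          mask = array(FALSE, dim = dim(zmap)),
                          fit = fit, degenerate = TRUE,
                          message = "no suprathreshold voxels"),
                     class = "gmm_threshold"))
  }
  thr <- posterior_crossing(fit, upper = max(z))
  mask <- array(FALSE, dim = dim(zmap))
  if (is.finite(thr)) mask[brain_mask] <- z >= thr
  structure(list(threshold = thr, mask = mask, fit = fit, degenerate = FALSE),
            class = "gmm_threshold")
}

# Two-component univariate Gaussian EM, quartile-initialised.
fit_gmm2 <- function(z, max_iter = 500, tol = 1e-8) {
  n <- length(z)
  q <- stats::quantile(z, c(0.25, 0.75), names = FALSE)
  mu <- q
  if (diff(q) < 1e-12) mu <- q + c(-1e-6, 1e-6)
  sg <- rep(max(stats::sd(z), 1e-8), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(z, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(z, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    g2 <- d2 / tot
    g1 <- 1 - g2
    n1 <- sum(g1); n2 <- sum(g2)
    if (n1 < 1e-8 || n2 < 1e-8) break
    w <- c(n1, n2) / n
    mu <- c(sum(g1 * z) / n1, sum(g2 * z) / n2)
    sg <- sqrt(c(sum(g1 * (z - mu[1])^2) / n1,
                 sum(g2 * (z - mu[2])^2) / n2))
    sg <- pmax(sg, 1e-8)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  # order components by mean: 1 = null (lower), 2 = active (higher)
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg <- rev(sg); w <- rev(w)
  }
  degenerate <- min(w) < 1e-3 || abs(mu[2] - mu[1]) < 1e-6 ||
    stats::sd(z) < 1e-10
  list(weights = w, means = mu, sds = sg, degenerate = degenerate)
}

# Smallest z above the lower mean where P(active | z) > 0.5. Log-space
# densities keep the posterior finite far into the tails.
posterior_crossing <- function(fit, upper) {
  post <- function(x) {
    ld1 <- log(fit$weights[1]) + stats::dnorm(x, fit$means[1], fit$sds[1],
                                              log = TRUE)
    ld2 <- log(fit$weights[2]) + stats::dnorm(x, fit$means[2], fit$sds[2],
                                              log = TRUE)
    stats::plogis(ld2 - ld1)
  }
  lo <- fit$means[1]
  hi <- max(upper, fit$means[2] + 6 * fit$sds[2])
  grid <- seq(lo, hi, length.out = 2048)
  p <- post(grid)
  ix <- which(p > 0.5)[1]
  if (is.na(ix)) return(Inf)
  if (ix == 1) return(lo)
  stats::uniroot(function(x) post(x) - 0.5, c(grid[ix - 1], grid[ix]),
                 tol = 1e-10)$root
}

#' @export
print.gmm_threshold <- function(x, ...) {
  if (x$degenerate) {
    cat("<gmm_threshold> degenerate fit: no suprathreshold voxels\n")
  } else {
    cat(sprintf("<gmm_threshold> threshold %.4g | %d active voxels | null N(%.3g, %.3g^2) w=%.2f, active N(%.3g, %.3g^2) w=%.2f\n",
                x$threshold, sum(x$mask),
                x$fit$means[1], x$fit$sds[1], x$fit$weights[1],
                x$fit$means[2], x$fit$sds[2], x$fit$weights[2]))
  }
  invisible(x)
}

#' Write an RSN map as NIfTI
#'
#' @param map An `rsn_map`.
#' @param path Output path; the seed index is appended when a directory is
#'   given.
#' @param voxel_size Voxel size in mm.
#' @return The path written, invisibly.
#' @export
write_rsn_map <- function(map, path, voxel_size = c(3.4, 3.4, 3.4)) {
  if (dir.exists(path)) {
    path <- file.path(path, sprintf("rsn_seed-%02d_zmap.nii",
                                    ifelse(is.na(map$seed_index), 0L, map$seed_index)))
  }
  img <- RNifti::asNifti(map$zmap)
  img <- RNifti::`pixdim<-`(img, voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}
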