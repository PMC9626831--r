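#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-subject seed stream, kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Legendre polynomial drift basis
#'
#' Legendre polynomials P_0..P_order evaluated on a uniform grid over
#' \[-1, 1\], the conventional slow-drift basis for fMRI detrending.
#'
#' @param n_timepoints Number of rows.
#' @param order Highest polynomial order (>= 0).
#' @return A `n_timepoints` x `(order + 1)` matrix.
#' @export
legendre_basis <- function(n_timepoints, order) {
  stopifnot(n_timepoints >= 2, order >= 0)
  x <- seq(-1, 1, length.out = n_timepoints)
  P <- matrix(0, n_timepoints, order + 1L)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {
      # Bonnet recursion: k P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  colnames(P) <- paste0("drift_", 0:order)
  P
}

# Separable 3D Gaussian smoothing of one volume (or each frame of a 4D
# array), kernel given as FWHM in mm per axis.
gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size) {
  if (all(fwhm_mm <= 0)) return(arr)
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  voxel_size <- rep_len(voxel_size, 3L)
  sigma_vox <- (fwhm_mm / voxel_size) / (2 * sqrt(2 * log(2)))
  kernels <- lapply(sigma_vox, function(s) {
    if (s <= 1e-8) return(1)
    half <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-half, half))^2 / (2 * s^2))
    k / sum(k)
  })
  smooth_axis <- function(x, k, axis) {
    if (length(k) == 1L) return(x)
    half <- (length(k) - 1L) / 2L
    d <- dim(x)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- matrix(xp, nrow = dp[1])
    n <- nrow(m)
    # replicate-pad ends so edges are not darkened
    mp <- rbind(m[rep(1L, half), , drop = FALSE], m,
                m[rep(n, half), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    }
    dim(out) <- dp
    aperm(out, order(perm))
  }
  apply_one <- function(v) {
    for (ax in 1:3) v <- smooth_axis(v, kernels[[ax]], ax)
    v
  }
  if (length(dim(arr)) == 3L) {
    apply_one(arr)
  } else {
    for (t in seq_len(dim(arr)[4])) {
      arr[, , , t] <- apply_one(arr[, , , t, drop = TRUE])
    }
    arr
  }
}

# One-step 6-neighbour binary erosion.
erode_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    r <- array(FALSE, dim(m))
    idx_src <- lapply(dim(m), seq_len)
    idx_dst <- idx_src
    n <- dim(m)[ax]
    if (by == 1) {
      idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1)
    } else {
      idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n
    }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  for (ax in 1:3) {
    out <- out & shift(mask, ax, 1) & shift(mask, ax, -1)
  }
  out
}

# Erosion depth per voxel: 0 outside mask, 1 on its outermost layer, etc.
# Serves as an integer distance-to-boundary transform.
erosion_depth <- function(mask) {
  depth <- array(0L, dim(mask))
  cur <- mask
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    depth[cur] <- k
    cur <- erode_mask(cur)
    if (k > max(dim(mask))) break
  }
  depth
}

# White noise band-limited to [low, high] Hz by a hard DFT mask,
# scaled to unit standard deviation. Returns a length-n vector.
bandlimited_noise <- function(n, tr, low_hz, high_hz) {
  x <- stats::rnorm(n)
  y <- bandpass_series(matrix(x, ncol = 1), low_hz, high_hz, tr)[, 1]
  s <- stats::sd(y)
  if (s < 1e-12) stop("empty passband for the given length and TR")
  y / s
}

fail_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}
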