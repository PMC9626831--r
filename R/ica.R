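#' Spatial ICA decomposition of a 4D volume
#'
#' PCA whitening across timepoints followed by symmetric FastICA (tanh
#' contrast) on the voxel dimension, the standard spatial-ICA model for
#' fMRI: the data are unmixed into spatially independent component maps
#' with associated component time courses (the mixing matrix). Component
#' time courses are variance-normalised; noise labels are left all-`FALSE`
#' (labelling is an external input).
#'
#' @param volume A [volume4d()].
#' @param brain_mask Logical 3D array; analysis restricted to these voxels.
#' @param n_components Number of components; `NULL` places the cut at the
#'   last clear drop (factor > 1.5) in the eigenspectrum within the first
#'   `T/4` components, separating structured components from the smooth
#'   noise tail. Over-asking pulls near-Gaussian noise components into the
#'   unmixing, which the FastICA iteration cannot separate; on persistent
#'   non-convergence the dimension is shrunk geometrically before failing.
#' @param rng_seed Seed for the random orthogonal unmixing init.
#' @param max_iter,tol FastICA iteration controls.
#' @param restarts Number of deterministic re-initialisations tried before
#'   declaring non-convergence.
#' @return A `decomposition`: `mixing` (T x C), `maps` (C x V over in-mask
#'   voxels), `noise_label` (C, all `FALSE`), `brain_mask`, `var_explained`.
#' @export
decompose_spatial_ica <- function(volume, brain_mask, n_components = NULL,
                                  rng_seed = 1L, max_iter = 1000, tol = 1e-5,
                                  restarts = 3) {
  stopifnot(inherits(volume, "volume4d"))
  fail_if(!any(brain_mask), "brain mask is empty")
  Y <- mask_matrix(volume, brain_mask)       # T x V
  T <- nrow(Y); V <- ncol(Y)
  Y <- Y - matrix(colMeans(Y), T, V, byrow = TRUE)  # demean voxels
  Y <- Y - rowMeans(Y)                               # centre variables

  cv <- tcrossprod(Y) / V
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  cum <- cumsum(eg$values[pos]) / sum(eg$values[pos])
  if (is.null(n_components)) {
    # scree-gap rule: cut where the eigenspectrum last drops by a clear
    # factor, separating structured components from the smooth noise tail
    lam <- eg$values[pos]
    upper <- min(max(2L, floor(T / 4)), length(lam) - 1L)
    ratios <- lam[seq_len(upper)] / lam[seq_len(upper) + 1L]
    gaps <- which(ratios > 1.5)
    n_components <- if (length(gaps)) max(gaps) else 2L
    n_components <- max(2L, min(n_components, which(cum >= 0.95)[1]))
  }
  C0 <- as.integer(n_components)
  fail_if(C0 >= T, "n_components (%d) must be < T (%d)", C0, T)
  fail_if(C0 < 1 || C0 > sum(pos), "n_components out of range (1..%d)", sum(pos))

  # symmetric FastICA with deterministic restarts; when the requested
  # subspace holds components too Gaussian to separate the iteration can
  # cycle, so on persistent non-convergence the dimension is reduced by one
  # (the usual practitioner remedy) before giving up
  init_seeds <- derive_seeds(rng_seed, restarts)
  converged <- FALSE
  iters <- 0L
  delta <- Inf
  W <- NULL; C <- C0; E <- NULL; Dh <- NULL; Z <- NULL
  C_ladder <- C0
  while (C_ladder[length(C_ladder)] > 2L) {
    C_ladder <- c(C_ladder, max(2L, floor(0.7 * C_ladder[length(C_ladder)])))
  }
  for (C_try in C_ladder) {
    C <- C_try
    E <- eg$vectors[, 1:C, drop = FALSE]
    Dh <- sqrt(eg$values[1:C])
    Z <- crossprod(E, Y) / Dh                # C x V, white across voxels
    for (attempt in seq_len(restarts)) {
      W <- with_seed(init_seeds[attempt], {
        qr.Q(qr(matrix(stats::rnorm(C * C), C, C)))
      })
      for (it in seq_len(max_iter)) {
        iters <- it
        WZ <- W %*% Z
        G <- tanh(WZ)
        W_new <- tcrossprod(G, Z) / V - diag(rowMeans(1 - G^2), C) %*% W
        sw <- eigen(tcrossprod(W_new), symmetric = TRUE)
        W_new <- sw$vectors %*% diag(1 / sqrt(pmax(sw$values, 1e-12)), C) %*%
          t(sw$vectors) %*% W_new
        delta <- max(abs(1 - abs(rowSums(W_new * W))))
        W <- W_new
        if (delta < tol) { converged <- TRUE; break }
      }
      if (converged) break
    }
    if (converged) break
  }
  fail_if(!converged,
          "FastICA did not converge in %d iterations x %d restarts (last delta %.2e)",
          max_iter, restarts, delta)

  S <- W %*% Z                               # C x V spatial maps
  A <- E %*% (Dh * t(W))                     # T x C mixing (time courses)
  # deterministic sign: largest-|value| map voxel positive
  for (c in seq_len(C)) {
    peak <- which.max(abs(S[c, ]))
    if (S[c, peak] < 0) { S[c, ] <- -S[c, ]; A[, c] <- -A[, c] }
  }
  # variance-normalise mixing columns
  sds <- apply(A, 2, stats::sd)
  sds[sds < 1e-12] <- 1
  A <- sweep(A, 2, sds, `/`)
  S <- S * sds

  structure(
    list(mixing = A, maps = S, noise_label = rep(FALSE, C),
         brain_mask = brain_mask, var_explained = cum[C], n_iter = iters),
    class = "decomposition"
  )
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d components over %d frames (%d labelled noise, %.1f%% variance)\n",
              ncol(x$mixing), nrow(x$mixing), sum(x$noise_label),
              100 * x$var_explained))
  invisible(x)
}

#' Label components against ground-truth noise time courses
#'
#' Marks a component as noise when its time course correlates (absolute
#' Pearson r above `r_threshold`) with any planted noise time course or with
#' the framewise-displacement series — the oracle stand-in for an external
#' component classifier.
#'
#' @param decomposition A [decompose_spatial_ica()] result.
#' @param subject A `synthetic_subject` (supplies truth and FWD), or a
#'   T x Q matrix of noise time courses.
#' @param r_threshold Absolute-correlation threshold.
#' @return The decomposition with `noise_label` filled in.
#' @export
label_components_oracle <- function(decomposition, subject, r_threshold = 0.5) {
  ref <- if (inherits(subject, "synthetic_subject")) {
    cbind(subject$truth_noise_timecourses, fwd = subject$fwd)
  } else {
    as.matrix(subject)
  }
  ref <- ref[, apply(ref, 2, stats::sd) > 1e-12, drop = FALSE]
  fail_if(ncol(ref) == 0, "no usable reference noise time courses")
  cors <- abs(stats::cor(decomposition$mixing, ref))
  decomposition$noise_label <- apply(cors, 1, max) > r_threshold
  decomposition
}

#' Read a noise-component label file
#'
#' Plain text, one 1-based component index per line.
#'
#' @param path File path.
#' @param n_components Total number of components.
#' @return Logical vector of length `n_components`.
#' @export
read_component_labels <- function(path, n_components) {
  idx <- as.integer(readLines(path))
  idx <- idx[!is.na(idx)]
  fail_if(any(idx < 1 | idx > n_components),
          "%s: component index out of range 1..%d", path, n_components)
  lab <- rep(FALSE, n_components)
  lab[idx] <- TRUE
  lab
}

#' Aggressive component regression
#'
#' Full OLS removal of the noise-labelled component time courses (plus any
#' extra confounds): all variance those columns explain is removed.
#'
#' @param volume A [volume4d()].
#' @param decomposition A `decomposition` with at least one noise label.
#' @param extra_design Optional additional confound columns (T x K matrix).
#' @return A denoised `volume4d`.
#' @export
regress_components_aggressive <- function(volume, decomposition,
                                          extra_design = NULL) {
  fail_if(!any(decomposition$noise_label), "no components labelled as noise")
  X <- decomposition$mixing[, decomposition$noise_label, drop = FALSE]
  if (!is.null(extra_design)) X <- cbind(X, as.matrix(extra_design))
  regress_full(volume, X)
}

#' Non-aggressive (partial) component regression
#'
#' Fits the full mixing matrix (all components) to each voxel by least
#' squares and subtracts only the noise-labelled components' fitted
#' contribution: `Y_clean = Y - M_noise beta_noise` with
#' `beta = pinv(M_all) Y`. Variance shared between noise and retained
#' components is attributed to the retained ones and kept.
#'
#' @param volume A [volume4d()].
#' @param decomposition A `decomposition` with noise labels.
#' @return A denoised `volume4d`.
#' @export
regress_components_nonaggressive <- function(volume, decomposition) {
  fail_if(!any(decomposition$noise_label), "no components labelled as noise")
  d <- dim(volume$data)
  fail_if(nrow(decomposition$mixing) != d[4], "decomposition covers %d frames, volume has %d",
          nrow(decomposition$mixing), d[4])
  M <- scale(decomposition$mixing, center = TRUE, scale = FALSE)
  sv <- svd(M)
  posv <- sv$d > max(sv$d) * 1e-10
  if (!all(posv)) {
    message(sprintf("mixing matrix rank-deficient (condition number %.3g); using pseudoinverse",
                    max(sv$d) / min(sv$d[sv$d > 0])))
  }
  pinv <- sv$v[, posv, drop = FALSE] %*%
    (t(sv$u[, posv, drop = FALSE]) / sv$d[posv])
  Y <- t(matrix(volume$data, prod(d[1:3]), d[4]))  # T x V
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  beta <- pinv %*% Yc                              # C x V
  noise <- decomposition$noise_label
  fit_noise <- M[, noise, drop = FALSE] %*% beta[noise, , drop = FALSE]
  out <- sweep(Yc - fit_noise, 2, mu, `+`)
  volume$data <- array(t(out), dim = d)
  volume
}
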