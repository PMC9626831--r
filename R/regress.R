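#' Full (aggressive) nuisance regression
#'
#' Ordinary least squares projection: every voxel time series is regressed
#' on the centred design plus an intercept, and the residual is returned
#' with the voxel mean restored. All variance the design columns explain is
#' removed; residuals are orthogonal to every design column. Collinear
#' columns are dropped via pivoted QR with a warning.
#'
#' @param volume A [volume4d()].
#' @param design A [build_design_matrix()] design, or a plain T x K matrix.
#' @return A `volume4d` of identical geometry.
#' @export
regress_full <- function(volume, design) {
  stopifnot(inherits(volume, "volume4d"))
  X <- if (inherits(design, "design_matrix")) design$values else as.matrix(design)
  d <- dim(volume$data)
  fail_if(nrow(X) != d[4], "design rows (%d) != timepoints (%d)", nrow(X), d[4])
  fail_if(ncol(X) >= d[4], "design has %d columns for %d timepoints", ncol(X), d[4])
  Y <- t(matrix(volume$data, prod(d[1:3]), d[4]))  # T x V
  res <- ols_residuals(Y, X)
  volume$data <- array(t(res), dim = d)
  volume
}

# Residuals of Y (T x V) on [1, centred X], voxel means restored.
ols_residuals <- function(Y, X) {
  T <- nrow(Y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  keep <- apply(Xc, 2, function(col) max(abs(col)) > 1e-12)
  Xc <- Xc[, keep, drop = FALSE]
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  if (ncol(Xc) == 0) return(sweep(Yc, 2, mu, `+`))
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    warning(sprintf("design rank-deficient: using %d of %d columns",
                    qrx$rank, ncol(Xc)))
  }
  res <- qr.resid(qrx, Yc)
  sweep(res, 2, mu, `+`)
}
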