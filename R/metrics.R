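map_values <- function(map, mask) {
  z <- if (inherits(map, "rsn_map")) map$zmap else map
  z[mask]
}

# Coerce per-subject, per-seed maps into an n_subjects x n_seeds x n_voxels
# array over the brain mask.
stack_maps <- function(maps, brain_mask = NULL) {
  if (is.array(maps) && length(dim(maps)) == 3L && is.numeric(maps)) {
    return(maps)
  }
  fail_if(!is.list(maps) || !length(maps), "expected a list of per-subject map lists")
  n_sub <- length(maps)
  n_seed <- length(maps[[1]])
  if (is.null(brain_mask) && inherits(maps[[1]][[1]], "rsn_map")) {
    brain_mask <- maps[[1]][[1]]$brain_mask
  }
  fail_if(is.null(brain_mask), "brain_mask required for plain-array maps")
  V <- sum(brain_mask)
  A <- array(NA_real_, dim = c(n_sub, n_seed, V))
  for (i in seq_len(n_sub)) {
    fail_if(length(maps[[i]]) != n_seed, "subject %d has %d maps, expected %d",
            i, length(maps[[i]]), n_seed)
    for (s in seq_len(n_seed)) {
      A[i, s, ] <- map_values(maps[[i]][[s]], brain_mask)
    }
  }
  A
}

#' Split-half network reproducibility
#'
#' For each random permutation the cohort is split into halves and each
#' half's per-seed z-maps are averaged; the spatial Pearson correlations
#' between corresponding half-means (the diagonal of the seed-by-seed
#' correlation matrix) measure reproducibility, while correlations between
#' non-corresponding seeds (off-diagonals) form the null. Each seed's pooled
#' diagonal values are standardised against the pooled null into a pseudo-z:
#' `(mean(diag_s) - mean(null)) / sd(null)`.
#'
#' @param maps Per-subject, per-seed unthresholded z-maps: a list (subjects)
#'   of lists (seeds) of `rsn_map`s or 3D arrays, or an
#'   `n_subjects x n_seeds x n_voxels` array.
#' @param n_permutations Number of random split-half permutations.
#' @param rng_seed Integer seed.
#' @param brain_mask Needed when `maps` contains plain arrays.
#' @return A tibble with one row per seed: `seed`, `pseudo_z`, `mean_diag_r`;
#'   attributes `diag` (permutations x seeds matrix) and `null` (pooled
#'   off-diagonal correlations).
#' @export
split_half_reproducibility <- function(maps, n_permutations = 500, rng_seed = 1L,
                                       brain_mask = NULL) {
  A <- stack_maps(maps, brain_mask)
  n_sub <- dim(A)[1]; n_seed <- dim(A)[2]
  fail_if(n_sub < 4, "need at least 4 subjects, got %d", n_sub)
  fail_if(n_seed < 2, "need at least 2 seeds for an off-diagonal null")
  half <- floor(n_sub / 2)

  # flatten to subjects x (seed, voxel) so half-averaging is one colMeans
  V <- dim(A)[3]
  flat <- matrix(A, n_sub, n_seed * V)
  diag_r <- matrix(NA_real_, n_permutations, n_seed)
  null_r <- vector("list", n_permutations)
  with_seed(rng_seed, {
    for (p in seq_len(n_permutations)) {
      perm <- sample.int(n_sub)
      h1 <- perm[seq_len(half)]
      h2 <- perm[(half + 1):n_sub]
      M1 <- matrix(colMeans(flat[h1, , drop = FALSE]), n_seed, V)
      M2 <- matrix(colMeans(flat[h2, , drop = FALSE]), n_seed, V)
      R <- stats::cor(t(M1), t(M2))
      diag_r[p, ] <- diag(R)
      null_r[[p]] <- R[row(R) != col(R)]
    }
  })
  null <- unlist(null_r)
  mu0 <- mean(null)
  sd0 <- stats::sd(null)
  fail_if(sd0 < 1e-12, "degenerate null distribution (zero spread)")
  out <- tibble::tibble(
    seed = seq_len(n_seed),
    pseudo_z = (colMeans(diag_r) - mu0) / sd0,
    mean_diag_r = colMeans(diag_r)
  )
  attr(out, "diag") <- diag_r
  attr(out, "null") <- null
  attr(out, "n_permutations") <- n_permutations
  out
}

#' Network identifiability
#'
#' Ratio of the mean absolute z inside a reference network mask to the mean
#' absolute z outside it (within the brain), computed on unthresholded maps.
#' A map carrying no network information scores 1.
#'
#' @param zmap 3D z array or `rsn_map`.
#' @param reference_mask Logical 3D reference network mask (inside the brain).
#' @param brain_mask Logical 3D analysis mask.
#' @return The identifiability score (positive scalar).
#' @export
identifiability <- function(zmap, reference_mask, brain_mask) {
  fail_if(!any(reference_mask), "reference mask is empty")
  fail_if(any(reference_mask & !brain_mask), "reference mask extends outside the brain")
  inside <- mean(abs(map_values(zmap, reference_mask)))
  outside_mask <- brain_mask & !reference_mask
  fail_if(!any(outside_mask), "no voxels outside the reference mask")
  outside <- mean(abs(map_values(zmap, outside_mask)))
  fail_if(outside < 1e-12, "degenerate map: zero mean |z| outside the reference mask")
  inside / outside
}

#' Connectivity sub-scores of identifiability
#'
#' True-positive connectivity (mean connection strength inside the target
#' network), false-positive connectivity (mean strength in grey matter
#' outside the target), and WM / CSF connectivity. Averaging is done on the
#' Fisher-z scale and reported back-transformed as r.
#'
#' @param map An `rsn_map` (z values are used).
#' @param atlas A [make_phantom_atlas()] atlas.
#' @param reference_mask Target network mask.
#' @return One-row tibble: `tp_conn_r`, `fp_conn_r`, `wm_conn_r`, `csf_conn_r`.
#' @export
connectivity_subscores <- function(map, atlas, reference_mask) {
  fail_if(!any(reference_mask), "reference mask is empty")
  fp_mask <- atlas$gm_mask & !reference_mask
  for (nm in c("fp_mask", "wm_mask", "csf_mask")) {
    m <- if (nm == "fp_mask") fp_mask else atlas[[nm]]
    fail_if(!any(m), "%s region is empty", nm)
  }
  zmean <- function(mask) mean(map_values(map, mask))
  tibble::tibble(
    tp_conn_r = tanh(zmean(reference_mask)),
    fp_conn_r = tanh(zmean(fp_mask)),
    wm_conn_r = tanh(zmean(atlas$wm_mask)),
    csf_conn_r = tanh(zmean(atlas$csf_mask))
  )
}

#' Edge activity
#'
#' Percentage of edge-mask voxels that are suprathreshold in a thresholded
#' activation mask; activation along the brain edge marks residual motion
#' artifact.
#'
#' @param active_mask Logical 3D mask of active voxels, or a
#'   [gmm_threshold()] result.
#' @param edge_mask Logical 3D edge shell.
#' @return Percentage in `[0, 100]`.
#' @export
edge_activity <- function(active_mask, edge_mask) {
  if (inherits(active_mask, "gmm_threshold")) active_mask <- active_mask$mask
  fail_if(!any(edge_mask), "edge mask is empty")
  fail_if(!all(dim(active_mask) == dim(edge_mask)), "mask grids differ")
  100 * sum(active_mask & edge_mask) / sum(edge_mask)
}

#' Spatial smoothness of a 3D map
#'
#' Fourier-amplitude concentration statistic: the 3D DFT amplitude spectrum
#' is split by spheres of increasing radius (j/7 of the maximum frequency
#' radius, j = 1..6, DC excluded) and each radius contributes the ratio of
#' the mean amplitude inside the sphere (low spatial frequencies) to the
#' mean outside (high frequencies). The statistic is the mean of the six
#' ratios; smoother, more spatially cohesive maps concentrate amplitude at
#' low frequencies and score higher, while fragmented, noise-like maps score
#' lower. Invariant to positive rescaling of the map.
#'
#' @param zmap 3D array or `rsn_map`.
#' @param n_radii Number of spherical shells (default 6).
#' @return The smoothness fraction (positive scalar).
#' @export
spatial_smoothness <- function(zmap, n_radii = 6) {
  z <- if (inherits(zmap, "rsn_map")) zmap$zmap else zmap
  d <- dim(z)
  fail_if(length(d) != 3L, "expected a 3D map")
  fail_if(any(d < 8), "all dimensions must be >= 8 for %d shells", n_radii)
  amp <- Mod(stats::fft(z))
  f_axis <- function(n) {
    k <- 0:(n - 1)
    pmin(k, n - k) / (n / 2)
  }
  f1 <- f_axis(d[1]); f2 <- f_axis(d[2]); f3 <- f_axis(d[3])
  r <- sqrt(outer(outer(f1^2, f2^2, `+`), f3^2, `+`))
  rmax <- max(r)
  dc <- array(FALSE, d); dc[1, 1, 1] <- TRUE
  ratios <- vapply(seq_len(n_radii), function(j) {
    rho <- j / (n_radii + 1) * rmax
    inside <- r <= rho & !dc
    outside <- r > rho
    fail_if(!any(inside) || !any(outside),
            "grid too small: empty frequency shell at radius %d", j)
    mean(amp[inside]) / mean(amp[outside])
  }, numeric(1))
  mean(ratios)
}

#' Assemble per-subject, per-technique metric records
#'
#' Binds per-map metric rows into the long benchmark table, averaging
#' per-seed metrics across seeds so each (subject, technique) cell is one
#' row. Missing cells (a subject lacking a technique) are an error, not a
#' silent drop.
#'
#' @param records A tibble (or list of rows) with at least `subject_id` and
#'   `technique`, optionally `seed`, plus numeric metric columns.
#' @return A tibble with one row per (subject, technique).
#' @export
collect_metrics <- function(records) {
  tab <- if (inherits(records, "data.frame")) {
    tibble::as_tibble(records)
  } else {
    dplyr::bind_rows(records)
  }
  fail_if(!all(c("subject_id", "technique") %in% names(tab)),
          "records need subject_id and technique columns")
  num_cols <- names(tab)[vapply(tab, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "seed")
  out <- tab |>
    dplyr::group_by(.data$subject_id, .data$technique) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  grid <- tidyr::expand_grid(subject_id = unique(out$subject_id),
                             technique = unique(out$technique))
  missing <- dplyr::anti_join(grid, out, by = c("subject_id", "technique"))
  fail_if(nrow(missing) > 0, "missing metric cells: %s",
          paste(missing$subject_id, missing$technique, sep = "/", collapse = ", "))
  dplyr::arrange(out, .data$technique, .data$subject_id)
}

#' Plot the benchmark metric table
#'
#' Faceted boxplots of each metric by technique.
#'
#' @param metric_table Output of [collect_metrics()].
#' @param metrics Metric columns to show (default: all numeric).
#' @return A ggplot object.
#' @export
plot_metrics <- function(metric_table, metrics = NULL) {
  num_cols <- names(metric_table)[vapply(metric_table, is.numeric, logical(1))]
  if (!is.null(metrics)) num_cols <- intersect(num_cols, metrics)
  long <- tidyr::pivot_longer(metric_table, dplyr::all_of(num_cols),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$technique, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
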