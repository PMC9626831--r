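#' Build a phantom brain atlas
#'
#' Constructs the mask collection every downstream stage works against: an
#' ellipsoidal brain, a 2-voxel edge shell, central CSF, a white-matter
#' shell, a cortical grey-matter band, `n_networks` reference networks (each
#' a pair of spherical blobs inside grey matter) and `n_seeds` small seed
#' regions, each seed a subset of the network it maps to. Stands in for the
#' anatomical segmentation a real study would obtain from structural MRI.
#'
#' @param grid_shape Integer length-3 voxel grid, e.g. `c(32, 32, 32)`.
#' @param n_seeds Number of seed regions (at most `2 * n_networks`).
#' @param n_networks Number of reference network masks.
#' @param rng_seed Integer seed; the atlas is deterministic given it.
#' @param voxel_size Voxel edge lengths in mm.
#' @param blob_radius Network blob radius in voxels.
#' @return A `phantom_atlas`: list of binary masks (`brain_mask`, `gm_mask`,
#'   `wm_mask`, `csf_mask`, `edge_mask`), `seed_masks`, `reference_networks`,
#'   and `seed_to_network` (index per seed, `NA` for unmapped).
#' @export
make_phantom_atlas <- function(grid_shape, n_seeds, n_networks, rng_seed,
                               voxel_size = c(3.4, 3.4, 3.4),
                               blob_radius = 2) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  fail_if(any(grid_shape < 12), "grid too small: each axis needs >= 12 voxels")
  fail_if(n_networks < 1 || n_seeds < 1, "need at least one seed and one network")
  fail_if(n_seeds > 2 * n_networks,
          "infeasible packing: %d seeds exceed 2 per network for %d networks",
          n_seeds, n_networks)

  centre <- (grid_shape + 1) / 2
  semi <- 0.92 * (grid_shape - 1) / 2
  ax <- lapply(1:3, function(i) (seq_len(grid_shape[i]) - centre[i]) / semi[i])
  rho <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))

  brain <- rho <= 1
  interior <- erode_mask(erode_mask(brain))
  edge <- brain & !interior
  csf <- rho <= 0.20
  wm <- rho > 0.25 & rho <= 0.50
  gm <- rho > 0.55 & interior

  # voxel coordinates for sphere carving
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                                  y = seq_len(grid_shape[2]),
                                  z = seq_len(grid_shape[3])))
  sphere_mask <- function(centre_idx, radius) {
    d2 <- (coords[, 1] - centre_idx[1])^2 + (coords[, 2] - centre_idx[2])^2 +
      (coords[, 3] - centre_idx[3])^2
    array(d2 <= radius^2, dim = grid_shape)
  }

  # greedy blob-centre packing deep inside the grey-matter band
  cand <- which(gm & rho > 0.60 & rho <= 0.88)
  fail_if(length(cand) < 10 * n_networks,
          "infeasible packing: grey-matter band too small for %d networks", n_networks)
  n_blobs <- 2L * n_networks
  min_sep <- 2 * blob_radius + 2
  centres <- with_seed(rng_seed, {
    order_cand <- sample(cand)
    picked <- matrix(NA_real_, 0, 3)
    for (v in order_cand) {
      p <- coords[v, ]
      if (nrow(picked) == 0 ||
          min(sqrt(rowSums(sweep(picked, 2, p)^2))) >= min_sep) {
        picked <- rbind(picked, p)
        if (nrow(picked) == n_blobs) break
      }
    }
    picked
  })
  fail_if(nrow(centres) < n_blobs,
          "infeasible packing: could not place %d network blobs on a %s grid",
          n_blobs, paste(grid_shape, collapse = "x"))

  networks <- vector("list", n_networks)
  for (m in seq_len(n_networks)) {
    b1 <- sphere_mask(centres[2 * m - 1, ], blob_radius)
    b2 <- sphere_mask(centres[2 * m, ], blob_radius)
    networks[[m]] <- (b1 | b2) & gm
    fail_if(sum(networks[[m]]) < 4, "network %d degenerate after grey-matter clip", m)
  }

  seed_to_network <- ((seq_len(n_seeds) - 1L) %% n_networks) + 1L
  seeds <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    m <- seed_to_network[s]
    which_blob <- if (s > n_networks) 2L else 1L
    c_idx <- centres[2 * (m - 1) + which_blob, ]
    seeds[[s]] <- sphere_mask(c_idx, 1) & networks[[m]]
    fail_if(sum(seeds[[s]]) < 1, "seed %d empty after network clip", s)
  }

  structure(
    list(
      grid_shape = grid_shape,
      voxel_size = rep_len(voxel_size, 3L),
      brain_mask = brain,
      gm_mask = gm,
      wm_mask = wm,
      csf_mask = csf,
      edge_mask = edge,
      seed_masks = seeds,
      reference_networks = networks,
      seed_to_network = seed_to_network
    ),
    class = "phantom_atlas"
  )
}

#' @export
print.phantom_atlas <- function(x, ...) {
  cat(sprintf(
    "<phantom_atlas> grid %s | brain %d vox (edge %d, gm %d, wm %d, csf %d) | %d seeds -> %d networks\n",
    paste(x$grid_shape, collapse = "x"), sum(x$brain_mask), sum(x$edge_mask),
    sum(x$gm_mask), sum(x$wm_mask), sum(x$csf_mask),
    length(x$seed_masks), length(x$reference_networks)))
  invisible(x)
}

#' Summarise atlas masks as a tibble
#'
#' @param x A `phantom_atlas`.
#' @param ... Unused.
#' @return A tibble with one row per mask and its voxel count.
#' @export
tidy.phantom_atlas <- function(x, ...) {
  base <- tibble::tibble(
    mask = c("brain", "gm", "wm", "csf", "edge",
             paste0("seed_", seq_along(x$seed_masks)),
             paste0("network_", seq_along(x$reference_networks))),
    n_voxels = c(sum(x$brain_mask), sum(x$gm_mask), sum(x$wm_mask),
                 sum(x$csf_mask), sum(x$edge_mask),
                 vapply(x$seed_masks, sum, numeric(1)),
                 vapply(x$reference_networks, sum, numeric(1)))
  )
  base
}
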