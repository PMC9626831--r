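#' Simulation configuration
#'
#' Defaults describe an older-adult-like resting-state cohort: 12-minute
#' runs at TR 2.5 s, ~1% network fluctuations band-limited below 0.1 Hz,
#' motion-coupled edge artifacts, physiological signals shared across
#' WM/CSF/global compartments with a partial leak into the network time
#' courses (the shared-variance structure that separates aggressive from
#' non-aggressive component regression), cubic scanner drift and thermal
#' noise. Signal units are arbitrary scanner units on a baseline of 1000.
#'
#' @param n_subjects Cohort size.
#' @param n_timepoints Frames per run.
#' @param tr Repetition time, seconds.
#' @param network_amplitude Amplitude of each planted network time course.
#' @param motion_artifact_amplitude Amplitude of the FWD-coupled edge artifact.
#' @param physio_amplitude Amplitude of shared physiological signals.
#' @param drift_amplitude Scale of polynomial drift coefficients.
#' @param thermal_sd White-noise standard deviation.
#' @param hf_motion_fraction Fraction of subjects given tremor-like motion.
#' @param passband Frequency band (Hz) of the planted network signals.
#' @param physio_leak Correlation-scale leak of low-frequency respiratory
#'   signal into the network time courses (0 = none).
#' @param baseline Mean intensity inside the brain.
#' @param rng_seed Master seed; all per-subject seeds derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12, n_timepoints = 288, tr = 2.5,
                       network_amplitude = 10, motion_artifact_amplitude = 20,
                       physio_amplitude = 8, drift_amplitude = 20,
                       thermal_sd = 5, hf_motion_fraction = 0.5,
                       passband = c(0.01, 0.08), physio_leak = 0.3,
                       baseline = 1000, rng_seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_timepoints = as.integer(n_timepoints),
    tr = tr, network_amplitude = network_amplitude,
    motion_artifact_amplitude = motion_artifact_amplitude,
    physio_amplitude = physio_amplitude, drift_amplitude = drift_amplitude,
    thermal_sd = thermal_sd, hf_motion_fraction = hf_motion_fraction,
    passband = as.numeric(passband), physio_leak = physio_leak,
    baseline = baseline, rng_seed = as.integer(rng_seed)
  )
  amps <- c("network_amplitude", "motion_artifact_amplitude", "physio_amplitude",
            "drift_amplitude", "thermal_sd")
  for (a in amps) fail_if(cfg[[a]] < 0, "%s must be >= 0", a)
  fail_if(cfg$n_timepoints < 2, "n_timepoints must be >= 2")
  fail_if(!(cfg$passband[1] > 0 && cfg$passband[2] > cfg$passband[1] &&
              cfg$passband[2] < 1 / (2 * cfg$tr)),
          "passband must satisfy 0 < low < high < Nyquist")
  fail_if(cfg$hf_motion_fraction < 0 || cfg$hf_motion_fraction > 1,
          "hf_motion_fraction must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d subjects, T=%d @ TR %.2gs | network %.3g, artifact %.3g, physio %.3g, drift %.3g, thermal %.3g | hf fraction %.2f | band %.3g-%.3g Hz | seed %d\n",
    x$n_subjects, x$n_timepoints, x$tr, x$network_amplitude,
    x$motion_artifact_amplitude, x$physio_amplitude, x$drift_amplitude,
    x$thermal_sd, x$hf_motion_fraction, x$passband[1], x$passband[2], x$rng_seed))
  invisible(x)
}

# Exponential distance-to-edge weight (scale 2 voxels): 1 on the brain
# surface, decaying inward — the spatial footprint of motion artifacts.
edge_weight <- function(atlas, scale = 2) {
  depth <- erosion_depth(atlas$brain_mask)
  w <- exp(-(pmax(depth - 1L, 0L)) / scale)
  w[!atlas$brain_mask] <- 0
  w
}

#' Simulate one synthetic subject
#'
#' Builds the voxel signal as
#' `baseline + sum_k network_map_k * network_tc_k + motion artifact +
#' physiological signals + polynomial drift + thermal noise`, where the
#' motion artifact is weighted toward the brain edge (exponential decay,
#' scale 2 voxels) with amplitude proportional to framewise displacement,
#' respiratory/cardiac-like signals are shared across WM, CSF and the whole
#' brain, and a fraction `physio_leak` of the low-frequency respiratory
#' signal leaks into every network time course.
#'
#' @param atlas A [make_phantom_atlas()] atlas.
#' @param config A [sim_config()].
#' @param subject_seed Integer seed for this subject.
#' @param motion_mode `"smooth"` or `"hf_tremor"`.
#' @return A `synthetic_subject`: `volume`, `motion`, ground-truth network
#'   and noise time courses, and per-component noise labels.
#' @export
simulate_subject <- function(atlas, config, subject_seed,
                             motion_mode = c("smooth", "hf_tremor")) {
  stopifnot(inherits(atlas, "phantom_atlas"), inherits(config, "sim_config"))
  motion_mode <- match.arg(motion_mode)
  T <- config$n_timepoints
  tr <- config$tr
  M <- length(atlas$reference_networks)

  motion <- simulate_motion_trace(T, tr, motion_mode, rng_seed = subject_seed)
  fwd <- framewise_displacement(motion)

  with_seed(subject_seed + 1L, {
    # physiological signals: low-frequency respiratory-volume and faster
    # cardiac-rate fluctuations, unit sd
    nyq <- 1 / (2 * tr)
    resp <- bandlimited_noise(T, tr, 0.01, 0.05)
    card <- bandlimited_noise(T, tr, 0.06, min(0.15, 0.9 * nyq))

    # band-limited network time courses with a respiratory leak
    lam <- config$physio_leak
    resp_in_band <- bandpass_series(resp, config$passband[1], config$passband[2], tr)
    if (stats::sd(resp_in_band) > 1e-12) {
      resp_in_band <- resp_in_band / stats::sd(resp_in_band)
    }
    net_tc <- sapply(seq_len(M), function(m) {
      gp <- bandlimited_noise(T, tr, config$passband[1], config$passband[2])
      sqrt(1 - lam^2) * gp + lam * resp_in_band
    })
    net_tc <- matrix(net_tc, nrow = T)

    # FWD-coupled artifact time course, unit sd when motion is present
    art_tc <- fwd - mean(fwd)
    if (stats::sd(art_tc) > 1e-12) art_tc <- art_tc / stats::sd(art_tc) else art_tc[] <- 0

    drift_basis <- legendre_basis(T, 3)[, -1, drop = FALSE]  # P1..P3
    drift_coef <- stats::rnorm(ncol(drift_basis))
    drift_tc <- drift_basis %*% drift_coef

    d <- atlas$grid_shape
    vol <- array(0, dim = c(d, T))
    brain_v <- as.vector(atlas$brain_mask)
    nb <- sum(brain_v)
    mat <- matrix(0, nb, T)  # brain voxels x time

    mat <- mat + config$baseline
    for (m in seq_len(M)) {
      in_net <- as.vector(atlas$reference_networks[[m]])[brain_v]
      if (any(in_net)) {
        mat[in_net, ] <- mat[in_net, ] +
          config$network_amplitude * matrix(net_tc[, m], sum(in_net), T, byrow = TRUE)
      }
    }

    w_edge <- as.vector(edge_weight(atlas))[brain_v]
    mat <- mat + config$motion_artifact_amplitude * (w_edge %o% art_tc)

    wm_v <- as.vector(atlas$wm_mask)[brain_v]
    csf_v <- as.vector(atlas$csf_mask)[brain_v]
    physio_global <- 0.3 * resp
    physio_wm <- 0.8 * resp + 0.4 * card
    physio_csf <- 1.0 * resp + 0.8 * card
    mat <- mat + config$physio_amplitude * (rep(1, nb) %o% physio_global)
    if (any(wm_v)) {
      mat[wm_v, ] <- mat[wm_v, ] +
        config$physio_amplitude * matrix(physio_wm, sum(wm_v), T, byrow = TRUE)
    }
    if (any(csf_v)) {
      mat[csf_v, ] <- mat[csf_v, ] +
        config$physio_amplitude * matrix(physio_csf, sum(csf_v), T, byrow = TRUE)
    }

    mat <- mat + config$drift_amplitude * (rep(1, nb) %o% as.numeric(drift_tc))
    if (config$thermal_sd > 0) {
      mat <- mat + matrix(stats::rnorm(nb * T, sd = config$thermal_sd), nb, T)
    }

    vm <- matrix(vol, prod(d), T)
    vm[brain_v, ] <- mat
    vol <- array(vm, dim = c(d, T))

    noise_tc <- cbind(artifact = art_tc, resp = resp, card = card)
    structure(
      list(
        id = NA_character_,
        volume = volume4d(vol, tr, atlas$voxel_size),
        motion = motion,
        fwd = fwd,
        motion_mode = motion_mode,
        truth_network_timecourses = net_tc,
        truth_noise_timecourses = noise_tc,
        truth_drift = drift_basis,
        truth_component_labels = c(rep(FALSE, M), rep(TRUE, ncol(noise_tc))),
        seed = subject_seed
      ),
      class = "synthetic_subject"
    )
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s | %s motion | median FWD %.3g mm\n",
              ifelse(is.na(x$id), "(unnamed)", x$id), x$motion_mode,
              stats::median(x$fwd)))
  print(x$volume)
  invisible(x)
}

#' Simulate a cohort of synthetic subjects
#'
#' Per-subject seeds are derived deterministically from `config$rng_seed`;
#' the first `round(hf_motion_fraction * n)` subjects receive tremor-like
#' high-frequency motion, the rest move smoothly. With `out_dir` set, each
#' subject's 4D NIfTI volume, motion text file and ground-truth time courses
#' are written as they are generated and, when `keep_in_memory = FALSE`,
#' dropped immediately, bounding memory by one subject.
#'
#' @param atlas A [make_phantom_atlas()] atlas.
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param keep_in_memory Return the subject objects (default `TRUE` when
#'   `out_dir` is `NULL`).
#' @return A list with `subjects` (possibly empty) and `manifest`, a tibble
#'   with one row per subject (id, seed, motion mode, file paths).
#' @export
simulate_cohort <- function(atlas, config, out_dir = NULL,
                            keep_in_memory = is.null(out_dir)) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  fail_if(n < 2, "a cohort needs at least 2 subjects")
  seeds <- derive_seeds(config$rng_seed, n)
  n_hf <- round(config$hf_motion_fraction * n)
  modes <- c(rep("hf_tremor", n_hf), rep("smooth", n - n_hf))
  ids <- sprintf("sub-%03d", seq_len(n))

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE)
    fail_if(!ok, "could not create output directory %s", out_dir)
  }

  subjects <- if (keep_in_memory) vector("list", n) else list()
  vol_paths <- mot_paths <- truth_paths <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- simulate_subject(atlas, config, seeds[i], modes[i])
    s$id <- ids[i]
    if (!is.null(out_dir)) {
      vol_paths[i] <- file.path(out_dir, paste0(ids[i], "_bold.nii"))
      mot_paths[i] <- file.path(out_dir, paste0(ids[i], "_motion.txt"))
      truth_paths[i] <- file.path(out_dir, paste0(ids[i], "_truth.tsv"))
      write_volume(s$volume, vol_paths[i])
      write_motion(s$motion, mot_paths[i])
      truth <- cbind(s$truth_network_timecourses, s$truth_noise_timecourses)
      colnames(truth) <- c(paste0("network_", seq_len(ncol(s$truth_network_timecourses))),
                           colnames(s$truth_noise_timecourses))
      utils::write.table(format(truth, digits = 10, scientific = FALSE, trim = TRUE),
                         truth_paths[i], sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (keep_in_memory) subjects[[i]] <- s
  }

  manifest <- tibble::tibble(
    subject_id = ids, seed = as.integer(seeds), motion_mode = modes,
    volume_path = vol_paths, motion_path = mot_paths, truth_path = truth_paths
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", pretty = TRUE, na = "null")
  }
  list(subjects = subjects, manifest = manifest)
}

#' Read and write 4D volumes as NIfTI-1
#'
#' @param volume A [volume4d()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` a `volume4d`.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  img <- RNifti::`pixdim<-`(img, c(volume$voxel_size, volume$tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param tr Repetition time override; taken from the header when `NULL`.
#' @export
read_volume <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (is.null(tr)) tr <- if (length(pd) >= 4) pd[4] else 1
  volume4d(array(as.numeric(img), dim = dim(img)), tr = tr,
           voxel_size = pd[1:3], affine = RNifti::xform(img))
}
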