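#' Apply one of the five denoising techniques
#'
#' The benchmarked techniques are:
#' \describe{
#'   \item{`censoring`}{24 motion parameters, spike regressors at frames with
#'     FWD at or above the cutoff, WM and CSF mean signals, Legendre
#'     detrending and bandpass-as-regression, all removed in one OLS fit.}
#'   \item{`censoring_gs`}{As `censoring`, plus the global mean signal.}
#'   \item{`aggressive_aroma`}{Spatial ICA on a copy smoothed with the wider
#'     kernel; noise-labelled component time courses fully regressed from the
#'     narrow-kernel data; then DFT bandpass.}
#'   \item{`nonaggressive_aroma`}{Same ICA, but partial regression: only the
#'     noise components' unique contribution from a joint fit of all
#'     components is removed; then DFT bandpass.}
#'   \item{`sock_style`}{Noise-component time courses appended to the
#'     `censoring` confound set (24 MP, WM/CSF, detrend, bandpass
#'     regressors) in a single OLS fit.}
#' }
#'
#' @param subject A `synthetic_subject` (or a list with `volume`, `motion`,
#'   and — for component techniques without an explicit label file — the
#'   ground-truth noise time courses).
#' @param technique One of `"censoring"`, `"censoring_gs"`,
#'   `"aggressive_aroma"`, `"nonaggressive_aroma"`, `"sock_style"` (aliases
#'   `aggr_aroma`, `nonaggr_aroma`, `sock` accepted).
#' @param atlas A [make_phantom_atlas()] atlas supplying the masks.
#' @param options List of knobs: `fwd_cutoff` (0.5 mm), `head_radius_mm`
#'   (50), `detrend_order` (3), `bandpass` (`TRUE`; `FALSE` skips the band
#'   limitation, e.g. on runs too short to spend frequency regressors),
#'   `passband` (0.009–0.08 Hz), `smooth`
#'   (`TRUE`), `smooth_fwhm` (4 mm), `ica_fwhm` (6 mm), `n_components`
#'   (`NULL` = automatic), `labels` (logical vector or label-file path;
#'   `NULL` = oracle labels from ground truth), `label_r_threshold` (0.5),
#'   `rng_seed` (ICA init; defaults to the subject's seed). Precomputed
#'   intermediates may be passed for reuse across techniques:
#'   `vol_smooth` (the narrow-kernel volume), `vol_ica` (the wide-kernel
#'   copy), `decomposition` (an unlabelled ICA decomposition).
#' @return A list of class `denoise_result`: `volume` (cleaned), `tdof`
#'   ([tdof_loss()] row), `technique`, and `decomposition` where applicable.
#' @export
apply_technique <- function(subject, technique, atlas, options = list()) {
  technique <- normalize_technique(technique)
  opt <- utils::modifyList(list(
    fwd_cutoff = 0.5, head_radius_mm = 50, detrend_order = 3,
    bandpass = TRUE, passband = c(0.009, 0.08),
    smooth = TRUE, smooth_fwhm = 4, ica_fwhm = 6,
    n_components = NULL, labels = NULL, label_r_threshold = 0.5,
    rng_seed = NULL, vol_smooth = NULL, vol_ica = NULL, decomposition = NULL
  ), options)
  if (is.null(opt$rng_seed)) {
    opt$rng_seed <- if (!is.null(subject$seed)) subject$seed else 1L
  }
  band <- if (isTRUE(opt$bandpass)) opt$passband else NULL

  vol0 <- subject$volume
  T <- dim(vol0$data)[4]
  trace <- subject$motion
  fwd <- if (!is.null(subject$fwd)) subject$fwd else {
    framewise_displacement(trace, opt$head_radius_mm)
  }
  vol <- if (!is.null(opt$vol_smooth)) {
    opt$vol_smooth
  } else if (opt$smooth) {
    smooth_volume(vol0, opt$smooth_fwhm)
  } else {
    vol0
  }

  wm_ts <- mask_mean_ts(vol, atlas$wm_mask)
  csf_ts <- mask_mean_ts(vol, atlas$csf_mask)

  if (technique %in% c("censoring", "censoring_gs")) {
    cm <- censor_mask(fwd, opt$fwd_cutoff)
    gs <- if (technique == "censoring_gs") mask_mean_ts(vol, atlas$brain_mask) else NULL
    design <- build_design_matrix(trace, wm_ts, csf_ts, global_ts = gs,
                                  censor = cm, detrend_order = opt$detrend_order,
                                  passband = band, tr = vol$tr,
                                  n_timepoints = T)
    out <- regress_full(vol, design)
    return(structure(list(volume = out, tdof = tdof_loss(cm, T),
                          technique = technique, design = design),
                     class = "denoise_result"))
  }

  # component techniques: ICA on the wide-kernel copy
  dec <- if (!is.null(opt$decomposition)) {
    opt$decomposition
  } else {
    vol_ica <- if (!is.null(opt$vol_ica)) {
      opt$vol_ica
    } else if (opt$smooth) {
      smooth_volume(vol0, opt$ica_fwhm)
    } else {
      vol0
    }
    decompose_spatial_ica(vol_ica, atlas$brain_mask,
                          n_components = opt$n_components,
                          rng_seed = opt$rng_seed)
  }
  dec$noise_label <- resolve_labels(dec, subject, opt)
  fail_if(!any(dec$noise_label),
          "technique '%s' needs at least one noise-labelled component", technique)

  if (technique == "aggressive_aroma") {
    out <- regress_components_aggressive(vol, dec)
    if (!is.null(band)) out <- bandpass_volume(out, band[1], band[2])
  } else if (technique == "nonaggressive_aroma") {
    out <- regress_components_nonaggressive(vol, dec)
    if (!is.null(band)) out <- bandpass_volume(out, band[1], band[2])
  } else { # sock_style: components join the censoring-style design
    comp <- dec$mixing[, dec$noise_label, drop = FALSE]
    colnames(comp) <- paste0("component_", which(dec$noise_label))
    design <- build_design_matrix(trace, wm_ts, csf_ts, global_ts = NULL,
                                  censor = NULL, detrend_order = opt$detrend_order,
                                  passband = band, tr = vol$tr,
                                  n_timepoints = T, extra = comp)
    out <- regress_full(vol, design)
  }

  structure(list(volume = out, tdof = tdof_loss(dec, T),
                 technique = technique, decomposition = dec),
            class = "denoise_result")
}

normalize_technique <- function(technique) {
  aliases <- c(censoring = "censoring", censoring_gs = "censoring_gs",
               aggressive_aroma = "aggressive_aroma", aggr_aroma = "aggressive_aroma",
               nonaggressive_aroma = "nonaggressive_aroma",
               nonaggr_aroma = "nonaggressive_aroma",
               sock_style = "sock_style", sock = "sock_style")
  fail_if(!technique %in% names(aliases),
          "unknown technique '%s' (expected one of %s)", technique,
          paste(unique(aliases), collapse = ", "))
  unname(aliases[technique])
}

resolve_labels <- function(dec, subject, opt) {
  C <- ncol(dec$mixing)
  if (!is.null(opt$labels)) {
    if (is.character(opt$labels)) return(read_component_labels(opt$labels, C))
    fail_if(length(opt$labels) != C,
            "label vector length %d != %d components", length(opt$labels), C)
    return(as.logical(opt$labels))
  }
  fail_if(is.null(subject$truth_noise_timecourses),
          "no labels given and subject carries no ground-truth noise time courses")
  label_components_oracle(dec, subject, opt$label_r_threshold)$noise_label
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("<denoise_result> %s | tDOF lost %d/%d (%.1f%%)\n", x$technique,
              x$tdof$n_lost, x$tdof$n_timepoints, 100 * x$tdof$fraction_lost))
  invisible(x)
}

#' All implemented technique names
#' @return Character vector in canonical order.
#' @export
technique_names <- function() {
  c("censoring", "censoring_gs", "aggressive_aroma",
    "nonaggressive_aroma", "sock_style")
}
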