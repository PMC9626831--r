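#' Construct a motion trace
#'
#' A motion trace is a tibble with one row per frame and six rigid-body
#' parameter columns — `rot_x`, `rot_y`, `rot_z` in radians and `trans_x`,
#' `trans_y`, `trans_z` in mm — carrying the TR as an attribute.
#'
#' @param params T x 6 numeric matrix in the column order above.
#' @param tr Repetition time in seconds.
#' @return A tibble of class `motion_trace`.
#' @export
motion_trace <- function(params, tr) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6L, nrow(params) >= 1L)
  fail_if(any(!is.finite(params)), "motion parameters must be finite")
  out <- tibble::as_tibble(params, .name_repair = "minimal")
  names(out) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  out <- tibble::add_column(out, frame = seq_len(nrow(out)), .before = 1)
  attr(out, "tr") <- tr
  class(out) <- c("motion_trace", class(out))
  out
}

motion_params <- function(trace) {
  as.matrix(trace[, c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")])
}

#' Simulate a rigid-body motion trace
#'
#' `smooth` mode produces slow, low-amplitude drift typical of compliant
#' young adults (median FWD well under 0.2 mm). `hf_tremor` mode adds
#' frame-to-frame jitter near the Nyquist frequency on top of the slow
#' baseline, reproducing the tremor-like pattern seen in older cohorts:
#' most frames exceed the 0.2 mm framewise-displacement threshold while only
#' a small fraction exceed 0.5 mm.
#'
#' @param n_timepoints Number of frames (>= 2).
#' @param tr Repetition time in seconds.
#' @param mode `"smooth"` or `"hf_tremor"`.
#' @param rng_seed Integer seed.
#' @return A [motion_trace()].
#' @export
simulate_motion_trace <- function(n_timepoints, tr, mode = c("smooth", "hf_tremor"),
                                  rng_seed = 1L) {
  fail_if(n_timepoints < 2, "need at least 2 timepoints")
  mode <- match.arg(mode)
  with_seed(rng_seed, {
    slow <- function(scale) {
      # heavily smoothed random walk: gradual head drift
      x <- cumsum(stats::rnorm(n_timepoints, sd = scale))
      stats::filter(x, rep(1 / 9, 9), sides = 2, circular = TRUE)
    }
    rot <- sapply(1:3, function(i) as.numeric(slow(2e-4)))
    trans <- sapply(1:3, function(i) as.numeric(slow(0.02)))
    if (mode == "hf_tremor") {
      # near-Nyquist jitter: fresh value every frame so successive
      # differences stay large (translations 0.06 mm, rotations 0.0008 rad)
      trans <- trans + matrix(stats::rnorm(3 * n_timepoints, sd = 0.06),
                              ncol = 3)
      rot <- rot + matrix(stats::rnorm(3 * n_timepoints, sd = 8e-4), ncol = 3)
    }
    motion_trace(cbind(rot, trans), tr)
  })
}

#' Framewise displacement
#'
#' Per-frame scalar motion magnitude: the sum of absolute backward
#' differences of the three translations (mm) plus the three rotations
#' linearised on a sphere of radius `head_radius_mm`. The first frame has no
#' predecessor and is defined as 0.
#'
#' @param trace A [motion_trace()] or T x 6 matrix (rotations first, radians).
#' @param head_radius_mm Sphere radius used to convert rotations to mm.
#' @return Numeric vector of length T, in mm.
#' @export
framewise_displacement <- function(trace, head_radius_mm = 50) {
  p <- if (inherits(trace, "motion_trace")) motion_params(trace) else as.matrix(trace)
  fail_if(any(!is.finite(p)), "motion parameters must be finite")
  if (nrow(p) == 1L) return(0)
  d <- abs(diff(p))
  fwd <- rowSums(d[, 4:6, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 1:3, drop = FALSE])
  c(0, fwd)
}

#' Motion censoring mask
#'
#' Flags frames whose framewise displacement meets or exceeds the cutoff.
#'
#' @param fwd Numeric FWD series in mm.
#' @param cutoff_mm Positive FWD threshold; frames with `fwd < cutoff_mm` are kept.
#' @return A list of class `censor_mask` with `keep` (logical per frame),
#'   `cutoff_mm`, and `n_dropped`.
#' @export
censor_mask <- function(fwd, cutoff_mm) {
  fail_if(length(fwd) == 0, "empty FWD series")
  fail_if(cutoff_mm <= 0, "cutoff_mm must be positive")
  keep <- fwd < cutoff_mm
  structure(list(keep = keep, cutoff_mm = cutoff_mm, n_dropped = sum(!keep)),
            class = "censor_mask")
}

#' @export
print.censor_mask <- function(x, ...) {
  cat(sprintf("<censor_mask> cutoff %.3g mm: %d of %d frames dropped (%.1f%%)\n",
              x$cutoff_mm, x$n_dropped, length(x$keep),
              100 * x$n_dropped / length(x$keep)))
  invisible(x)
}

#' 24-parameter motion expansion
#'
#' Expands the six rigid-body parameters into the conventional 24-regressor
#' set: the parameters R, their one-frame backward shift R_{t-1}, and the
#' squares of both. Backward-shift values at the first frame are 0.
#'
#' @param trace A [motion_trace()] or T x 6 matrix.
#' @return T x 24 matrix with columns `R*`, `Rlag*`, `Rsq*`, `Rlagsq*`.
#' @export
expand_motion_24 <- function(trace) {
  p <- if (inherits(trace, "motion_trace")) motion_params(trace) else as.matrix(trace)
  fail_if(nrow(p) < 2, "need at least 2 timepoints for the lagged expansion")
  lag1 <- rbind(0, p[-nrow(p), , drop = FALSE])
  out <- cbind(p, lag1, p^2, lag1^2)
  nm <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  colnames(out) <- c(nm, paste0(nm, "_lag"), paste0(nm, "_sq"), paste0(nm, "_lag_sq"))
  out
}

#' Temporal degrees-of-freedom loss
#'
#' Counts frames of temporal information lost to a denoising step: for
#' censoring, the number of dropped frames; for component regression, the
#' number of noise-labelled components — each regressor costs one temporal
#' degree of freedom.
#'
#' @param x A [censor_mask()], a `decomposition` with noise labels, or a
#'   non-negative count of lost regressors.
#' @param n_timepoints Series length the loss is measured against.
#' @return One-row tibble: `n_timepoints`, `n_lost`, `fraction_lost`, `source`.
#' @export
tdof_loss <- function(x, n_timepoints) {
  if (inherits(x, "censor_mask")) {
    fail_if(length(x$keep) != n_timepoints,
            "censor mask covers %d frames, volume has %d", length(x$keep), n_timepoints)
    n_lost <- x$n_dropped
    source <- "censoring"
  } else if (inherits(x, "decomposition")) {
    n_lost <- sum(x$noise_label)
    source <- "components"
  } else {
    fail_if(!is.numeric(x) || length(x) != 1 || x < 0, "expected a count of lost regressors")
    n_lost <- as.integer(x)
    source <- "regressors"
  }
  fail_if(n_lost > n_timepoints, "cannot lose more frames than exist")
  tibble::tibble(
    n_timepoints = as.integer(n_timepoints),
    n_lost = as.integer(n_lost),
    fraction_lost = n_lost / n_timepoints,
    source = source
  )
}

#' Plot a motion trace and its framewise displacement
#'
#' Two panels: translations over time, and the FWD series with the 0.2 mm
#' and 0.5 mm reference thresholds.
#'
#' @param object A [motion_trace()].
#' @param head_radius_mm Passed to [framewise_displacement()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motion_trace <- function(object, head_radius_mm = 50, ...) {
  fwd <- framewise_displacement(object, head_radius_mm)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("frame", "trans_x", "trans_y", "trans_z")],
    -"frame", names_to = "series", values_to = "value")
  long$panel <- "translation (mm)"
  fwd_df <- tibble::tibble(frame = seq_along(fwd), series = "FWD",
                           value = fwd, panel = "framewise displacement (mm)")
  dat <- dplyr::bind_rows(long, fwd_df)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$frame, y = .data$value,
                                    colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(
      data = tibble::tibble(panel = "framewise displacement (mm)",
                            yint = c(0.2, 0.5)),
      ggplot2::aes(yintercept = .data$yint), linetype = "dashed",
      colour = "grey40") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Read a 6-column motion parameter file
#'
#' Whitespace-delimited text, one row per frame, columns
#' `rot_x rot_y rot_z trans_x trans_y trans_z`. Rotations are radians by
#' default; `units = "degrees"` converts on read for files written in the
#' degree dialect.
#'
#' @param path File path.
#' @param tr Repetition time in seconds.
#' @param units `"radians"` or `"degrees"` for the rotation columns.
#' @return A [motion_trace()].
#' @export
read_motion <- function(path, tr, units = c("radians", "degrees")) {
  units <- match.arg(units)
  m <- as.matrix(utils::read.table(path))
  fail_if(ncol(m) != 6, "%s: expected 6 columns, found %d", path, ncol(m))
  if (units == "degrees") m[, 1:3] <- m[, 1:3] * pi / 180
  motion_trace(m, tr)
}

#' Write a motion trace as 6-column text
#'
#' @param trace A [motion_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(trace, path) {
  m <- motion_params(trace)
  utils::write.table(format(m, digits = 10, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
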