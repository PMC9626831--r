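#' Build a nuisance design matrix
#'
#' Assembles the confound regressors of the censoring-style techniques in a
#' single labelled matrix: the 24-parameter motion expansion, one indicator
#' ("spike") column per censored frame, WM and CSF mean signals, an optional
#' global signal, Legendre drift up to `detrend_order`, and — when a
#' passband is given — sine/cosine pairs at every DFT frequency outside the
#' band, which implements the bandpass as regression simultaneous with the
#' other confounds.
#'
#' @param trace A [motion_trace()] (or T x 6 matrix).
#' @param wm_ts,csf_ts WM and CSF mean time courses (length T).
#' @param global_ts Optional global-signal time course.
#' @param censor Optional [censor_mask()].
#' @param detrend_order Legendre drift order (>= 0).
#' @param passband Optional `c(low_hz, high_hz)`; frequencies outside it are
#'   regressed out.
#' @param tr Repetition time, seconds.
#' @param n_timepoints Series length T.
#' @param extra Optional extra columns (matrix with colnames), tagged
#'   `component`.
#' @return A list of class `design_matrix`: `values` (T x K), `labels`,
#'   `categories` (one of motion, spike, tissue, global, drift, frequency,
#'   component).
#' @export
build_design_matrix <- function(trace, wm_ts, csf_ts, global_ts = NULL,
                                censor = NULL, detrend_order = 3,
                                passband = NULL, tr, n_timepoints,
                                extra = NULL) {
  T <- n_timepoints
  cols <- list()
  cats <- character(0)

  mp <- expand_motion_24(trace)
  fail_if(nrow(mp) != T, "motion trace has %d frames, expected %d", nrow(mp), T)
  cols$motion <- mp
  cats <- c(cats, rep("motion", ncol(mp)))

  if (!is.null(censor)) {
    fail_if(length(censor$keep) != T, "censor mask length mismatch")
    bad <- which(!censor$keep)
    if (length(bad)) {
      sp <- matrix(0, T, length(bad))
      sp[cbind(bad, seq_along(bad))] <- 1
      colnames(sp) <- paste0("spike_", bad)
      cols$spike <- sp
      cats <- c(cats, rep("spike", ncol(sp)))
    }
  }

  fail_if(length(wm_ts) != T || length(csf_ts) != T, "tissue series length mismatch")
  tis <- cbind(wm = wm_ts, csf = csf_ts)
  cols$tissue <- tis
  cats <- c(cats, rep("tissue", 2))

  if (!is.null(global_ts)) {
    fail_if(length(global_ts) != T, "global series length mismatch")
    gs <- matrix(global_ts, ncol = 1, dimnames = list(NULL, "global"))
    cols$global <- gs
    cats <- c(cats, "global")
  }

  dr <- legendre_basis(T, detrend_order)
  cols$drift <- dr
  cats <- c(cats, rep("drift", ncol(dr)))

  if (!is.null(passband)) {
    fr <- frequency_regressors(T, tr, passband[1], passband[2])
    if (ncol(fr)) {
      cols$frequency <- fr
      cats <- c(cats, rep("frequency", ncol(fr)))
    }
  }

  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    fail_if(nrow(extra) != T, "extra regressors length mismatch")
    if (is.null(colnames(extra))) {
      colnames(extra) <- paste0("component_", seq_len(ncol(extra)))
    }
    cols$component <- extra
    cats <- c(cats, rep("component", ncol(extra)))
  }

  values <- do.call(cbind, unname(cols))
  fail_if(ncol(values) >= T,
          "design has %d columns for %d timepoints; OLS needs K < T",
          ncol(values), T)
  structure(list(values = values, labels = colnames(values), categories = cats),
            class = "design_matrix")
}

# Sine/cosine regressors at every DFT frequency strictly outside
# [low_hz, high_hz]; the DC bin is omitted (covered by the drift columns).
frequency_regressors <- function(n, tr, low_hz, high_hz) {
  t_idx <- seq_len(n) - 1L
  kmax <- floor(n / 2)
  out <- list()
  for (k in seq_len(kmax)) {
    f <- k / (n * tr)
    if (f >= low_hz - 1e-12 && f <= high_hz + 1e-12) next
    s <- sin(2 * pi * k * t_idx / n)
    co <- cos(2 * pi * k * t_idx / n)
    if (k == n / 2) {
      out[[length(out) + 1L]] <- matrix(co, ncol = 1,
                                        dimnames = list(NULL, sprintf("cos_f%0.4f", f)))
    } else {
      m <- cbind(s, co)
      colnames(m) <- sprintf(c("sin_f%0.4f", "cos_f%0.4f"), f)
      out[[length(out) + 1L]] <- m
    }
  }
  if (!length(out)) return(matrix(0, n, 0))
  do.call(cbind, out)
}

#' @export
print.design_matrix <- function(x, ...) {
  tab <- table(factor(x$categories,
                      levels = c("motion", "spike", "tissue", "global",
                                 "drift", "frequency", "component")))
  cat(sprintf("<design_matrix> %d x %d | %s\n", nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(tab)[tab > 0], tab[tab > 0]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
tidy.design_matrix <- function(x, ...) {
  tibble::tibble(column = x$labels, category = x$categories,
                 sd = apply(x$values, 2, stats::sd))
}
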