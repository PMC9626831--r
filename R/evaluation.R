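#' Kruskal-Wallis test across technique groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k-1 degrees of
#' freedom. When every value in every group is identical the test is
#' degenerate and returns H = 0, p = 1.
#'
#' @param groups List of numeric vectors, one per group.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  fail_if(length(groups) < 2, "need at least 2 groups")
  fail_if(any(lengths(groups) < 1), "every group needs at least one value")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (max(values) - min(values) < 1e-300) {
    return(tibble::tibble(statistic = 0, df = length(groups) - 1L,
                          p_value = 1, n = length(values)))
  }
  kt <- stats::kruskal.test(values, g)
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, n = length(values))
}

#' Pairwise Mann-Whitney U tests with Bonferroni correction
#'
#' All k(k-1)/2 group pairs are compared with two-sided Mann-Whitney U tests
#' (exact p for small tie-free samples, normal approximation with tie and
#' continuity correction otherwise) and Bonferroni-corrected within the
#' family of pairwise tests: `p_corrected = min(1, p * n_pairs)`. The U
#' statistic is oriented to the first-named group: the number of (a, b)
#' pairs with a > b, counting ties as 1/2.
#'
#' @param groups List of numeric vectors.
#' @param labels Group names; defaults to `names(groups)` or indices.
#' @return Tibble with one row per pair: `group_a`, `group_b`, `statistic`
#'   (U), `p_value`, `p_corrected`, `n_comparisons`.
#' @export
pairwise_mannwhitney_bonferroni <- function(groups, labels = NULL) {
  fail_if(length(groups) < 2, "need at least 2 groups")
  fail_if(any(lengths(groups) < 1), "every group needs at least one value")
  if (is.null(labels)) {
    labels <- names(groups)
    if (is.null(labels)) labels <- as.character(seq_along(groups))
  }
  pairs <- utils::combn(length(groups), 2)
  n_comp <- ncol(pairs)
  rows <- lapply(seq_len(n_comp), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    x <- groups[[a]]; y <- groups[[b]]
    if (max(c(x, y)) - min(c(x, y)) < 1e-300) {
      u <- length(x) * length(y) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                                correct = TRUE))
      u <- unname(wt$statistic)
      p <- wt$p.value
    }
    tibble::tibble(group_a = labels[a], group_b = labels[b],
                   statistic = u, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_corrected <- pmin(1, out$p_value * n_comp)
  out$n_comparisons <- n_comp
  out
}

metric_directions <- function() {
  c(reproducibility_z = "higher", identifiability_z = "higher",
    smoothness = "higher", tp_conn_r = "higher",
    edge_activity_pct = "lower", tdof_fraction = "lower",
    fp_conn_r = "lower", wm_conn_r = "lower", csf_conn_r = "lower")
}

#' Rank denoising techniques per quality metric
#'
#' For every metric column: per-technique mean ± sd, best/worst flags by the
#' metric's direction of goodness (higher is better for reproducibility,
#' identifiability, smoothness and true-positive connectivity; lower is
#' better for edge activity, tDOF loss and false-positive/WM/CSF
#' connectivity), a Kruskal-Wallis test across techniques, and the
#' Bonferroni-corrected pairwise Mann-Whitney table. Ties on the mean flag
#' every tied technique.
#'
#' @param metric_table Long table from [collect_metrics()]: one row per
#'   (subject, technique) with numeric metric columns. For reproducibility,
#'   which is a cohort-level quantity, pass the per-seed pseudo-z table via
#'   `reproducibility`.
#' @param reproducibility Optional tibble with `technique`, `seed`,
#'   `pseudo_z` columns; seeds act as the replication unit for that metric.
#' @param metrics Metric columns to rank; defaults to every recognised
#'   metric column present. Requesting a column with no defined direction of
#'   goodness is an error.
#' @return A `technique_comparison` object; see [tidy.technique_comparison()]
#'   and [glance.technique_comparison()].
#' @export
rank_techniques <- function(metric_table, reproducibility = NULL,
                            metrics = NULL) {
  dirs <- metric_directions()
  techniques <- unique(metric_table$technique)
  if (is.null(metrics)) {
    metrics <- intersect(names(dirs), names(metric_table))
  } else {
    unknown <- setdiff(metrics, names(dirs))
    fail_if(length(unknown) > 0, "direction undefined for metric '%s'",
            unknown[1])
    metrics <- intersect(metrics, names(metric_table))
  }
  per_metric <- list()

  eval_metric <- function(name, values_by_tech) {
    direction <- dirs[[name]]
    fail_if(is.null(direction), "direction undefined for metric '%s'", name)
    means <- vapply(values_by_tech, mean, numeric(1))
    sds <- vapply(values_by_tech, stats::sd, numeric(1))
    target <- if (direction == "higher") max(means) else min(means)
    anti <- if (direction == "higher") min(means) else max(means)
    summary <- tibble::tibble(
      technique = names(values_by_tech),
      mean = unname(means), sd = unname(sds),
      n = unname(lengths(values_by_tech)),
      best = abs(means - target) < 1e-12,
      worst = abs(means - anti) < 1e-12
    )
    testable <- length(values_by_tech) >= 2 && all(lengths(values_by_tech) >= 2)
    list(
      metric = name, direction = direction, summary = summary,
      kruskal = if (testable) kruskal_wallis(values_by_tech) else NULL,
      pairwise = if (testable) pairwise_mannwhitney_bonferroni(values_by_tech) else NULL
    )
  }

  for (m in metrics) {
    if (m == "reproducibility_z" && !is.null(reproducibility)) next
    vals <- split(metric_table[[m]], metric_table$technique)[techniques]
    vals <- vals[!vapply(vals, is.null, logical(1))]
    per_metric[[m]] <- eval_metric(m, vals)
  }
  if (!is.null(reproducibility)) {
    vals <- split(reproducibility$pseudo_z, reproducibility$technique)
    per_metric[["reproducibility_z"]] <- eval_metric("reproducibility_z", vals)
  }
  fail_if(!length(per_metric), "no known metric columns found")
  structure(list(metrics = per_metric, techniques = techniques),
            class = "technique_comparison")
}

#' @export
print.technique_comparison <- function(x, ...) {
  cat("<technique_comparison>\n")
  for (m in x$metrics) {
    best <- paste(m$summary$technique[m$summary$best], collapse = ", ")
    worst <- paste(m$summary$technique[m$summary$worst], collapse = ", ")
    p <- if (!is.null(m$kruskal)) sprintf(", KW p = %.3g", m$kruskal$p_value) else ""
    cat(sprintf("  %-20s (%s better): best %s | worst %s%s\n",
                m$metric, m$direction, best, worst, p))
  }
  invisible(x)
}

#' Tidy a technique comparison
#'
#' @param x A `technique_comparison`.
#' @param ... Unused.
#' @return Pairwise Mann-Whitney results, one row per (metric, pair).
#' @export
tidy.technique_comparison <- function(x, ...) {
  rows <- lapply(x$metrics, function(m) {
    if (is.null(m$pairwise)) return(NULL)
    dplyr::mutate(m$pairwise, metric = m$metric, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Glance at a technique comparison
#'
#' @param x A `technique_comparison`.
#' @param ... Unused.
#' @return One row per metric: direction, best/worst technique, H, p.
#' @export
glance.technique_comparison <- function(x, ...) {
  dplyr::bind_rows(lapply(x$metrics, function(m) {
    tibble::tibble(
      metric = m$metric, direction = m$direction,
      best = paste(m$summary$technique[m$summary$best], collapse = ","),
      worst = paste(m$summary$technique[m$summary$worst], collapse = ","),
      kruskal_H = if (!is.null(m$kruskal)) m$kruskal$statistic else NA_real_,
      kruskal_p = if (!is.null(m$kruskal)) m$kruskal$p_value else NA_real_
    )
  }))
}

#' Per-technique summary table of a comparison
#'
#' @param x A `technique_comparison`.
#' @return One row per (metric, technique) with mean, sd and flags.
#' @export
comparison_summary <- function(x) {
  dplyr::bind_rows(lapply(x$metrics, function(m) {
    dplyr::mutate(m$summary, metric = m$metric, direction = m$direction,
                  .before = 1)
  }))
}

#' @rdname rank_techniques
#' @param object A `technique_comparison`.
#' @param ... Unused.
#' @export
autoplot.technique_comparison <- function(object, ...) {
  dat <- comparison_summary(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$technique, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             linewidth = 0.3, fatten = 1.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± sd") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
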