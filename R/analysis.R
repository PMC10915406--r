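#' Pearson correlation with significance
#'
#' Sample Pearson correlation coefficient together with the two-sided
#' p-value from the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r` and `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_eciml("eciml_validation_error", "x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_eciml("eciml_undefined_correlation", "correlation undefined for a constant vector")
  }
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p)
}

#' Correlate dataset statistics with model performance
#'
#' Across a collection of datasets, correlates each dataset statistic
#' (e.g. top-5 protein similarity, AOIE, number of enzymes) with each
#' aggregated model metric (e.g. mean LPOT AUPR). Also returns the
#' statistic-vs-statistic correlation matrix and the linear-regression
#' overlay (slope/intercept) for each pair.
#'
#' @param stats_rows data.frame, one row per dataset: a `dataset` id
#'   column plus one column per statistic.
#' @param result_rows data.frame, one row per dataset: a `dataset` id
#'   column plus one column per metric.
#' @return data.frame of class `correlation_records` with columns
#'   `statistic_name`, `metric_name`, `r`, `r2`, `p_value`, `slope`,
#'   `intercept`, `n`; the statistic correlation matrix is attached as
#'   attribute `"statistic_correlations"`.
#' @export
correlate_statistics_with_performance <- function(stats_rows, result_rows) {
  stopifnot("dataset" %in% names(stats_rows), "dataset" %in% names(result_rows))
  merged <- merge(stats_rows, result_rows, by = "dataset")
  if (nrow(merged) < 3L) {
    stop_eciml("eciml_validation_error",
               "need at least 3 datasets with both statistics and metrics")
  }
  stat_names <- setdiff(names(stats_rows), "dataset")
  metric_names <- setdiff(names(result_rows), "dataset")
  out <- do.call(rbind, lapply(stat_names, function(s) {
    do.call(rbind, lapply(metric_names, function(m) {
      x <- merged[[s]]; y <- merged[[m]]
      pc <- pearson_correlation(x, y)
      slope <- pc$r * stats::sd(y) / stats::sd(x)
      data.frame(statistic_name = s, metric_name = m,
                 r = pc$r, r2 = pc$r^2, p_value = pc$p_value,
                 slope = slope, intercept = mean(y) - slope * mean(x),
                 n = nrow(merged), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "statistic_correlations") <-
    stats::cor(as.matrix(merged[, stat_names, drop = FALSE]))
  class(out) <- c("correlation_records", class(out))
  out
}

#' Per-cluster mean silhouette coefficients
#'
#' For each labelled cluster, the mean silhouette value of its members,
#' computed with Euclidean distances in the descriptor space. Silhouette
#' values lie in \[-1, 1\]: close to 1 for a cluster well separated from
#' the others, around 0 for random labelling.
#'
#' @param vectors numeric matrix (objects x dimensions) or a
#'   [descriptor_table()].
#' @param labels cluster labels, one per object (>= 2 distinct).
#' @return named numeric vector: label -> mean silhouette.
#' @export
per_cluster_silhouette <- function(vectors, labels) {
  if (inherits(vectors, "descriptor_table")) vectors <- vectors$vectors
  vectors <- as.matrix(vectors)
  labels <- as.character(labels)
  stopifnot(nrow(vectors) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop_eciml("eciml_undefined_coefficient",
               "silhouette needs at least 2 clusters")
  }
  f <- factor(labels)
  sil <- cluster::silhouette(as.integer(f), stats::dist(vectors))
  widths <- sil[, "sil_width"]
  out <- tapply(widths, f, mean)
  stats::setNames(as.numeric(out), levels(f))
}

#' 2D embedding of a descriptor table by t-SNE
#'
#' Runs (exact) t-SNE on the descriptor vectors to produce two-dimensional
#' coordinates for visual inspection of, e.g., enzyme-family structure.
#' The perplexity is automatically reduced to `(n - 1) / 3` when the
#' default exceeds what n points support; an explicitly requested
#' perplexity `>= n` is a configuration error. Deterministic given `seed`.
#'
#' @param descriptor_table a [descriptor_table()] or numeric matrix
#'   (n >= 5 rows).
#' @param perplexity t-SNE perplexity (default 30, auto-reduced).
#' @param seed RNG seed for the initial layout.
#' @param max_iter gradient-descent iterations (default 400).
#' @return n x 2 coordinate matrix (rownames = object ids).
#' @export
embed_2d <- function(descriptor_table, perplexity = 30, seed = 1L, max_iter = 400L) {
  explicit <- !missing(perplexity)
  x <- if (inherits(descriptor_table, "descriptor_table")) {
    descriptor_table$vectors
  } else {
    as.matrix(descriptor_table)
  }
  n <- nrow(x)
  if (n < 5L) stop_eciml("eciml_config_error", "t-SNE needs at least 5 points")
  if (explicit && perplexity >= n) {
    stop_eciml("eciml_config_error", "perplexity must be smaller than the number of points")
  }
  perplexity <- min(perplexity, (n - 1) / 3)
  coords <- tsne_exact(x, perplexity = perplexity, seed = seed, max_iter = max_iter)
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("dim1", "dim2")
  coords
}
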