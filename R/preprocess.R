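#' Interquartile-range filter on probes
#'
#' Retains probes whose across-sample interquartile range (IQR) is at least
#' `threshold`; the conventional unsupervised filter that removes probes with
#' little dynamic range before classification. The default of 0.8 log2 units
#' is the standard setting this pipeline documents. Quartiles use linear
#' interpolation between order statistics (R's default, type 7).
#'
#' @param x numeric matrix, probes x samples.
#' @param threshold minimum IQR to keep a probe (>= 0). `0` keeps all probes.
#' @return The matrix restricted to surviving probes, order preserved.
#' @export
iqr_filter <- function(x, threshold = 0.8) {
  .assert_matrix(x, "expression matrix")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("'threshold' must be a single number >= 0")
  q <- matrixStats_rowQuantiles(x, c(0.25, 0.75))
  keep <- (q[, 2L] - q[, 1L]) >= threshold
  x[keep, , drop = FALSE]
}

# Row-wise quantiles (type 7) without a matrixStats dependency.
matrixStats_rowQuantiles <- function(x, probs) {
  t(apply(x, 1L, stats::quantile, probs = probs, names = FALSE, type = 7))
}

#' Standardize probes to mean 0, variance 1
#'
#' Row-wise z-scoring (sample variance, denominator n - 1), the normalization
#' used before clustering, heatmaps and signature scoring.
#'
#' @param x numeric matrix, probes x samples (>= 2 samples).
#' @return Matrix of the same shape with every row at mean 0, variance 1.
#' @export
standardize_probes <- function(x) {
  .assert_matrix(x, "expression matrix")
  if (ncol(x) < 2L) stop("need at least 2 samples to standardize")
  v <- .row_vars(x)
  if (any(v == 0)) {
    bad <- rownames(x)[which(v == 0)]
    stop("zero-variance probe(s): ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  (x - rowMeans(x)) / sqrt(v)
}

#' Center expression within sample groups
#'
#' Subtracts, for every probe, the group mean from each group's samples, so
#' values become relative to the mean expression of the probe within its
#' group. Used to remove tumour-class differences before enrichment analysis
#' ("normalized within the class predictions").
#'
#' @param x numeric matrix, probes x samples.
#' @param groups per-sample group labels (length `ncol(x)`, no missing).
#' @return Matrix with per-probe, per-group means equal to 0.
#' @export
center_within_groups <- function(x, groups) {
  .assert_matrix(x, "expression matrix")
  if (length(groups) != ncol(x))
    stop("'groups' must have one label per sample")
  if (anyNA(groups)) stop("'groups' contains missing labels")
  groups <- as.character(groups)
  out <- x
  for (g in unique(groups)) {
    j <- which(groups == g)
    out[, j] <- x[, j, drop = FALSE] - rowMeans(x[, j, drop = FALSE])
  }
  out
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Clusters probes or samples with average linkage. Distances are Euclidean
#' by default; `"correlation"` uses 1 - Pearson correlation, the usual choice
#' for expression profiles.
#'
#' @param x numeric matrix, probes x samples.
#' @param axis cluster `"rows"` (probes) or `"columns"` (samples).
#' @param distance `"euclidean"` or `"correlation"`.
#' @return An [stats::hclust] object; serialize with [as_newick()].
#' @export
average_linkage_cluster <- function(x,
                                    axis = c("rows", "columns"),
                                    distance = c("euclidean", "correlation")) {
  .assert_matrix(x, "expression matrix")
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  items <- if (axis == "rows") x else t(x)
  if (nrow(items) < 2L) stop("need at least 2 items to cluster")
  d <- switch(distance,
    euclidean = stats::dist(items),
    correlation = stats::as.dist(1 - stats::cor(t(items)))
  )
  stats::hclust(d, method = "average")
}
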