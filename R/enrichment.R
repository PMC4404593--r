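#' Hypergeometric gene-set overlap test
#'
#' For each set, counts the overlap `k` between the query gene list and the
#' set restricted to the universe (`K` genes), and computes the upper-tail
#' hypergeometric probability `P(X >= k)` of drawing at least `k` set genes
#' in `|query|` draws from the universe — the classic "compute overlaps"
#' test against a curated collection. q-values are Benjamini-Hochberg across
#' the tested sets; significant enrichments are conventionally reported at
#' `q < 0.01`.
#'
#' @param query character vector of gene symbols; must lie in `universe`.
#' @param sets named list of character vectors (e.g. from [read_gmt()] or
#'   [simulate_gene_sets()]).
#' @param universe character vector of all eligible gene symbols (e.g. all
#'   annotated genes on the filtered matrix).
#' @return A data frame: `set`, `K` (set size in universe), `k` (overlap),
#'   `ratio` (`k/K`), `p`, `q`, in the input set order.
#' @export
overlap_test <- function(query, sets, universe) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!all(query %in% universe))
    stop("'query' must be a subset of 'universe'")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must be a uniquely named list")
  U <- length(universe)
  nq <- length(query)
  res <- lapply(sets, function(s) {
    s <- intersect(unique(as.character(s)), universe)
    K <- length(s)
    k <- length(intersect(s, query))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, U - K, nq, lower.tail = FALSE)
    c(K = K, k = k, p = p)
  })
  m <- do.call(rbind, res)
  data.frame(set = names(sets), K = as.integer(m[, "K"]),
             k = as.integer(m[, "k"]),
             ratio = ifelse(m[, "K"] > 0, m[, "k"] / m[, "K"], NA_real_),
             p = m[, "p"], q = bh_fdr(m[, "p"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Signal-to-noise ratio per gene between two groups, with the GSEA-style
# floor on each group's standard deviation (at least 0.2 * |mean|, and 0.2
# when the mean is essentially zero).
.signal_to_noise <- function(m1, s1, m2, s2) {
  fix <- function(s, m) {
    floor_ <- 0.2 * abs(m)
    floor_[floor_ < 0.2 * .Machine$double.eps^0.25] <- 0.2
    pmax(s, floor_)
  }
  (m1 - m2) / (fix(s1, m1) + fix(s2, m2))
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score for a ranked
# statistic. `stat` is a named vector (gene-level), `hits` a logical vector
# aligned with `stat`. Genes are ranked by decreasing statistic.
.gsea_es <- function(stat, hits, weight = 1) {
  ord <- order(stat, decreasing = TRUE)
  h <- hits[ord]
  w <- abs(stat[ord])^weight
  Nh <- sum(h)
  N <- length(stat)
  if (Nh == 0L || Nh == N) return(0)
  wh <- sum(w[h])
  p_hit <- cumsum(ifelse(h, w, 0)) / wh
  p_miss <- cumsum(!h) / (N - Nh)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' Permutation gene-set enrichment analysis
#'
#' Ranks genes by the signal-to-noise ratio between two sample groups,
#' computes the weighted Kolmogorov-Smirnov running-sum enrichment score
#' (ES, weight 1 by default) of a gene set on that ranking, and calibrates
#' it against a permutation null. With at least `min_label_perm` samples in
#' each group the null permutes group labels (recomputing the ranking each
#' time); smaller groups fall back to gene-set permutation with a notice.
#' NES is ES divided by the mean magnitude of same-sign permuted scores, and
#' the p-value is the fraction of same-sign permuted scores at least as
#' extreme as the observed ES.
#'
#' Probes are collapsed to genes beforehand by keeping, per gene, the probe
#' with the highest mean expression.
#'
#' @param x numeric matrix, probes x samples.
#' @param groups per-sample labels with exactly 2 levels, each >= 3 samples.
#' @param set character vector of gene symbols.
#' @param annotation data frame with `probe_id`, `gene_symbol`.
#' @param n_perm number of permutations (default 1000).
#' @param weight exponent on the ranking statistic in the running sum.
#' @param seed RNG seed for the permutations.
#' @param min_label_perm minimum per-group size for label permutation.
#' @return A list of class `"gsea_result"`: `es`, `nes`, `p`, `n_perm`,
#'   `perm_type`, `set_size` (genes used), `n_genes` (ranked genes).
#' @export
gsea <- function(x, groups, set, annotation, n_perm = 1000, weight = 1,
                 seed = NULL, min_label_perm = 7) {
  .assert_matrix(x, "expression matrix")
  groups <- factor(as.character(groups))
  if (nlevels(groups) != 2L)
    stop("'groups' must have exactly 2 levels")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 3L) stop("both groups need at least 3 samples")

  # collapse probes -> genes: keep the probe with the highest mean expression
  ann <- annotation[match(rownames(x), annotation$probe_id), ]
  keep <- !is.na(ann$gene_symbol) & nzchar(ann$gene_symbol)
  xg <- x[keep, , drop = FALSE]
  gene <- ann$gene_symbol[keep]
  means <- rowMeans(xg)
  best <- tapply(seq_along(gene), gene, function(ii) ii[which.max(means[ii])])
  xg <- xg[as.integer(best), , drop = FALSE]
  rownames(xg) <- names(best)

  hits <- rownames(xg) %in% set
  if (!any(hits)) stop("gene set has no overlap with the ranked genes")

  g1 <- groups == levels(groups)[1]
  stat_of <- function(sel1) {
    x1 <- xg[, sel1, drop = FALSE]
    x2 <- xg[, !sel1, drop = FALSE]
    .signal_to_noise(rowMeans(x1), sqrt(.row_vars(x1)),
                     rowMeans(x2), sqrt(.row_vars(x2)))
  }
  stat <- stat_of(g1)
  es <- .gsea_es(stat, hits, weight)

  perm_type <- if (min(n1, n2) >= min_label_perm) "label" else "gene_set"
  if (perm_type == "gene_set")
    message("small groups: using gene-set permutation instead of ",
            "label permutation")
  es_perm <- with_seed(seed, {
    if (perm_type == "label") {
      vapply(seq_len(n_perm), function(b) {
        sel1 <- seq_len(ncol(xg)) %in% sample(ncol(xg), n1)
        .gsea_es(stat_of(sel1), hits, weight)
      }, numeric(1))
    } else {
      nh <- sum(hits)
      vapply(seq_len(n_perm), function(b) {
        h <- seq_len(nrow(xg)) %in% sample(nrow(xg), nh)
        .gsea_es(stat, h, weight)
      }, numeric(1))
    }
  })
  same <- es_perm[sign(es_perm) == sign(es)]
  p <- if (length(same)) sum(abs(same) >= abs(es)) / length(same) else 0
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  structure(list(es = es, nes = nes, p = p, n_perm = as.integer(n_perm),
                 perm_type = perm_type, set_size = sum(hits),
                 n_genes = nrow(xg)),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf(
    "GSEA: ES = %.3f, NES = %.3f, p = %.4g (%d %s permutations)\n",
    x$es, x$nes, x$p, x$n_perm, x$perm_type))
  cat(sprintf("  set genes used: %d of %d ranked genes\n",
              x$set_size, x$n_genes))
  invisible(x)
}

#' Chromosomal-instability signature score
#'
#' Translates a signature's gene symbols to probes, keeps the top
#' `variance_keep_fraction` of those probes by across-sample variance (the
#' variance filter that removes redundant, non-responsive probes; 0.5 is the
#' documented setting), standardizes the retained probes to mean 0,
#' variance 1, and scores each sample as the mean of the standardized
#' values. Applied with a chromosomal-instability signature it indexes how
#' chromosome-unstable each tumour looks.
#'
#' @param x numeric matrix, probes x samples.
#' @param signature character vector of gene symbols.
#' @param annotation data frame with `probe_id`, `gene_symbol`.
#' @param variance_keep_fraction fraction of signature probes kept (0, 1\].
#' @return A data frame: `sample_id`, `score`; attribute `n_probes_used`.
#' @export
instability_score <- function(x, signature, annotation,
                              variance_keep_fraction = 0.5) {
  .assert_matrix(x, "expression matrix")
  if (!is.numeric(variance_keep_fraction) || variance_keep_fraction <= 0 ||
      variance_keep_fraction > 1)
    stop("'variance_keep_fraction' must be in (0, 1]")
  probes <- annotation$probe_id[annotation$gene_symbol %in% signature]
  probes <- intersect(probes, rownames(x))
  if (!length(probes))
    stop("no signature probes present in the matrix after translation")
  xs <- x[probes, , drop = FALSE]
  v <- .row_vars(xs)
  n_keep <- max(1L, ceiling(variance_keep_fraction * length(probes)))
  keep <- order(v, decreasing = TRUE)[seq_len(n_keep)]
  xs <- xs[sort(keep), , drop = FALSE]
  v2 <- .row_vars(xs)
  z <- if (all(v2 > 0)) standardize_probes(xs) else xs * 0
  out <- data.frame(sample_id = colnames(x), score = colMeans(z),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_probes_used") <- nrow(xs)
  out
}

#' Correlation between outlier and instability scores
#'
#' Pearson correlation (two-sided p from the t transform) between each
#' sample's outlier score and instability score on the samples present in
#' both tables. A positive correlation links divergence from the known
#' tumour classes to chromosomal instability.
#'
#' @param outliers data frame with `sample_id` and `os` (e.g. from
#'   [loocv_outlier_scores()]).
#' @param instability data frame with `sample_id` and `score` (from
#'   [instability_score()]).
#' @return A list: `r`, `p`, `n`, `conf_int`.
#' @export
correlate_outlier_instability <- function(outliers, instability) {
  if (!all(c("sample_id", "os") %in% names(outliers)))
    stop("'outliers' must have 'sample_id' and 'os' columns")
  if (!all(c("sample_id", "score") %in% names(instability)))
    stop("'instability' must have 'sample_id' and 'score' columns")
  m <- merge(outliers[, c("sample_id", "os")],
             instability[, c("sample_id", "score")], by = "sample_id")
  if (nrow(m) < 3L) stop("need at least 3 shared samples")
  ct <- stats::cor.test(m$os, m$score, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m),
       conf_int = unname(ct$conf.int))
}
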