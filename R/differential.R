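#' Paired differential expression between CUP and metastases of known origin
#'
#' Tests every probe for a CUP-vs-MOKO group effect while eliminating
#' tumour-class differences, by fitting the additive two-factor fixed-effects
#' model `value = class effect + group effect + residual` per probe and
#' t-testing the group coefficient (two-sided) on
#' `n - (number of classes) - 1` residual degrees of freedom. Classes that
#' lack either group cannot contribute a within-class contrast and are
#' excluded with a notice, mirroring how unmatched tumour classes are dropped
#' from a paired analysis.
#'
#' All probes share one design matrix, so a single QR decomposition fits the
#' model for the whole matrix; variances are probe-wise (no pooling or
#' moderation).
#'
#' @param x numeric matrix, probes x samples.
#' @param group per-sample group, `"CUP"` or `"MOKO"`.
#' @param classes per-sample (predicted) tumour class, pairing each CUP with
#'   metastases of the same class.
#' @return A data frame of class `"de_result"`: `probe_id`, `effect` (mean
#'   CUP - MOKO difference after class elimination, log2 units), `t`, `p`,
#'   `q` (Benjamini-Hochberg), `direction` (`"up"`/`"down"`). Attributes
#'   `classes_used`, `classes_dropped`, `df`.
#' @seealso [extract_core_set()], [bh_fdr()]
#' @export
paired_class_test <- function(x, group, classes) {
  .assert_matrix(x, "expression matrix")
  if (length(group) != ncol(x) || length(classes) != ncol(x))
    stop("'group' and 'classes' must have one entry per sample")
  group <- as.character(group)
  if (!all(group %in% c("CUP", "MOKO")))
    stop("'group' must contain only 'CUP' and 'MOKO'")
  classes <- as.character(classes)

  tab <- table(classes, factor(group, levels = c("CUP", "MOKO")))
  ok <- rownames(tab)[tab[, "CUP"] >= 1 & tab[, "MOKO"] >= 1]
  dropped <- setdiff(rownames(tab), ok)
  if (length(dropped))
    message("excluding class(es) without both groups: ",
            paste(dropped, collapse = ", "))
  if (length(ok) < 1L)
    stop("no class contains both CUP and MOKO samples")
  keep <- classes %in% ok
  xs <- x[, keep, drop = FALSE]
  cls <- factor(classes[keep])
  grp <- factor(group[keep], levels = c("MOKO", "CUP"))
  n <- ncol(xs)
  Kc <- nlevels(cls)
  df <- n - Kc - 1L
  if (df < 1L)
    stop("not enough samples for the two-factor model (residual df < 1)")

  X <- stats::model.matrix(~ cls + grp)
  qrX <- qr(X)
  coefs <- qr.coef(qrX, t(xs))
  resid <- qr.resid(qrX, t(xs))
  rss <- colSums(resid^2)
  sigma2 <- rss / df
  v_gg <- chol2inv(qr.R(qrX))[ncol(X), ncol(X)]
  effect <- coefs["grpCUP", ]
  se <- sqrt(sigma2 * v_gg)
  t_stat <- effect / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  out <- data.frame(probe_id = rownames(xs), effect = unname(effect),
                    t = unname(t_stat), p = unname(p),
                    q = bh_fdr(unname(p)),
                    direction = ifelse(effect >= 0, "up", "down"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "classes_used") <- ok
  attr(out, "classes_dropped") <- dropped
  attr(out, "df") <- df
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving on the input indexing.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `pvalues`.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1))
    stop("'pvalues' must be numeric in [0, 1] with no missing values")
  stats::p.adjust(pvalues, method = "BH")
}

#' Extract the CUP core set of differentially expressed probes and genes
#'
#' Splits probes passing `p < p_cutoff` by the sign of the group effect into
#' up- and down-regulated lists and translates them to deduplicated gene
#' symbols; unannotated probes are dropped from the gene lists. The
#' documented cut-off for defining the core set is `p < 1e-8`.
#'
#' @param de a `"de_result"` from [paired_class_test()].
#' @param annotation data frame with `probe_id` and `gene_symbol` columns.
#' @param p_cutoff p-value cut-off in (0, 1); default `1e-8`.
#' @return A list of class `"core_set"`: `up_probes`, `down_probes`,
#'   `up_genes`, `down_genes`, `p_cutoff`.
#' @export
extract_core_set <- function(de, annotation, p_cutoff = 1e-8) {
  if (!all(c("probe_id", "p", "effect") %in% names(de)))
    stop("'de' must come from paired_class_test()")
  if (!all(c("probe_id", "gene_symbol") %in% names(annotation)))
    stop("'annotation' must have 'probe_id' and 'gene_symbol' columns")
  if (!is.numeric(p_cutoff) || p_cutoff <= 0 || p_cutoff >= 1)
    stop("'p_cutoff' must be in (0, 1)")
  hit <- de$p < p_cutoff
  up_probes <- de$probe_id[hit & de$effect > 0]
  down_probes <- de$probe_id[hit & de$effect < 0]
  translate <- function(probes) {
    g <- annotation$gene_symbol[match(probes, annotation$probe_id)]
    unique(g[!is.na(g) & nzchar(g)])
  }
  structure(list(up_probes = up_probes, down_probes = down_probes,
                 up_genes = translate(up_probes),
                 down_genes = translate(down_probes),
                 p_cutoff = p_cutoff),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("CUP core set (p < %g):\n", x$p_cutoff))
  cat(sprintf("  up:   %d probes, %d unique genes\n",
              length(x$up_probes), length(x$up_genes)))
  cat(sprintf("  down: %d probes, %d unique genes\n",
              length(x$down_probes), length(x$down_genes)))
  invisible(x)
}
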