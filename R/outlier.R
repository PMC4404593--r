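#' Leave-one-out outlier scores
#'
#' Scores every labelled sample with `OS = -log p(x)` under a quadratic
#' discriminant model fitted on all *other* samples, so a sample never
#' contributes to the density it is scored against. The held-out model's
#' maximum-a-posteriori class is recorded alongside, giving the
#' correct/incorrect flag used for error-rate binning.
#'
#' Per-class sufficient statistics are updated incrementally across splits,
#' so the loop costs O(probes x classes) per sample. Class priors are fixed
#' at the full-cohort frequencies across splits (see [loocv_grid_search()]).
#'
#' @param x numeric matrix, probes x samples (typically after feature
#'   selection / IQR filtering).
#' @param classes per-sample class labels; every class needs >= 3 samples so
#'   each held-out model still has >= 2 per class.
#' @param method `"qda"` (default; per-class variances) or `"lda"`.
#' @param eps variance floor.
#' @return A data frame of class `"outlier_table"`: `sample_id`, `os`
#'   (natural-log units), `predicted`, `true_class`, `correct`.
#' @seealso [outlier_score()], [bin_error_rates()], [fit_error_curve()]
#' @export
loocv_outlier_scores <- function(x, classes, method = c("qda", "lda"),
                                 eps = 1e-6) {
  .assert_matrix(x, "expression matrix")
  method <- match.arg(method)
  if (length(classes) != ncol(x))
    stop("'classes' must have one label per sample")
  classes <- factor(classes)
  lev <- levels(classes)
  K <- length(lev)
  if (K < 2L) stop("need at least 2 classes")
  n_k <- as.numeric(table(classes))
  if (any(n_k < 3L))
    stop("leave-one-out outlier scoring needs >= 3 samples per class; ",
         "too small: ", paste(lev[n_k < 3L], collapse = ", "))
  n <- ncol(x)
  p <- nrow(x)
  ind <- .class_indicator(classes)
  S_all <- x %*% ind
  Q_all <- (x^2) %*% ind
  log2pi <- log(2 * pi)
  lprior <- log(n_k / n)  # full-cohort priors, fixed across splits

  os <- numeric(n)
  pred <- character(n)
  for (i in seq_len(n)) {
    ki <- as.integer(classes[i])
    xi <- x[, i]
    nk <- n_k; nk[ki] <- nk[ki] - 1
    ntr <- n - 1L
    S <- S_all; S[, ki] <- S[, ki] - xi
    Q <- Q_all; Q[, ki] <- Q[, ki] - xi^2
    mu <- sweep(S, 2L, nk, `/`)
    wss <- pmax(Q - sweep(S^2, 2L, nk, `/`), 0)
    vars <- if (method == "lda") {
      matrix(pmax(rowSums(wss) / ntr, eps), p, K)
    } else {
      pmax(sweep(wss, 2L, nk, `/`), eps)
    }
    lj <- vapply(seq_len(K), function(k) {
      v <- vars[, k]
      -0.5 * (p * log2pi + sum(log(v)) + sum((xi - mu[, k])^2 / v)) +
        lprior[k]
    }, numeric(1))
    os[i] <- -.logsumexp(lj)
    pred[i] <- lev[which.max(lj)]
  }
  out <- data.frame(sample_id = colnames(x), os = os, predicted = pred,
                    true_class = as.character(classes),
                    correct = pred == as.character(classes),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("outlier_table", "data.frame")
  out
}

#' Bin samples by outlier score and compute per-bin error rates
#'
#' Sorts samples by outlier score and splits them into `n_bins`
#' equal-frequency bins (any remainder is spread over the lowest-score
#' bins), then reports each bin's error rate, median OS and OS span — the
#' points of the error-vs-outlier-score curve.
#'
#' @param table an `"outlier_table"` (or any data frame with `os` and
#'   `correct` columns).
#' @param n_bins number of bins (default 10); must not exceed the sample
#'   count.
#' @return A data frame: `bin`, `n`, `os_median`, `os_min`, `os_max`,
#'   `error_rate`.
#' @export
bin_error_rates <- function(table, n_bins = 10) {
  if (!all(c("os", "correct") %in% names(table)))
    stop("'table' must have 'os' and 'correct' columns")
  if (anyNA(table$correct))
    stop("'correct' flags are required for error binning")
  n <- nrow(table)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L || n < n_bins)
    stop("need at least as many samples as bins")
  ord <- order(table$os)
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  idx_end <- cumsum(sizes)
  idx_start <- c(1L, idx_end[-n_bins] + 1L)
  out <- data.frame(bin = seq_len(n_bins), n = sizes,
                    os_median = NA_real_, os_min = NA_real_,
                    os_max = NA_real_, error_rate = NA_real_)
  for (b in seq_len(n_bins)) {
    ii <- ord[idx_start[b]:idx_end[b]]
    out$os_median[b] <- stats::median(table$os[ii])
    out$os_min[b] <- min(table$os[ii])
    out$os_max[b] <- max(table$os[ii])
    out$error_rate[b] <- mean(!table$correct[ii])
  }
  out
}

#' Polynomial fit of error rate on outlier score
#'
#' Least-squares polynomial (default degree 2) of per-bin error rate on the
#' bin's median outlier score. The fitted curve estimates the expected
#' misclassification risk of a new sample from its outlier score alone;
#' predictions are clipped to \[0, 1\].
#'
#' @param bins output of [bin_error_rates()].
#' @param degree polynomial degree; needs at least `degree + 1` bins.
#' @return An object of class `"error_curve"` with `coefficients`
#'   (intercept first), `degree`, and the bin table.
#' @export
fit_error_curve <- function(bins, degree = 2) {
  if (!all(c("os_median", "error_rate") %in% names(bins)))
    stop("'bins' must come from bin_error_rates()")
  degree <- as.integer(degree)
  if (degree < 1L) stop("'degree' must be >= 1")
  if (nrow(bins) < degree + 1L)
    stop("need at least degree + 1 = ", degree + 1L, " bins")
  fit <- stats::lm(error_rate ~ poly(os_median, degree, raw = TRUE),
                   data = bins)
  cf <- unname(stats::coef(fit))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((bins$error_rate - mean(bins$error_rate))^2)
  structure(list(coefficients = cf, degree = degree, bins = bins,
                 r_squared = if (tss > 0) 1 - rss / tss else 1),
            class = "error_curve")
}

#' @export
print.error_curve <- function(x, ...) {
  terms <- c("1", paste0("OS^", seq_len(x$degree)))
  cat("Polynomial error curve (degree ", x$degree, "):\n  error(OS) = ",
      paste(sprintf("%.4g*%s", x$coefficients, terms), collapse = " + "),
      "\n", sep = "")
  cat(sprintf("  R^2 on %d bins: %.3f\n", nrow(x$bins), x$r_squared))
  invisible(x)
}

#' @export
predict.error_curve <- function(object, newdata, ...) {
  os <- if (is.list(newdata)) newdata$os else newdata
  val <- rep(object$coefficients[1], length(os))
  for (d in seq_len(object$degree))
    val <- val + object$coefficients[d + 1] * os^d
  pmin(pmax(val, 0), 1)
}
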