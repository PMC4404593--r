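#' Per-probe one-way ANOVA F statistics
#'
#' Scores every probe for class separation with the one-way ANOVA F test:
#' `F = (SSB / (K - 1)) / (SSW / (N - K))` against the F distribution with
#' `(K - 1, N - K)` degrees of freedom. Used as the univariate feature
#' selection step ahead of discriminant analysis.
#'
#' Probes that are constant across all samples get `F = 0`, `p = 1`; probes
#' with zero within-class variance but real between-class spread get
#' `F = Inf`, `p = 0`.
#'
#' @param x numeric matrix, probes x samples.
#' @param classes per-sample class labels; at least 2 classes, each with at
#'   least 2 samples.
#' @return A data frame with columns `probe_id`, `f`, `p`.
#' @seealso [loocv_grid_search()]
#' @export
f_statistics <- function(x, classes) {
  .assert_matrix(x, "expression matrix")
  if (length(classes) != ncol(x))
    stop("'classes' must have one label per sample")
  classes <- factor(classes)
  lev <- levels(classes)
  K <- length(lev)
  if (K < 2L) stop("need at least 2 classes")
  n_k <- table(classes)
  small <- names(n_k)[n_k < 2L]
  if (length(small))
    stop("class(es) with fewer than 2 samples: ", paste(small, collapse = ", "))
  n <- ncol(x)

  S <- x %*% .class_indicator(classes)           # p x K row sums per class
  Q_tot <- rowSums(x^2)
  grand <- rowSums(S) / n
  nk <- as.numeric(n_k)
  mu <- sweep(S, 2L, nk, `/`)
  within_ss <- Q_tot - rowSums(sweep(S^2, 2L, nk, `/`))
  between_ss <- rowSums(sweep(mu^2, 2L, nk, `*`)) - n * grand^2
  # guard tiny negatives from floating-point cancellation
  within_ss <- pmax(within_ss, 0)
  between_ss <- pmax(between_ss, 0)

  f <- (between_ss / (K - 1)) / (within_ss / (n - K))
  p <- stats::pf(f, K - 1, n - K, lower.tail = FALSE)
  const <- (within_ss + between_ss) <= 1e-12 * pmax(Q_tot, 1)
  f[const] <- 0
  p[const] <- 1
  zero_w <- !const & within_ss == 0
  f[zero_w] <- Inf
  p[zero_w] <- 0
  data.frame(probe_id = rownames(x), f = f, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# samples x K 0/1 indicator matrix for a factor.
.class_indicator <- function(classes) {
  lev <- levels(classes)
  m <- matrix(0, length(classes), length(lev),
              dimnames = list(NULL, lev))
  m[cbind(seq_along(classes), as.integer(classes))] <- 1
  m
}

# Leave-one-out predictions over a grid of F-test p-value cut-offs.
# Feature selection and model fitting are redone inside every split using
# only the remaining samples; sufficient statistics (per-class sums and sums
# of squares) are updated incrementally so the loop is O(p * K) per split.
# Class priors are estimated once from the full cohort and held fixed across
# splits: re-estimating them per split makes the left-out sample's class
# always the rarest in training, a systematic bias that drives null-data
# accuracy below chance.
# Returns a character matrix (samples x cut-offs) of predicted labels.
.loocv_predictions <- function(x, classes, cutoffs,
                               method = "lda", eps = 1e-6) {
  classes <- factor(classes)
  lev <- levels(classes)
  K <- length(lev)
  n <- ncol(x)
  n_k <- as.numeric(table(classes))
  if (any(n_k < 3L))
    stop("leave-one-out with feature selection needs >= 3 samples per class; ",
         "class(es) too small: ",
         paste(lev[n_k < 3L], collapse = ", "))
  p <- nrow(x)
  ind <- .class_indicator(classes)
  S_all <- x %*% ind            # p x K
  Q_all <- (x^2) %*% ind        # p x K
  preds <- matrix(NA_character_, n, length(cutoffs),
                  dimnames = list(colnames(x), as.character(cutoffs)))
  fallback <- 0L
  log2pi <- log(2 * pi)
  lprior <- log(n_k / n)  # full-cohort priors, fixed across splits

  for (i in seq_len(n)) {
    ki <- as.integer(classes[i])
    xi <- x[, i]
    nk <- n_k
    nk[ki] <- nk[ki] - 1
    ntr <- n - 1L
    S <- S_all; S[, ki] <- S[, ki] - xi
    Q <- Q_all; Q[, ki] <- Q[, ki] - xi^2
    mu <- sweep(S, 2L, nk, `/`)
    wss <- pmax(Q - sweep(S^2, 2L, nk, `/`), 0)      # p x K within SS
    within <- rowSums(wss)
    grand <- rowSums(S) / ntr
    between <- pmax(rowSums(sweep(mu^2, 2L, nk, `*`)) - ntr * grand^2, 0)
    f <- (between / (K - 1)) / (within / (ntr - K))
    pv <- stats::pf(f, K - 1, ntr - K, lower.tail = FALSE)
    tot <- rowSums(Q)
    pv[(within + between) <= 1e-12 * pmax(tot, 1)] <- 1
    pv[within == 0 & between > 0] <- 0

    vars <- if (method == "lda") {
      matrix(pmax(within / ntr, eps), p, K)
    } else {
      pmax(sweep(wss, 2L, nk, `/`), eps)
    }

    for (ci in seq_along(cutoffs)) {
      sel <- which(pv < cutoffs[ci])
      if (!length(sel)) {
        preds[i, ci] <- lev[which.max(lprior)]
        fallback <- fallback + 1L
        next
      }
      ll <- vapply(seq_len(K), function(k) {
        v <- vars[sel, k]
        -0.5 * (length(sel) * log2pi + sum(log(v)) +
                  sum((xi[sel] - mu[sel, k])^2 / v)) + lprior[k]
      }, numeric(1))
      preds[i, ci] <- lev[which.max(ll)]
    }
  }
  if (fallback > 0L)
    message(fallback, " split/cut-off combination(s) selected no probes; ",
            "fell back to the prior-only prediction")
  preds
}

#' LOOCV grid search over F-test p-value cut-offs
#'
#' For each left-out sample, recomputes the per-probe F test on the remaining
#' samples, selects probes below each candidate p-value cut-off, fits the
#' discriminant model on those probes, and predicts the held-out sample. The
#' cut-off maximizing leave-one-out accuracy is returned; ties are broken
#' toward the stricter (smaller) cut-off, i.e. fewer features.
#'
#' Class priors are estimated once from the full cohort and held fixed
#' across splits (as in `MASS::lda`'s cross-validation): re-estimating them
#' inside each split makes the left-out sample's class systematically the
#' rarest in training, which biases null-data accuracy below chance. If a
#' cut-off selects no probes in some split, that split's prediction falls
#' back to the highest-prior class.
#'
#' @param x numeric matrix, probes x samples.
#' @param classes per-sample class labels (>= 3 samples per class).
#' @param cutoff_grid numeric vector of p-value cut-offs; default
#'   `10^-(2:12)`.
#' @param method `"lda"` or `"qda"` (diagonal covariance).
#' @param eps variance floor.
#' @return A list of class `"loocv_grid"`: `best_cutoff`, `best_accuracy`,
#'   `accuracy` (named per-cut-off), `predictions` (samples x cut-offs
#'   character matrix), `n` (number of samples).
#' @export
loocv_grid_search <- function(x, classes, cutoff_grid = 10^-(2:12),
                              method = c("lda", "qda"), eps = 1e-6) {
  .assert_matrix(x, "expression matrix")
  method <- match.arg(method)
  if (!length(cutoff_grid)) stop("'cutoff_grid' must be non-empty")
  cutoff_grid <- sort(unique(as.numeric(cutoff_grid)), decreasing = TRUE)
  preds <- .loocv_predictions(x, classes, cutoff_grid, method = method,
                              eps = eps)
  truth <- as.character(classes)
  acc <- apply(preds, 2L, function(p) mean(p == truth))
  best <- which(acc == max(acc))
  best <- best[length(best)]  # grid sorted decreasing -> last max = smallest
  structure(list(best_cutoff = cutoff_grid[best],
                 best_accuracy = unname(acc[best]),
                 accuracy = acc, predictions = preds, n = ncol(x),
                 method = method),
            class = "loocv_grid")
}

#' @export
print.loocv_grid <- function(x, ...) {
  cat("LOOCV grid search (", x$method, ", n = ", x$n, ")\n", sep = "")
  df <- data.frame(cutoff = as.numeric(names(x$accuracy)),
                   accuracy = round(unname(x$accuracy), 4))
  print(df, row.names = FALSE)
  cat(sprintf("best cut-off: %g (accuracy %.4f)\n",
              x$best_cutoff, x$best_accuracy))
  invisible(x)
}

#' Accuracy and confusion matrix of class predictions
#'
#' @param predicted predicted class labels.
#' @param truth true class labels, aligned with `predicted`.
#' @return A list with `accuracy` (fraction correct) and `confusion`
#'   (contingency table, rows = truth, columns = predicted).
#' @export
evaluate_predictions <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have the same length")
  lev <- union(unique(as.character(truth)), unique(as.character(predicted)))
  predicted <- factor(as.character(predicted), levels = lev)
  truth <- factor(as.character(truth), levels = lev)
  list(accuracy = mean(predicted == truth),
       confusion = table(truth = truth, predicted = predicted))
}
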