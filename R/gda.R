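#' Gaussian discriminant model (LDA / QDA)
#'
#' Fits class-conditional Gaussian densities `p(x|c)` and class priors
#' `p(c)` by maximum likelihood on a probes-by-samples expression matrix.
#' `method = "lda"` pools a single covariance across classes (linear
#' discriminant analysis); `method = "qda"` estimates one covariance per
#' class (quadratic discriminant analysis). Prediction applies Bayes'
#' theorem, `p(c|x) = p(x|c) p(c) / p(x)` with
#' `p(x) = sum_c p(x|c) p(c)`, computed throughout in log space so that
#' hundreds of features do not underflow. The marginal density also yields
#' the outlier score `OS = -log p(x)` (see [outlier_score()]).
#'
#' With expression data the feature count routinely exceeds class sizes, so
#' the default covariance is diagonal: probe-wise variances, pooled across
#' classes for LDA, per class for QDA, floored at `eps`. `cov_mode = "full"`
#' estimates full covariances shrunk toward a scaled identity,
#' `(1 - lambda) S + lambda * mean(diag(S)) I`, which keeps them invertible.
#'
#' @param x numeric matrix, probes x samples, log2 scale.
#' @param classes per-sample class labels (length `ncol(x)`); every class
#'   needs at least 2 samples.
#' @param method `"lda"` (shared covariance) or `"qda"` (per-class).
#' @param cov_mode `"diagonal"` (default) or `"full"` (shrunk).
#' @param lambda shrinkage intensity in \[0, 1\] for `cov_mode = "full"`.
#' @param eps variance floor (> 0) applied to diagonal entries.
#' @param priors optional named numeric vector of class priors; defaults to
#'   the observed class frequencies (maximum likelihood).
#'
#' @return An object of class `"gda"`: a list with elements `means`
#'   (probes x classes), `priors`, `method`, `cov_mode`, `var` (probe-wise
#'   variances; vector for LDA, probes x classes matrix for QDA), `cov`
#'   (list of Cholesky factors when `cov_mode = "full"`), `n_per_class`,
#'   `probe_ids`, `class_levels`.
#' @seealso [predict.gda()], [posterior()], [outlier_score()],
#'   [loocv_grid_search()]
#' @examples
#' cfg <- cohort_config(n_classes = 3, n_probes = 60, n_primary_per_class = 8,
#'                      n_metastasis_per_class = 8, n_cup = 0, n_normal = 0,
#'                      probes_per_class_signature = 10,
#'                      instability_signature_size = 5, seed = 2)
#' coh <- simulate_cohort(cfg)
#' fit <- gda(coh$expr, coh$samples$class_label)
#' fit
#' head(predict(fit, coh$expr)$class)
#' @export
gda <- function(x, classes,
                method = c("lda", "qda"),
                cov_mode = c("diagonal", "full"),
                lambda = 0.1, eps = 1e-6, priors = NULL) {
  .assert_matrix(x, "expression matrix")
  method <- match.arg(method)
  cov_mode <- match.arg(cov_mode)
  if (length(classes) != ncol(x))
    stop("'classes' must have one label per sample (column)")
  if (anyNA(classes)) stop("'classes' contains missing labels")
  if (!is.numeric(eps) || eps <= 0) stop("'eps' must be > 0")
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("'lambda' must be in [0, 1]")

  classes <- factor(classes)
  lev <- levels(classes)
  K <- length(lev)
  if (K < 2L) stop("need at least 2 classes")
  n_k <- table(classes)
  small <- names(n_k)[n_k < 2L]
  if (length(small))
    stop("class(es) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  n <- ncol(x)
  p <- nrow(x)

  means <- matrix(0, p, K, dimnames = list(rownames(x), lev))
  for (k in seq_len(K))
    means[, k] <- rowMeans(x[, classes == lev[k], drop = FALSE])

  if (is.null(priors)) {
    priors <- as.numeric(n_k) / n
    names(priors) <- lev
  } else {
    if (is.null(names(priors)) || !setequal(names(priors), lev))
      stop("'priors' must be named with the class labels")
    priors <- priors[lev]
    if (any(priors < 0) || sum(priors) <= 0) stop("invalid 'priors'")
    priors <- priors / sum(priors)
  }

  obj <- list(method = method, cov_mode = cov_mode, lambda = lambda,
              eps = eps, means = means, priors = priors,
              n_per_class = as.integer(n_k), probe_ids = rownames(x),
              class_levels = lev)
  names(obj$n_per_class) <- lev

  if (cov_mode == "diagonal") {
    # maximum-likelihood variances (denominator n_c), floored at eps
    vk <- matrix(0, p, K, dimnames = list(rownames(x), lev))
    for (k in seq_len(K)) {
      xc <- x[, classes == lev[k], drop = FALSE] - means[, k]
      vk[, k] <- rowMeans(xc^2)
    }
    if (method == "lda") {
      v <- as.vector(vk %*% (as.numeric(n_k) / n))
      obj$var <- pmax(v, eps)
    } else {
      obj$var <- pmax(vk, eps)
    }
  } else {
    shrink <- function(S) {
      St <- (1 - lambda) * S + lambda * mean(diag(S)) * diag(p)
      d <- diag(St)
      diag(St) <- pmax(d, eps)
      St
    }
    Sk <- vector("list", K)
    for (k in seq_len(K)) {
      xc <- x[, classes == lev[k], drop = FALSE] - means[, k]
      Sk[[k]] <- tcrossprod(xc) / as.integer(n_k[k])
    }
    if (method == "lda") {
      S <- Reduce(`+`, Map(function(S, w) S * w, Sk, as.numeric(n_k)/n))
      obj$cov <- list(shared = chol(shrink(S)))
    } else {
      obj$cov <- lapply(Sk, function(S) chol(shrink(S)))
      names(obj$cov) <- lev
    }
  }
  class(obj) <- "gda"
  obj
}

# Per-class Gaussian log-densities for newdata: K x S matrix.
.gda_loglik <- function(object, x) {
  p <- length(object$probe_ids)
  lev <- object$class_levels
  K <- length(lev)
  ll <- matrix(0, K, ncol(x), dimnames = list(lev, colnames(x)))
  cst <- -0.5 * p * log(2 * pi)
  if (object$cov_mode == "diagonal") {
    for (k in seq_len(K)) {
      v <- if (object$method == "lda") object$var else object$var[, k]
      d <- x - object$means[, k]
      ll[k, ] <- cst - 0.5 * sum(log(v)) - 0.5 * colSums(d^2 / v)
    }
  } else {
    for (k in seq_len(K)) {
      R <- if (object$method == "lda") object$cov$shared else object$cov[[k]]
      d <- x - object$means[, k]
      z <- backsolve(R, d, transpose = TRUE)
      ll[k, ] <- cst - sum(log(diag(R))) - 0.5 * colSums(z^2)
    }
  }
  ll
}

.coerce_newdata <- function(object, newdata) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, ncol = 1L,
                      dimnames = list(names(newdata), "x"))
  }
  if (nrow(newdata) != length(object$probe_ids))
    stop("'newdata' has ", nrow(newdata), " probes; model expects ",
         length(object$probe_ids))
  if (!is.null(rownames(newdata)) &&
      !identical(rownames(newdata), object$probe_ids)) {
    if (!all(object$probe_ids %in% rownames(newdata)))
      stop("'newdata' probe names do not match the model's probes")
    newdata <- newdata[object$probe_ids, , drop = FALSE]
  }
  if (anyNA(newdata) || any(!is.finite(newdata)))
    stop("'newdata' contains non-finite values")
  newdata
}

# Core posterior computation with per-sample prior vectors (K x S matrix of
# priors, columns summing to 1). Returns posterior (S x K), log_px (S).
.gda_posterior <- function(object, x, prior_mat) {
  ll <- .gda_loglik(object, x)
  lj <- ll + log(prior_mat)  # K x S; log joint
  log_px <- apply(lj, 2L, .logsumexp)
  post <- t(exp(sweep(lj, 2L, log_px, `-`)))
  list(posterior = post, log_px = log_px)
}

#' Bayes posterior class probabilities
#'
#' Evaluates `p(c|x)` for each column of `newdata` under a fitted [gda()]
#' model with the model's priors, and exposes the log marginal density
#' `log p(x)` alongside.
#'
#' @param object a `"gda"` model.
#' @param newdata numeric matrix (probes x samples) or a single expression
#'   vector; probe names, when present, must match the model's probes.
#' @return A list with `posterior` (samples x classes matrix, rows summing
#'   to 1) and `log_px` (per-sample log marginal density).
#' @export
posterior <- function(object, newdata) {
  if (!inherits(object, "gda")) stop("'object' must be a gda model")
  x <- .coerce_newdata(object, newdata)
  K <- length(object$class_levels)
  pm <- matrix(object$priors, K, ncol(x))
  .gda_posterior(object, x, pm)
}

#' Predict tissue of origin from a Gaussian discriminant model
#'
#' Computes Bayes posteriors and the maximum-a-posteriori class. When a
#' sample's sex and a map of sex-specific classes are supplied, the priors of
#' classes impossible for that sex (e.g. prostate in a female patient) are
#' set to zero and the remaining priors renormalized before applying Bayes'
#' theorem; samples of unknown sex are left unmasked.
#'
#' @param object a `"gda"` model.
#' @param newdata probes x samples matrix or a single expression vector.
#' @param sex optional per-sample sex, `"M"`, `"F"` or `"unknown"`; recycled
#'   if length 1.
#' @param sex_map named character vector mapping class labels to the only
#'   sex in which they occur, e.g. `c(ovary = "F", cervix = "F",
#'   prostate = "M")`.
#' @param ... unused.
#' @return A list of class `"gda_prediction"`: `sample_id`, `class`
#'   (factor of predicted classes), `posterior` (samples x classes),
#'   `log_px`, `outlier_score` (`-log p(x)`), `masked` (logical; whether sex
#'   masking changed the prior). Posterior ties are broken toward the
#'   earlier class level with a message.
#' @export
predict.gda <- function(object, newdata, sex = NULL, sex_map = NULL, ...) {
  x <- .coerce_newdata(object, newdata)
  lev <- object$class_levels
  K <- length(lev)
  S <- ncol(x)
  pm <- matrix(object$priors, K, S, dimnames = list(lev, colnames(x)))
  masked <- rep(FALSE, S)
  if (!is.null(sex) && !is.null(sex_map) && length(sex_map)) {
    if (is.null(names(sex_map)))
      stop("'sex_map' must be a named vector (class -> sex)")
    unknown_cls <- setdiff(names(sex_map), lev)
    sex_map <- sex_map[names(sex_map) %in% lev]
    sex <- rep_len(as.character(sex), S)
    for (j in seq_len(S)) {
      if (is.na(sex[j]) || !sex[j] %in% c("M", "F")) next
      disallow <- names(sex_map)[sex_map != sex[j]]
      if (!length(disallow)) next
      pm[disallow, j] <- 0
      tot <- sum(pm[, j])
      if (tot <= 0)
        stop("sex masking removed every class for sample ",
             colnames(x)[j] %||% j)
      pm[, j] <- pm[, j] / tot
      masked[j] <- TRUE
    }
  }
  res <- .gda_posterior(object, x, pm)
  pred <- .argmax_classes(res$posterior, lev)
  structure(list(sample_id = colnames(x), class = pred,
                 posterior = res$posterior, log_px = res$log_px,
                 outlier_score = -res$log_px, masked = masked),
            class = "gda_prediction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise argmax with first-level tie-break; messages once when ties occur.
.argmax_classes <- function(post, lev) {
  idx <- max.col(post, ties.method = "first")
  n_ties <- sum(rowSums(post == post[cbind(seq_len(nrow(post)), idx)]) > 1L)
  if (n_ties > 0L)
    message(n_ties, " posterior tie(s) broken toward the earlier class level")
  factor(lev[idx], levels = lev)
}

#' Density-based outlier score
#'
#' `OS = -log p(x)` (natural log), where `p(x) = sum_c p(x|c) p(c)` is the
#' marginal density of the sample under the fitted class mixture. A high OS
#' means the expression profile is unlike every training class; for CUP
#' samples it quantifies how far the tumour has diverged from the predefined
#' tumour classes.
#'
#' @param object a `"gda"` model (typically `method = "qda"`).
#' @param newdata probes x samples matrix or single vector.
#' @return Named numeric vector of outlier scores.
#' @export
outlier_score <- function(object, newdata) {
  -posterior(object, newdata)$log_px
}

#' @export
print.gda <- function(x, ...) {
  cat(sprintf("Gaussian discriminant model (%s, %s covariance)\n",
              toupper(x$method), x$cov_mode))
  cat(sprintf("  %d probes, %d classes: %s\n", length(x$probe_ids),
              length(x$class_levels),
              paste(x$class_levels, collapse = ", ")))
  cat("  class sizes:",
      paste(sprintf("%s=%d", x$class_levels, x$n_per_class), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.gda <- function(object, ...) {
  out <- list(method = object$method, cov_mode = object$cov_mode,
              n_probes = length(object$probe_ids),
              classes = object$class_levels,
              n_per_class = object$n_per_class,
              priors = object$priors)
  class(out) <- "summary.gda"
  out
}

#' @export
print.summary.gda <- function(x, ...) {
  cat(sprintf("Gaussian discriminant model (%s, %s covariance)\n",
              toupper(x$method), x$cov_mode))
  cat(sprintf("  probes: %d\n", x$n_probes))
  df <- data.frame(class = x$classes, n = as.integer(x$n_per_class),
                   prior = round(unname(x$priors), 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gda <- function(object, ...) object$means

#' Simulate expression profiles from a fitted discriminant model
#'
#' Draws samples from the fitted Gaussian mixture: a class from the priors,
#' then an expression vector from that class's Gaussian. Only supported for
#' diagonal covariance models.
#'
#' @param object a `"gda"` model with `cov_mode = "diagonal"`.
#' @param nsim number of samples.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A list with `x` (probes x nsim matrix) and `class` (factor).
#' @export
simulate.gda <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$cov_mode != "diagonal")
    stop("simulate() is only implemented for diagonal covariance models")
  with_seed(seed, {
    lev <- object$class_levels
    k <- sample(length(lev), nsim, replace = TRUE, prob = object$priors)
    p <- length(object$probe_ids)
    out <- matrix(0, p, nsim,
                  dimnames = list(object$probe_ids,
                                  sprintf("sim%04d", seq_len(nsim))))
    for (j in seq_len(nsim)) {
      v <- if (object$method == "lda") object$var else object$var[, k[j]]
      out[, j] <- stats::rnorm(p, object$means[, k[j]], sqrt(v))
    }
    list(x = out, class = factor(lev[k], levels = lev))
  })
}
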