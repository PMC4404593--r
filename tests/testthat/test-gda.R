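test_that("per-probe F statistics match an explicit sum-of-squares decomposition", {
  set.seed(5)
  x <- named_matrix(rnorm(20 * 12, 7), 20, 12)
  cls <- rep(c("a", "b", "c"), each = 4)
  fs <- f_statistics(x, cls)
  for (i in c(1, 7, 20)) {
    orc <- oracle_f_oneway(x[i, ], cls)
    expect_equal(fs$f[i], orc$f, tolerance = 1e-10)
    expect_equal(fs$p[i], orc$p, tolerance = 1e-10)
  }
  # and against R's own ANOVA on one probe
  a <- anova(lm(x[3, ] ~ factor(cls)))
  expect_equal(fs$f[3], a$`F value`[1], tolerance = 1e-10)
  # degenerate probes
  x[1, ] <- 5                                   # constant everywhere
  x[2, ] <- rep(c(0, 10, 20), each = 4)         # separated, no within noise
  fs2 <- f_statistics(x, cls)
  expect_equal(fs2$f[1], 0)
  expect_equal(fs2$p[1], 1)
  expect_equal(fs2$p[2], 0)
  x[3, ] <- x[3, ] + 100 * (cls == "b")         # enormous shift, tiny noise
  expect_lt(f_statistics(x, cls)$p[3], 1e-12)
  expect_error(f_statistics(x, c(rep("a", 11), "b")), "b")
})

test_that("maximum-likelihood fit recovers means, priors and pooled variances", {
  # duplicated sample per class: means equal the sample, variances floored
  x1 <- named_matrix(rep(c(1, 2, 3), each = 2), 1, 6)
  x1[1, ] <- rep(c(1, 2, 3), times = 2)
  cls1 <- rep(c("a", "b", "c"), times = 2)
  x1[1, cls1 == "a"] <- 1; x1[1, cls1 == "b"] <- 2; x1[1, cls1 == "c"] <- 3
  fit1 <- gda(x1, cls1, eps = 1e-6)
  expect_equal(unname(fit1$means[1, ]), c(1, 2, 3))
  expect_equal(unname(fit1$var), 1e-6)
  expect_equal(unname(fit1$priors), rep(1 / 3, 3))
  # two-class toy: pooled diagonal variance by the explicit ML formula
  x2 <- named_matrix(c(1, 3, 2, 6, 10, 12), 1, 6)
  cls2 <- rep(c("a", "b"), each = 3)
  fit2 <- gda(x2, cls2)
  va <- mean((x2[1, 1:3] - mean(x2[1, 1:3]))^2)
  vb <- mean((x2[1, 4:6] - mean(x2[1, 4:6]))^2)
  expect_equal(unname(fit2$var), (3 * va + 3 * vb) / 6, tolerance = 1e-12)
  # QDA keeps them separate (ML, divide by n_c)
  fitq <- gda(x2, cls2, method = "qda")
  expect_equal(unname(fitq$var[1, ]), c(va, vb), tolerance = 1e-12)
  # sample order is irrelevant
  perm <- c(4, 1, 6, 3, 2, 5)
  fit2p <- gda(x2[, perm, drop = FALSE], cls2[perm])
  expect_equal(fit2p$means, fit2$means)
  expect_equal(fit2p$var, fit2$var)
  expect_equal(fit2p$priors, fit2$priors)
})

test_that("posteriors equal direct Gaussian density arithmetic", {
  set.seed(6)
  x <- named_matrix(rnorm(5 * 18, 7), 5, 18)
  cls <- rep(c("a", "b", "c"), each = 6)
  x[1:2, cls == "b"] <- x[1:2, cls == "b"] + 2
  for (method in c("lda", "qda")) {
    fit <- gda(x, cls, method = method)
    newx <- named_matrix(rnorm(5 * 4, 7), 5, 4)
    rownames(newx) <- rownames(x)
    po <- posterior(fit, newx)
    for (j in 1:4) {
      orc <- oracle_posterior(newx[, j], fit$means, fit$var, fit$priors)
      expect_equal(unname(po$posterior[j, ]), unname(orc$posterior),
                   tolerance = 1e-12)
      expect_equal(unname(po$log_px[j]), log(orc$px), tolerance = 1e-12)
    }
    expect_true(all(abs(rowSums(po$posterior) - 1) < 1e-9))
  }
})

test_that("posterior symmetries: class mean wins, identical classes tie", {
  x <- named_matrix(c(0, 0, 0.1, -0.1, 5, 5, 5.1, 4.9), 2, 4)
  cls <- c("a", "a", "b", "b")
  fit <- gda(x, cls, eps = 1e-4)
  expect_equal(as.character(predict(fit, fit$means[, "a"])$class), "a")
  expect_equal(as.character(predict(fit, fit$means[, "b"])$class), "b")
  # two identical classes with equal priors -> posterior (0.5, 0.5)
  xi <- named_matrix(c(1, 2, 1, 2, 1, 2, 1, 2), 2, 4)
  xi[, 2] <- c(3, 0); xi[, 4] <- c(3, 0)
  fi <- gda(xi, c("a", "a", "b", "b"))
  po <- suppressMessages(posterior(fi, c(0.3, 0.8)))
  expect_equal(unname(po$posterior[1, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("sex masking renormalizes priors exactly and moves predictions", {
  coh <- small_cohort(seed = 6)
  lab <- coh$samples$class_label != "unknown"
  fit <- gda(coh$expr[, lab], coh$samples$class_label[lab])
  sex_map <- c(C01 = "F", C02 = "M")
  newx <- coh$expr[, which(!lab)[1:4]]
  un <- predict(fit, newx)
  ma <- predict(fit, newx, sex = c("M", "F", "unknown", "M"),
                sex_map = sex_map)
  # unknown sex: untouched
  expect_equal(ma$posterior[3, ], un$posterior[3, ])
  expect_false(ma$masked[3])
  # masked posterior equals conditional renormalization over allowed classes
  for (j in c(1, 2, 4)) {
    disallow <- names(sex_map)[sex_map != c("M", "F", NA, "M")[j]]
    cond <- un$posterior[j, ]
    cond[disallow] <- 0
    cond <- cond / sum(cond)
    expect_equal(ma$posterior[j, ], cond, tolerance = 1e-12)
    expect_true(abs(sum(ma$posterior[j, ]) - 1) < 1e-9)
  }
  # a male sample whose unmasked argmax is a female-only class must move
  xa <- fit$means[, "C01"]
  pm <- predict(fit, xa, sex = "M", sex_map = c(C01 = "F"))
  expect_false(as.character(pm$class) == "C01")
  # masking away every class is an error
  expect_error(predict(fit, xa, sex = "M",
                       sex_map = setNames(rep("F", 4),
                                          fit$class_levels)),
               "every class")
})

test_that("LOOCV grid search matches a naive per-split rerun", {
  set.seed(7)
  n_per <- 5
  x <- named_matrix(rnorm(40 * 15, 7), 40, 15)
  cls <- rep(c("a", "b", "c"), each = n_per)
  x[1:4, cls == "b"] <- x[1:4, cls == "b"] + 1.5
  grid <- c(1e-2, 1e-4)
  res <- suppressMessages(loocv_grid_search(x, cls, grid))
  priors <- setNames(rep(n_per, 3) / 15, c("a", "b", "c"))
  naive <- matrix(NA_character_, 15, 2)
  for (i in 1:15) {
    fs <- f_statistics(x[, -i], cls[-i])
    for (ci in 1:2) {
      sel <- fs$probe_id[fs$p < grid[ci]]
      if (!length(sel)) {
        naive[i, ci] <- names(priors)[which.max(priors)]
      } else {
        m <- gda(x[sel, -i, drop = FALSE], cls[-i], priors = priors)
        naive[i, ci] <- as.character(
          suppressMessages(predict(m, x[sel, i, drop = FALSE]))$class)
      }
    }
  }
  acc_naive <- colMeans(naive == cls)
  expect_equal(unname(res$accuracy[as.character(sort(grid,
                                                     decreasing = TRUE))]),
               acc_naive[order(grid, decreasing = TRUE)])
  # single-value grid returns that value
  res1 <- suppressMessages(loocv_grid_search(x, cls, 1e-3))
  expect_equal(res1$best_cutoff, 1e-3)
  # ties break toward the stricter cut-off
  resall <- suppressMessages(loocv_grid_search(x, cls, c(1e-2, 1e-3)))
  if (diff(range(resall$accuracy)) == 0)
    expect_equal(resall$best_cutoff, 1e-3)
})

test_that("prediction evaluation counts by hand", {
  truth <- c("a", "a", "b", "b", "b", "c", "c", "c", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "c", "c", "c", "a", "c")
  ev <- evaluate_predictions(pred, truth)
  expect_equal(ev$accuracy, 7 / 10)
  expect_equal(unname(ev$confusion["b", "b"]), 2)
  expect_equal(unname(ev$confusion["c", "a"]), 1)
  expect_equal(sum(ev$confusion), 10)
  ev2 <- evaluate_predictions(truth, truth)
  expect_equal(ev2$accuracy, 1)
  expect_true(all(ev2$confusion[upper.tri(ev2$confusion)] == 0))
})

test_that("model methods print, summarize, and simulate from the mixture", {
  coh <- small_cohort(seed = 8)
  lab <- coh$samples$class_label != "unknown"
  fit <- gda(coh$expr[, lab], coh$samples$class_label[lab])
  expect_output(print(fit), "Gaussian discriminant")
  expect_output(print(summary(fit)), "prior")
  expect_identical(coef(fit), fit$means)
  sim <- simulate(fit, nsim = 30, seed = 1)
  expect_equal(dim(sim$x), c(length(fit$probe_ids), 30))
  # simulated samples are classified back to their generating class mostly
  pr <- suppressMessages(predict(fit, sim$x))
  expect_gt(mean(as.character(pr$class) == as.character(sim$class)), 0.5)
  sim2 <- simulate(fit, nsim = 30, seed = 1)
  expect_identical(sim$x, sim2$x)
})
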