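test_that("hypergeometric overlap p matches exhaustive enumeration", {
  # universe of 20, set = first 5 elements, query of 6: enumerate all draws
  uni <- sprintf("g%02d", 1:20)
  gset <- uni[1:5]
  query <- uni[c(1, 2, 3, 6, 7, 8)]            # k = 3 with the set
  ov <- overlap_test(query, list(S = gset), uni)
  expect_equal(ov$k, 3L)
  expect_equal(ov$K, 5L)
  expect_equal(ov$p, oracle_hyper_enum(20, 5, 6, 3), tolerance = 1e-10)
  # several random small instances
  set.seed(16)
  for (rep_i in 1:6) {
    U <- sample(10:20, 1); Ks <- sample(2:6, 1); nq <- sample(3:7, 1)
    uni_i <- sprintf("u%02d", 1:U)
    set_i <- uni_i[1:Ks]
    query_i <- sample(uni_i, nq)
    k <- length(intersect(set_i, query_i))
    ov_i <- overlap_test(query_i, list(S = set_i), uni_i)
    expect_equal(ov_i$p, oracle_hyper_enum(U, Ks, nq, k), tolerance = 1e-10)
  }
})

test_that("overlap test boundary cases behave as certain events", {
  uni <- sprintf("g%02d", 1:12)
  # zero overlap -> P(X >= 0) = 1
  ov0 <- overlap_test(uni[1:3], list(S = uni[10:12]), uni)
  expect_equal(ov0$k, 0L)
  expect_equal(ov0$p, 1)
  # query = set = universe -> k = K and the event is certain
  ov1 <- overlap_test(uni, list(S = uni), uni)
  expect_equal(ov1$k, ov1$K)
  expect_equal(ov1$p, 1)
  expect_equal(ov1$ratio, 1)
  # sets are intersected with the universe before testing
  ov2 <- overlap_test(uni[1:4], list(S = c(uni[1:3], "NOT_THERE")), uni)
  expect_equal(ov2$K, 3L)
  expect_error(overlap_test(c(uni[1], "ALIEN"), list(S = uni[1:3]), uni),
               "subset")
  # BH across sets
  ovm <- overlap_test(uni[1:6], list(A = uni[1:5], B = uni[7:11],
                                     C = uni[2:4]), uni)
  expect_equal(ovm$q, bh_fdr(ovm$p))
})

test_that("enrichment score equals a hand-traced running sum", {
  # 10 genes, set at the very top of the ranking
  stat <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5),
                   sprintf("g%02d", 1:10))
  hits <- sprintf("g%02d", 1:3)
  es <- cuporigin:::.gsea_es(stat, names(stat) %in% hits, weight = 1)
  # manual walk: hit increments |stat|/12 at ranks 1..3, misses -1/7
  expect_equal(es, 12 / 12 - 0 / 7, tolerance = 1e-12)
  expect_gt(es, 0)
  expect_equal(es, oracle_es(stat, hits, 1), tolerance = 1e-12)
  # random instances vs the naive oracle, both weights
  set.seed(17)
  for (rep_i in 1:8) {
    st <- setNames(rnorm(30), sprintf("r%02d", 1:30))
    hs <- sample(names(st), 6)
    for (w in c(0, 1)) {
      expect_equal(cuporigin:::.gsea_es(st, names(st) %in% hs, w),
                   oracle_es(st, hs, w), tolerance = 1e-12)
    }
  }
  # all genes in the set: no misses to balance -> ES defined as 0
  expect_equal(cuporigin:::.gsea_es(stat, rep(TRUE, 10), 1), 0)
})

test_that("unweighted ES is invariant to monotone transforms of the statistic", {
  set.seed(18)
  st <- setNames(rnorm(25), sprintf("m%02d", 1:25))
  hs <- sample(names(st), 5)
  h <- names(st) %in% hs
  es0 <- cuporigin:::.gsea_es(st, h, weight = 0)
  for (f in list(function(z) 2 * z + 3, function(z) z^3,
                 function(z) rank(z))) {
    expect_equal(cuporigin:::.gsea_es(setNames(f(st), names(st)), h, 0),
                 es0, tolerance = 1e-12)
  }
  # weight 1 depends only on the statistic values through |stat| and order:
  # scaling preserves the score's sign and the ranking
  es1 <- cuporigin:::.gsea_es(st, h, weight = 1)
  es1s <- cuporigin:::.gsea_es(st * 2, h, weight = 1)
  expect_equal(sign(es1), sign(es1s))
})

test_that("gsea is seeded, NES carries the ES sign, and a planted set enriches", {
  coh <- simulate_cohort(cohort_config(
    n_classes = 2, n_probes = 300, probes_per_class_signature = 10,
    n_primary_per_class = 2, n_metastasis_per_class = 10, n_cup = 16,
    n_normal = 0, cup_dispersion_factor = 1, instability_effect = 2,
    met_instability_fraction = 0, instability_signature_size = 25,
    seed = 19))
  keep <- coh$samples$group %in% c("CUP", "metastasis")
  grp <- ifelse(coh$samples$group[keep] == "CUP", "CUP", "MOKO")
  sets <- simulate_gene_sets(coh, n_decoys = 1, decoy_size = 20, seed = 1)
  g1 <- gsea(coh$expr[, keep], grp, sets$CIN_SIGNATURE, coh$annotation,
             n_perm = 200, seed = 20)
  g2 <- gsea(coh$expr[, keep], grp, sets$CIN_SIGNATURE, coh$annotation,
             n_perm = 200, seed = 20)
  expect_identical(g1, g2)
  expect_equal(sign(g1$nes), sign(g1$es))
  expect_lt(g1$p, 0.05)                 # planted up-shift is detected
  expect_gt(abs(g1$es), abs(gsea(coh$expr[, keep], grp, sets$DECOY_001,
                                 coh$annotation, n_perm = 50,
                                 seed = 21)$es))
  expect_error(gsea(coh$expr[, keep], grp, c("NOPE1", "NOPE2"),
                    coh$annotation, n_perm = 10, seed = 1), "no overlap")
})

test_that("label-permutation p-values are calibrated on a null cohort", {
  coh <- simulate_cohort(cohort_config(
    n_classes = 2, n_probes = 800, probes_per_class_signature = 5,
    n_primary_per_class = 2, n_metastasis_per_class = 10, n_cup = 20,
    n_normal = 0, class_effect = 0, metastasis_effect = 0,
    cup_dispersion_factor = 1, instability_effect = 0,
    instability_signature_size = 5, seed = 22))
  keep <- coh$samples$group %in% c("CUP", "metastasis")
  grp <- ifelse(coh$samples$group[keep] == "CUP", "CUP", "MOKO")
  decoys <- simulate_gene_sets(coh, n_decoys = 50, decoy_size = 15,
                               seed = 23)
  decoys <- decoys[grep("DECOY", names(decoys))]
  ps <- vapply(seq_along(decoys), function(i)
    gsea(coh$expr[, keep], grp, decoys[[i]], coh$annotation,
         n_perm = 100, seed = 100 + i)$p, numeric(1))
  expect_gte(mean(ps < 0.05), 0.0)
  expect_lte(mean(ps < 0.05), 0.14)
})

test_that("instability score filters by variance, standardizes, and shifts ignore it", {
  set.seed(24)
  x <- named_matrix(rnorm(40 * 12, 7), 40, 12)
  ann <- data.frame(probe_id = rownames(x),
                    gene_symbol = sprintf("G%03d", rep(1:20, each = 2)),
                    stringsAsFactors = FALSE)
  sig <- sprintf("G%03d", 1:10)                 # 20 probes
  # inflate variance of a known half of the signature probes
  x[1:10, ] <- x[1:10, ] * 4
  sc <- instability_score(x, sig, ann, 0.5)
  expect_equal(attr(sc, "n_probes_used"), 10L)
  expect_equal(nrow(sc), 12L)
  # oracle: the ten high-variance probes, standardized, column means
  z <- standardize_probes(x[1:10, ])
  expect_equal(sc$score, unname(colMeans(z)), tolerance = 1e-10)
  # adding a constant to any probe changes nothing (standardization)
  x2 <- x; x2[3, ] <- x2[3, ] + 50
  expect_equal(instability_score(x2, sig, ann, 0.5)$score, sc$score,
               tolerance = 1e-10)
  # identical samples -> all scores 0
  xc <- named_matrix(rep(5, 40 * 12), 40, 12)
  expect_true(all(instability_score(xc, sig, ann, 1)$score == 0))
  expect_error(instability_score(x, "ABSENT", ann), "no signature probes")
})

test_that("outlier-instability correlation behaves on exact and null inputs", {
  ids <- sprintf("s%02d", 1:30)
  ot <- data.frame(sample_id = ids, os = seq(1, 30))
  inst <- data.frame(sample_id = ids, score = seq(2, 60, by = 2))
  cc <- correlate_outlier_instability(ot, inst)
  expect_equal(cc$r, 1, tolerance = 1e-12)
  expect_equal(cc$n, 30L)
  # independent scores: |r| small in most seeds
  set.seed(25)
  rs <- replicate(60, {
    o <- data.frame(sample_id = ids, os = rnorm(30))
    i <- data.frame(sample_id = ids, score = rnorm(30))
    correlate_outlier_instability(o, i)$r
  })
  expect_gt(mean(abs(rs) < 0.4), 0.9)
  expect_error(correlate_outlier_instability(ot[1:2, ], inst), "at least 3")
})
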