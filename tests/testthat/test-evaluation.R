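test_that("validation metrics: perfect scores and perfect separation", {
  set.seed(1)
  resp <- rnorm(30, -0.5, 0.8)
  vm <- validation_metrics(resp, resp)
  expect_equal(vm$mse, 0)
  expect_equal(vm$spearman_r, 1)
  expect_equal(vm$pearson_r, 1)
  # scores that perfectly rank responders give AUC 1
  cls <- classify_volumetric_response(resp, "recist30")
  if (length(unique(cls)) == 2)
    expect_equal(unname(vm$auc["recist30"]), 1)
  # constant scores: correlations missing, AUC 0.5
  vc <- validation_metrics(rep(0.2, 30), resp)
  expect_true(is.na(vc$spearman_r))
  expect_equal(unname(vc$auc["recist30"]), 0.5)
})

test_that("AUC equals the exhaustive pair-count oracle and flips with sign", {
  set.seed(42)
  scores <- round(rnorm(50), 1)                     # ties on purpose
  cls <- runif(50) < 0.4
  expect_equal(auc_rank(scores, cls), oracle_auc_pairs(scores, cls))
  tie_free <- rank(rnorm(50)) / 7
  expect_equal(auc_rank(tie_free, cls) + auc_rank(-tie_free, cls), 1)
})

test_that("point-biserial equals Pearson on the indicator, with t-based p", {
  set.seed(7)
  x <- rnorm(40); g <- rep(c(0, 1), 20)
  pb <- point_biserial(x, g)
  expect_equal(pb$r, cor(x, g), tolerance = 1e-12)
  ct <- cor.test(x, g)
  expect_equal(pb$p, ct$p.value, tolerance = 1e-9)
  # symmetric construction: identical distributions give r = 0
  v <- c(1, 2, 3, 1, 2, 3)
  expect_equal(point_biserial(v, c(0, 0, 0, 1, 1, 1))$r, 0)
  expect_error(point_biserial(x, rep(1, 40)), "non-empty")
})

test_that("Benjamini-Hochberg matches the direct min formula and its properties", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # direct formula: min over j >= i of p_(j) * m / j
  expect_equal(benjamini_hochberg(p), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.3), 0.3)
  set.seed(11)
  q <- runif(40)
  adj <- benjamini_hochberg(q)
  expect_true(all(adj >= q))
  ord <- order(q)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  # BH rejects at least as much as Bonferroni at any alpha
  for (alpha in c(0.01, 0.05, 0.1))
    expect_gte(sum(adj <= alpha), sum(p.adjust(q, "bonferroni") <= alpha))
})

test_that("Mann-Whitney: separation, symmetry, and exact-branch enumeration", {
  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6)
  res <- group_compare(c(g1, g2), rep(c("a", "b"), each = 3))
  expect_true(res$U %in% c(0, 9))                   # complete separation
  swap <- group_compare(c(g2, g1), rep(c("a", "b"), each = 3))
  expect_equal(swap$U, 9 - res$U)
  expect_equal(swap$p, res$p)
  # exact branch equals enumeration of all C(6,3) assignments
  set.seed(3)
  x <- rnorm(3); y <- rnorm(3) + 0.5
  obs <- group_compare(c(x, y), rep(c("a", "b"), each = 3))
  expect_true(obs$exact)
  pool <- c(x, y)
  Us <- apply(combn(6, 3), 2, function(idx) {
    xx <- pool[idx]; yy <- pool[-idx]
    sum(outer(xx, yy, `>`))
  })
  p_enum <- min(1, 2 * min(mean(Us <= obs$U), mean(Us >= obs$U)))
  expect_equal(obs$p, p_enum, tolerance = 1e-12)
  # identical constant samples: no evidence of difference
  expect_equal(group_compare(rep(5, 8), rep(c("a", "b"), 4))$p, 1)
})

test_that("importance report counts selections and normalizes importances", {
  ch <- make_cohort(cohort_spec(90, 8, beta = c(x1 = 1.5), noise_sd = 0.2,
                                seed = 21L))
  m <- fit_ensemble(ch$features, ch$response,
                    pipeline_spec(search_iterations = 4L), base_seed = 0)
  rep_all <- importance_report(m, min_seeds = 0)
  expect_true(all(rep_all$selection_count >= 0 & rep_all$selection_count <= 15))
  expect_equal(rep_all$selection_count[rep_all$feature == "x1"], 15)
  expect_equal(rep_all$feature[1], "x1")            # top-ranked by selection
  # per-member importances are normalized: EN member coefficients sum to 1
  en <- Filter(function(mb) mb$algorithm == "elastic_net", m$members)[[1]]
  co <- abs(as.vector(coef(en$model))[-1])
  if (sum(co) > 0) expect_equal(sum(co / sum(co)), 1)
  # default filter keeps only features selected in >= 3 seeds
  rep3 <- importance_report(m)
  expect_true(all(rep3$n_seeds_selected >= 3))
})
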