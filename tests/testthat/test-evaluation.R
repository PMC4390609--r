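# ROC/AUC: trapezoid-vs-concordance equivalence, tie handling, invariances,
# consensus-vs-individual and tier-direction properties on the seeded
# score benchmark.

test_that("perfect, reversed and tied rankings give 1, 0 and 0.5", {
  r <- roc_curve(c(5, 4, 3, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)
  expect_equal(roc_curve(c(2, 3, 4, 5), c(TRUE, TRUE, FALSE, FALSE))$auc, 0)
  # equal scores, labels [1, 0]: tie counted as half concordance
  expect_equal(roc_curve(c(1, 1), c(TRUE, FALSE))$auc, 0.5)
})

test_that("curves start at (0,0), end at (1,1) and are non-decreasing", {
  set.seed(31)
  for (k in 1:10) {
    sc <- rnorm(30); lab <- runif(30) < 0.4
    if (!any(lab) || all(lab)) next
    r <- roc_curve(sc, lab)
    p <- r$points
    expect_equal(unlist(p[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(p[nrow(p), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(p$fpr) >= 0) && all(diff(p$tpr) >= 0))
  }
})

test_that("trapezoid AUC equals brute-force concordance with ties at 1/2", {
  set.seed(32)
  for (k in 1:60) {
    n <- sample(4:20, 1)
    sc <- sample(1:6, n, replace = TRUE)     # many ties
    lab <- runif(n) < 0.5
    if (!any(lab) || all(lab)) next
    expect_equal(roc_curve(sc, lab)$auc, oracle_auc(sc, lab),
                 label = paste("instance", k))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  sc <- rnorm(200); lab <- runif(200) < plogis(sc)
  want <- as.numeric(pROC::auc(pROC::roc(as.numeric(lab), sc, quiet = TRUE,
                                         direction = "<")))
  expect_equal(roc_curve(sc, lab)$auc, want, tolerance = 1e-12)
})

test_that("AUC is invariant under monotone transforms and flips under
           label reversal", {
  set.seed(34)
  sc <- rnorm(80); lab <- runif(80) < 0.5
  lab[1] <- TRUE; lab[2] <- FALSE
  a <- roc_curve(sc, lab)$auc
  expect_equal(roc_curve(exp(sc / 2), lab)$auc, a)
  expect_equal(roc_curve(sc, !lab)$auc, 1 - a, tolerance = 1e-12)
})

test_that("single-class labels are an error", {
  expect_error(roc_curve(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("an uninformative engine scores AUC ~ 0.5 on the benchmark", {
  bench <- generate_score_benchmark(n = 2000, a = c(flat = 0, good = 1),
                                    seed = 606)
  r <- roc_curve(bench$score_flat, bench$label)
  expect_lt(abs(r$auc - 0.5), 0.05)
  expect_gt(roc_curve(bench$score_good, bench$label)$auc, r$auc)
})

test_that("consensus outperforms each individual engine on the packaged
           benchmark", {
  bench <- generate_score_benchmark(n = 4000, seed = 808)
  engines <- c("seedscan", "dpalign", "duplexfold")
  zs <- lapply(engines, function(e) {
    s <- bench[[paste0("score_", e)]]
    (s - mean(s)) / sqrt(mean((s - mean(s))^2))
  })
  names(zs) <- engines
  # per-engine calibrated weights at each prediction's own score
  ws <- lapply(engines, function(e) {
    sites <- data.frame(engine = e, raw_score = bench[[paste0("score_", e)]],
                        validated = bench$label)
    cv <- calibrate_weights(sites)[[e]]
    lookup_weight(cv, bench[[paste0("score_", e)]])
  })
  cws <- Reduce(`+`, Map(`*`, zs, ws)) / Reduce(`+`, ws)
  aucs <- vapply(zs, function(z) roc_curve(z, bench$label)$auc, numeric(1))
  auc_cws <- roc_curve(cws, bench$label)$auc
  expect_true(all(auc_cws >= aucs))
})

test_that("tier stratification: noiseless positives beat corrupted ones", {
  ev <- evaluate_pipeline(cached_pipeline(11))
  expect_true(all(c("high", "low") %in% names(ev$tiers)))
  expect_gt(ev$tiers$high$auc, ev$tiers$low$auc)
})

test_that("tiers without positives are skipped with a warning", {
  eval_tab <- data.frame(mirna_id = c("hsa-miR-1-3p", "hsa-miR-2-5p"),
                         gene_symbol = c("A", "B"), cws = c(1, -1),
                         validated = c(TRUE, FALSE))
  recs <- data.frame(mirna_id = "hsa-mir-1-3p", gene_symbol = "A",
                     source_db = "oncomirdb", evidence = NA,
                     reliability_tier = "high", stringsAsFactors = FALSE)
  w <- capture_warnings(res <- evaluate_by_tier(eval_tab, recs))
  expect_match(w, "medium", all = FALSE)
  expect_match(w, "low", all = FALSE)
  expect_named(res, "high")
  expect_equal(res$high$auc, 1)
})
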