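# Consensus layer: Z-standardization, precision-above-score calibration
# (weighted PAVA), overlap grouping, and the consensus weighted score.

fake_sites <- function(engine, raw, mirna = "hsa-miR-1-3p", tx = "t1",
                       g_start = NULL, g_end = NULL, type = "8mer",
                       seed_start = NULL, seed_end = NULL) {
  n <- length(raw)
  if (is.null(g_start)) g_start <- seq(100, by = 50, length.out = n)
  if (is.null(g_end)) g_end <- g_start + 7
  if (is.null(seed_start)) seed_start <- g_start - 100
  if (is.null(seed_end)) seed_end <- g_end - 100
  data.frame(engine = engine, mirna_id = mirna, transcript_id = tx,
             utr_start = seed_start, utr_end = seed_end,
             seed_start = seed_start, seed_end = seed_end,
             chrom = "c1", strand = "+", g_start = g_start, g_end = g_end,
             g_blocks = paste0(g_start, "-", g_end),
             site_type = type, raw_score = raw, energy = NA_real_,
             conservation = NA_real_, stringsAsFactors = FALSE)
}

test_that("standardization gives per-engine mean 0 / sd 1 (population sd)", {
  sites <- fake_sites("seedscan", c(1, 2, 3))
  z <- standardize(sites)$z
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-9)
})

test_that("energy-oriented engines map the most negative energy to the
           largest z", {
  sites <- fake_sites("duplexfold", c(-20, -10))   # raw energies here
  z <- standardize(sites, orientation_map = c(duplexfold = "lower"))$z
  expect_equal(z, c(1, -1))
})

test_that("constant scores are a degenerate-input error naming the engine", {
  sites <- fake_sites("seedscan", c(2, 2, 2))
  expect_error(standardize(sites), "seedscan")
})

test_that("hand-computed PAVA calibration example is matched exactly", {
  sites <- fake_sites("e1", c(3, 2, 1))
  sites$validated <- c(TRUE, FALSE, TRUE)
  curves <- calibrate_weights(sites)
  cv <- curves$e1
  # raw W: {3: 1, 2: 1/2, 1: 2/3}; PAVA pools (2/3 * 3 + 1/2 * 2)/5 = 0.6
  expect_equal(cv$score, c(1, 2, 3))
  expect_equal(cv$W, c(0.6, 0.6, 1.0))
  expect_equal(lookup_weight(cv, c(1, 2, 2.5, 3, 99)),
               c(0.6, 0.6, 0.6, 1.0, 1.0))
  # curves are non-decreasing by construction
  expect_true(all(diff(cv$W) >= 0))
})

test_that("all-validated gives W = 1 and none-validated gives W = floor", {
  sites <- fake_sites("e1", c(5, 4, 3, 2))
  sites$validated <- rep(TRUE, 4)
  expect_equal(calibrate_weights(sites)$e1$W, rep(1, 4))
  sites$validated <- rep(FALSE, 4)
  expect_equal(calibrate_weights(sites)$e1$W, rep(1e-6, 4))
})

test_that("weighted PAVA is monotone, weight-aware and idempotent", {
  set.seed(7)
  for (k in 1:20) {
    y <- runif(30); w <- sample(1:5, 30, replace = TRUE)
    fit <- pava_nondecreasing(y, w)
    expect_true(all(diff(fit) >= -1e-12))
    expect_equal(pava_nondecreasing(fit, w), fit, tolerance = 1e-12)
    # weighted mean is preserved
    expect_equal(sum(fit * w), sum(y * w), tolerance = 1e-9)
  }
})

test_that("calibration recovers a known monotone precision curve", {
  bench <- generate_score_benchmark(n = 10000, seed = 909)
  sites <- fake_sites("e1", bench$score_seedscan,
                      g_start = seq(100, by = 50,
                                    length.out = nrow(bench)))
  sites$validated <- bench$label
  cv <- calibrate_weights(sites)$e1
  # independent Monte-Carlo truth at the decile scores of the fit data
  set.seed(1234)
  nmc <- 400000
  qmc <- rnorm(nmc)
  smc <- 1.0 * qmc + rnorm(nmc)
  lmc <- rbinom(nmc, 1, plogis(2 * qmc))
  dec <- quantile(bench$score_seedscan, probs = seq(0.1, 0.9, by = 0.1))
  for (d in dec) {
    truth <- mean(lmc[smc >= d])
    expect_lt(abs(lookup_weight(cv, d) - truth), 0.05)
  }
})

test_that("overlap grouping follows the same-genomic-position rule", {
  a <- fake_sites("seedscan", 10, g_start = 100, g_end = 107,
                  seed_start = 0, seed_end = 7)
  b <- fake_sites("dpalign", 150, g_start = 100, g_end = 107,
                  seed_start = 0, seed_end = 7)
  c2 <- fake_sites("duplexfold", 5, g_start = 105, g_end = 112,
                   seed_start = 5, seed_end = 12)
  other <- fake_sites("seedscan", 8, tx = "t2", g_start = 100, g_end = 107)
  # identical coordinates and type from two engines: exact agreement
  g1 <- group_overlapping(rbind(a, b))
  expect_equal(nrow(g1), 1)
  expect_equal(g1$agreement, 2)
  expect_true(g1$agreement_exact)
  # 2 bp overlap merges but is not exact agreement
  g2 <- group_overlapping(rbind(a, c2))
  expect_equal(nrow(g2), 1)
  expect_equal(g2$agreement, 2)
  expect_false(g2$agreement_exact)
  # same interval on different transcripts stays apart
  g3 <- group_overlapping(rbind(a, other))
  expect_equal(nrow(g3), 2)
})

test_that("grouping is independent of input order", {
  set.seed(11)
  sites <- rbind(
    fake_sites("seedscan", runif(6, 1, 4),
               g_start = c(100, 104, 200, 300, 304, 500)),
    fake_sites("dpalign", runif(6, 140, 180),
               g_start = c(102, 150, 202, 302, 400, 503)))
  g_ref <- group_overlapping(sites)
  key <- function(g) {
    k <- paste(g$mirna_id, g$transcript_id, g$g_start, g$g_end, g$agreement)
    sort(k)
  }
  for (k in 1:5) {
    g_shuf <- group_overlapping(sites[sample(nrow(sites)), ])
    expect_equal(key(g_shuf), key(g_ref))
  }
})

test_that("the consensus weighted score is the printed equation", {
  expect_equal(compute_cws(c(1.0, 2.0), c(0.2, 0.8)), 1.8)
  # single member: CWS reduces to z1 regardless of W1
  expect_equal(compute_cws(3.7, 0.01), 3.7)
  # equal weights: arithmetic mean of z
  z <- c(-1, 0.5, 2)
  expect_equal(compute_cws(z, rep(0.3, 3)), mean(z))
})

test_that("CWS is a convex combination of its members' z-scores", {
  set.seed(21)
  for (k in 1:50) {
    z <- rnorm(sample(1:4, 1))
    W <- runif(length(z), 1e-6, 1)
    cws <- compute_cws(z, W)
    expect_gte(cws, min(z) - 1e-12)
    expect_lte(cws, max(z) + 1e-12)
  }
})

test_that("ranking is by descending CWS with deterministic tie-breaks", {
  groups <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m4"),
    transcript_id = "t", g_start = c(1, 2, 3, 4),
    agreement = c(1, 3, 1, 2),
    cws = c(0.5, 1.8, -0.2, 1.8), stringsAsFactors = FALSE)
  r <- rank_predictions(groups)
  expect_equal(r$cws, c(1.8, 1.8, 0.5, -0.2))
  expect_equal(r$agreement[1:2], c(3, 2))   # agreement breaks the cws tie
  expect_equal(nrow(rank_predictions(groups[0, ])), 0)
})
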