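test_that("Beta frequency draws have the stated mean and spread", {
  # concentration limit pins the draw to its mean
  expect_equal(sampleTargetFrequency(0.5, 1e9, seed = 1), 0.5,
               tolerance = 1e-3)
  # Monte-Carlo mean at beta = 50
  set.seed(12)
  draws <- replicate(10000, sampleTargetFrequency(0.3, 50))
  se <- sqrt(0.3 * 0.7 / 51 / 10000)
  expect_lt(abs(mean(draws) - 0.3), 3 * se)
  # smaller concentration, larger spread
  set.seed(13)
  v10 <- var(replicate(3000, sampleTargetFrequency(0.3, 10)))
  v100 <- var(replicate(3000, sampleTargetFrequency(0.3, 100)))
  expect_gt(v10, v100)
  # degenerate means
  expect_equal(sampleTargetFrequency(0, 10), 0)
  expect_equal(sampleTargetFrequency(1, 10), 1)
})

test_that("simulated datasets respect their stated design", {
  # all-clean dataset
  clean <- simulateDataset("RDD", nSites = 30, nVariant = 0, seed = 2)
  expect_true(all(clean$truth$class == "clean"))

  # RRD: variant sites respect the Delta floor; SNPs are pairwise equal
  sim <- simulateDataset("RRD", nSites = 200, replicates = 2, seed = 4)
  tv <- subset(sim$truth, class == "variant")
  expect_true(all(abs(tv$targetFreqI - tv$targetFreqII) >= 0.1 - 1e-12))
  ts <- subset(sim$truth, class == "snp")
  expect_true(all(ts$targetFreqI == ts$targetFreqII))
  expect_true(all(ts$targetFreqI %in% c(0.5, 1)))

  # RDD: genomic side carries frequency 0 at variant sites; no SNPs
  rdd <- simulateDataset("RDD", nSites = 100, seed = 5)
  expect_true(all(rdd$truth$targetFreqI == 0))
  expect_false(any(rdd$truth$class == "snp"))
  expect_error(simulateDataset("RDD", nSites = 10, nSnp = 2))
  expect_error(simulateDataset("RDD", nSites = 10, nVariant = 11))

  # coverage bounds hold in every replicate
  covs <- unlist(lapply(seq_len(length(sim$tally)), function(i) {
    vapply(c(replicateTallies(sim$tally, "I")[[i]],
             replicateTallies(sim$tally, "II")[[i]]),
           function(r) sum(r$counts), numeric(1))
  }))
  expect_true(all(covs >= 5 & covs <= 1000))

  # determinism: identical seeds give identical count tables
  a <- tempfile()
  b <- tempfile()
  writeCountTable(simulateDataset("RRD", nSites = 40, seed = 9)$tally, a)
  writeCountTable(simulateDataset("RRD", nSites = 40, seed = 9)$tally, b)
  expect_identical(readLines(a), readLines(b))
})

test_that("evaluation arithmetic matches the metric definitions", {
  # construct calls with known confusion counts: TP=8 FP=2 TN=88 FN=2
  n <- 100
  pos <- 100L + (seq_len(n) - 1L) * 10L
  truth <- data.frame(contig = "sim1", position = pos - 1L,
                      class = c(rep("variant", 10), rep("clean", 90)))
  calls <- GRanges("sim1", IRanges(pos, pos))
  calls$z <- 0
  calls$filter <- "."
  calls$passed <- c(rep(TRUE, 8), rep(FALSE, 2),
                    rep(TRUE, 2), rep(FALSE, 88))
  rep <- evaluateCalls(calls, truth)
  expect_equal(rep$TPR, 0.8)
  expect_equal(rep$precision, 0.8)
  expect_equal(rep$accuracy, 0.96)
  expect_equal(rep$F, 0.8)

  # zero predicted positives: precision NaN with a warning
  calls$passed <- rep(FALSE, n)
  expect_warning(rep0 <- evaluateCalls(calls, truth), "precision")
  expect_true(is.nan(rep0$precision))

  # perfect caller: everything 1
  calls$passed <- truth$class == "variant"
  rep1 <- evaluateCalls(calls, truth)
  expect_equal(unlist(rep1[c("TPR", "precision", "accuracy", "F")]),
               c(TPR = 1, precision = 1, accuracy = 1, F = 1))

  # site-set mismatch is an error
  bad <- GRanges("sim1", IRanges(99999, 99999))
  bad$z <- 0
  bad$filter <- "."
  bad$passed <- TRUE
  expect_error(evaluateCalls(bad, truth), "missing")
})

test_that("threshold sweep brackets the score range coherently", {
  sim <- simulateDataset("RDD", nSites = 60, replicates = 2, seed = 6)
  calls <- suppressWarnings(
    callSites(sim$tally, panel = FilterPanel(enabled = character(0)))
  )
  sweep <- suppressWarnings(thresholdSweep(calls, sim$truth))
  expect_equal(nrow(sweep), length(unique(calls$z)))
  # lowest threshold scores every site as positive
  lo <- sweep[which.min(sweep$threshold), ]
  expect_equal(lo$TP + lo$FN, sum(sim$truth$class == "variant"))
  expect_equal(lo$TPR, 1)
  # a threshold above max(z) predicts nothing
  above <- suppressWarnings(
    evaluateCalls(calls, sim$truth, threshold = max(calls$z) + 1)
  )
  expect_equal(above$TP + above$FP, 0)
  # sweep row at a default threshold agrees with direct evaluation
  t0 <- sweep$threshold[5]
  direct <- suppressWarnings(evaluateCalls(calls, sim$truth,
                                           threshold = t0))
  expect_equal(sweep[5, c("TP", "FP", "TN", "FN")],
               direct[, c("TP", "FP", "TN", "FN")],
               ignore_attr = TRUE)
})

test_that("fixed-frequency overrides drive controlled effect sizes", {
  sim <- simulateDataset("RRD", nSites = 30, nVariant = 30, nSnp = 0,
                         replicates = 2, variantFreqI = 0.2,
                         variantFreqII = 0.5, seed = 10)
  expect_true(all(sim$truth$targetFreqI == 0.2))
  expect_true(all(sim$truth$targetFreqII == 0.5))
  expect_error(simulateDataset("RDD", nSites = 10, variantFreqI = 0.2,
                               variantFreqII = 0.3, seed = 1))
})
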