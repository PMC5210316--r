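test_that("identical samples score zero and swaps are symmetric", {
  set.seed(42)
  for (i in 1:20) {
    X <- sampleDirMult(exp(runif(4, log(0.5), log(10))),
                       n = sample(10:200, 1), N = sample(1:3, 1))
    D <- makeSample(X)
    expect_lt(abs(zScore(D, D)$z), 1e-4)
  }
  X1 <- sampleDirMult(c(5, 1, 1, 1), 80, 2, seed = 1)
  X2 <- sampleDirMult(c(2, 4, 1, 1), 80, 3, seed = 2)
  D1 <- makeSample(X1)
  D2 <- makeSample(X2)
  expect_equal(zScore(D1, D2)$z, zScore(D2, D1)$z, tolerance = 1e-9)
})

test_that("z is invariant under replicate permutation and non-negative", {
  set.seed(43)
  X1 <- sampleDirMult(c(5, 2, 1, 1), 60, 4)
  X2 <- sampleDirMult(c(1, 5, 1, 1), 60, 4)
  D1 <- makeSample(X1)
  D2 <- makeSample(X2)
  z <- zScore(D1, D2)$z
  expect_equal(zScore(D1[c(3, 1, 4, 2)], D2[c(2, 4, 1, 3)])$z, z,
               tolerance = 1e-9)
  for (i in 1:50) {
    A <- makeSample(sampleDirMult(exp(runif(4, log(0.3), log(20))),
                                  sample(5:150, 1), sample(1:3, 1)))
    B <- makeSample(sampleDirMult(exp(runif(4, log(0.3), log(20))),
                                  sample(5:150, 1), sample(1:3, 1)))
    expect_gte(zScore(A, B)$z, -1e-4)
  }
})

test_that("stronger sample separation yields a larger z", {
  # half-and-half vs nearly-pure: the former diverges far more from a
  # pure-A partner (ordering cross-checked with the grid-search oracle)
  DI <- makeSample(rbind(c(30, 0, 0, 0), c(28, 0, 0, 0)))
  DIIa <- makeSample(rbind(c(15, 15, 0, 0), c(14, 16, 0, 0)))
  DIIb <- makeSample(rbind(c(29, 1, 0, 0), c(28, 2, 0, 0)))
  za <- zScore(DI, DIIa)$z
  zb <- zScore(DI, DIIb)$z
  expect_gt(za, zb)

  # grid oracle agrees on the ordering of the likelihood-ratio scores
  gridZ <- function(A, B) {
    XA <- rddiff:::.adjustedMatrix(A)
    XB <- rddiff:::.adjustedMatrix(B)
    gv <- c(0.25, 1, 4, 16, 64, 256)
    gridFitOracle(XA, gv) + gridFitOracle(XB, gv) -
      gridFitOracle(rbind(XA, XB), gv)
  }
  expect_gt(gridZ(DI, DIIa), gridZ(DI, DIIb))
})

test_that("median z grows with the frequency difference", {
  set.seed(44)
  meds <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(delta) {
    zs <- vapply(1:30, function(i) {
      f1 <- 0.25
      f2 <- f1 + delta
      X1 <- t(replicate(3, as.integer(rmultinom(1, 150,
        c(1 - f1, f1, 0, 0) + 1e-4))))
      X2 <- t(replicate(3, as.integer(rmultinom(1, 150,
        c(1 - f2, f2, 0, 0) + 1e-4))))
      zScore(makeSample(X1), makeSample(X2))$z
    }, numeric(1))
    median(zs)
  }, numeric(1))
  expect_true(all(diff(meds) >= -1e-9))
})

test_that("coverage balancing follows the mono-allelic deep-stack rule", {
  gdna <- list(makeRec(c(500, 0, 0, 0)))
  cdna <- list(makeRec(c(20, 10, 0, 0)))
  out <- balanceCoverage(gdna, cdna, refBase = "A", triggerRatio = 2)
  expect_true(out$balanced)
  # gDNA replaced by a copy of the cDNA stack with variants -> reference
  expect_equal(length(out$recsI), 1L)
  expect_equal(unname(out$recsI[[1]]$counts), c(30, 0, 0, 0))
  expect_equal(length(out$recsI[[1]]$quals$A), 30L) # qualities retained
  expect_equal(unname(out$recsII[[1]]$counts), c(20, 10, 0, 0))

  # replicate-count asymmetry: balanced side inherits the hetero side's N
  cdna2 <- list(makeRec(c(20, 10, 0, 0)), makeRec(c(25, 5, 0, 0)))
  out2 <- balanceCoverage(gdna, cdna2, refBase = "A", triggerRatio = 2)
  expect_true(out2$balanced)
  expect_equal(length(out2$recsI), 2L)

  # both sides poly-allelic: untouched
  out3 <- balanceCoverage(list(makeRec(c(400, 100, 0, 0))), cdna, "A", 2)
  expect_false(out3$balanced)
  expect_equal(out3$recsI[[1]]$counts[["A"]], 400L)

  # ratio below trigger: untouched
  out4 <- balanceCoverage(list(makeRec(c(45, 0, 0, 0))), cdna, "A", 2)
  expect_false(out4$balanced)
})

test_that("site calling applies thresholds, filters and skip rules", {
  # mode-scoped default thresholds: same z passes RDD (1.15), fails RRD (1.56)
  mkTally <- function(mode) {
    sites <- GRanges("chr1", IRanges(101, 101), strand = "*", ref = "A")
    tallyI <- list(list(makeRec(c(30, 0, 0, 0)), makeRec(c(28, 0, 0, 0))))
    tallyII <- list(list(makeRec(c(22, 8, 0, 0)), makeRec(c(24, 6, 0, 0))))
    SiteTallySet(sites, tallyI, tallyII, mode = mode, hasContext = FALSE)
  }
  panel <- FilterPanel(enabled = character(0))
  rdd <- callSites(mkTally("RDD"), panel = panel)
  rrd <- callSites(mkTally("RRD"), panel = panel)
  expect_equal(rdd$z, rrd$z, tolerance = 1e-6)
  z <- rdd$z
  expect_true(z > 1.56) # fixture chosen to clear both defaults
  expect_true(rdd$passed && rrd$passed)
  # a threshold above z fails the site regardless of mode
  expect_false(callSites(mkTally("RDD"), threshold = z + 1,
                         panel = panel)$passed)

  # filter flags veto a passing score
  rddM <- callSites(mkTally("RDD"), panel = FilterPanel(enabled = "H"))
  # gDNA is deep and homozygous -> H must NOT fire here
  expect_equal(rddM$filter, ".")
  shallow <- SiteTallySet(
    GRanges("chr1", IRanges(101, 101), strand = "*", ref = "A"),
    list(list(makeRec(c(4, 0, 0, 0)))),
    list(list(makeRec(c(22, 8, 0, 0)))),
    mode = "RDD", hasContext = FALSE
  )
  flagged <- callSites(shallow, panel = FilterPanel(enabled = "H"))
  expect_equal(flagged$filter, "H")
  expect_false(flagged$passed)

  # zero-coverage replicate: site skipped with a message
  empty <- SiteTallySet(
    GRanges("chr1", IRanges(c(101, 111), c(101, 111)), strand = "*",
            ref = c("A", "A")),
    list(list(makeRec(c(10, 0, 0, 0))), list(makeRec(c(0, 0, 0, 0)))),
    list(list(makeRec(c(5, 5, 0, 0))), list(makeRec(c(5, 5, 0, 0)))),
    mode = "RDD", hasContext = FALSE
  )
  expect_message(res <- callSites(empty, panel = panel), "skipped")
  expect_equal(length(res), 1L)
})
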