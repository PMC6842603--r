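# fixture: cluster sizes and per-cluster mislabel structure are chosen
# directly; label "bad" marks the planted mislabels at the audited rank
makeSamplingTruth <- function(nLarge = 10, sizeLarge = 100, largeErr = 0,
                              nSmall = 200, sizeSmall = 5, smallErr = 0.1,
                              seed = 1) {
  set.seed(seed)
  rows <- list()
  cid <- 0
  addCluster <- function(size, nBad) {
    cid <<- cid + 1
    lab <- rep("good", size)
    if (nBad > 0) lab[seq_len(nBad)] <- "bad"
    rows[[length(rows) + 1]] <<- data.frame(
      accession = sprintf("C%04dS%04d", cid, seq_len(size)),
      cluster = cid, label = lab,
      isMislabeled = lab == "bad", stringsAsFactors = FALSE)
  }
  for (i in seq_len(nLarge)) addCluster(sizeLarge,
                                        rbinom(1, sizeLarge, largeErr))
  for (i in seq_len(nSmall)) addCluster(sizeSmall,
                                        rbinom(1, sizeSmall, smallErr))
  do.call(rbind, rows)
}

test_that("auditing every cluster recovers the planted rate exactly", {
  truth <- makeSamplingTruth(nLarge = 3, nSmall = 20, seed = 5)
  nc <- length(unique(truth$cluster))
  for (strat in c("random-sequence", "random-cluster")) {
    r <- simulateStrategy(truth, strat, effort = nc, replicates = 2,
                          seed = 10)
    expect_equal(r$estimate, rep(100 * mean(truth$isMislabeled), 2))
  }
  r <- simulateStrategy(truth, "large-cluster-exhaustive", effort = 1,
                        replicates = 1, seed = 10, largeMin = 1)
  expect_equal(r$estimate, 100 * mean(truth$isMislabeled))
})

test_that("fixed seeds give byte-identical strategy results", {
  truth <- makeSamplingTruth(seed = 6)
  a <- simulateStrategy(truth, "random-sequence", effort = 20,
                        replicates = 5, seed = 77)
  b <- simulateStrategy(truth, "random-sequence", effort = 20,
                        replicates = 5, seed = 77)
  expect_identical(a, b)
})

test_that("excess effort is capped with a warning", {
  truth <- makeSamplingTruth(nLarge = 1, nSmall = 3, seed = 7)
  expect_warning(r <- simulateStrategy(truth, "random-cluster",
                                       effort = 100, replicates = 1,
                                       seed = 1), "capped")
  expect_equal(r$effort, 4)
})

test_that("single-sequence draws audit clusters in proportion to size", {
  # with effort 1 the audited-cluster law is exactly s/N
  truth <- makeSamplingTruth(nLarge = 2, sizeLarge = 50, nSmall = 20,
                             sizeSmall = 5, seed = 8)
  N <- nrow(truth)
  hits <- integer(0)
  r <- simulateStrategy(truth, "random-sequence", effort = 1,
                        replicates = 400, seed = 30)
  # recover which cluster was audited from the estimate: a large cluster
  # audit looks at 50 sequences; instead track via estimates vs sizes is
  # ambiguous, so check the size-biased law on the estimate's mean:
  # E[estimate] = sum_c (s_c/N) * rate_c
  rate_c <- tapply(truth$isMislabeled, truth$cluster, mean)
  s_c <- tapply(truth$isMislabeled, truth$cluster, length)
  expected <- 100 * sum((s_c / N) * rate_c)
  expect_lt(abs(mean(r$estimate) - expected), 3)
})

test_that("sequence sampling underestimates when errors sit in small clusters", {
  truth <- makeSamplingTruth(nLarge = 10, sizeLarge = 100, largeErr = 0,
                             nSmall = 200, sizeSmall = 5, smallErr = 0.1,
                             seed = 9)
  rs <- simulateStrategy(truth, "random-sequence", effort = 50,
                         replicates = 500, seed = 100)
  rc <- simulateStrategy(truth, "random-cluster", effort = 50,
                         replicates = 500, seed = 100)
  cmp <- compareStrategies(rbind(rs, rc))
  bSeq <- cmp[cmp$strategy == "random-sequence", ]
  bClu <- cmp[cmp$strategy == "random-cluster", ]
  expect_lt(bSeq$meanBias, 0)
  expect_lt(abs(bClu$meanBias), 3 * bClu$seBias)
})

test_that("the exhaustive large-cluster strategy brackets the truth", {
  truth <- makeSamplingTruth(nLarge = 5, sizeLarge = 120, largeErr = 0.02,
                             nSmall = 100, sizeSmall = 6, smallErr = 0.05,
                             seed = 11)
  r <- simulateStrategy(truth, "large-cluster-exhaustive", effort = 1,
                        replicates = 1, seed = 2, largeMin = 100)
  truthRate <- 100 * mean(truth$isMislabeled)
  expect_lte(r$estMin, truthRate + 1e-9)
  expect_gte(r$estMax, truthRate - 1e-9)
  cmp <- compareStrategies(rbind(
    r, simulateStrategy(truth, "random-cluster", effort = 30,
                        replicates = 20, seed = 3)))
  expect_equal(cmp$coverage[cmp$strategy == "large-cluster-exhaustive"], 1)
})

test_that("a single replicate has RMSE equal to absolute bias", {
  truth <- makeSamplingTruth(nLarge = 2, nSmall = 10, seed = 12)
  a <- simulateStrategy(truth, "random-cluster", effort = 3,
                        replicates = 1, seed = 5)
  b <- simulateStrategy(truth, "random-sequence", effort = 3,
                        replicates = 1, seed = 5)
  cmp <- compareStrategies(rbind(a, b))
  expect_equal(cmp$rmse, abs(cmp$meanBias))
  expect_error(compareStrategies(a), "two strategies")
})

test_that("samplingTruth joins clusters with the truth table", {
  db <- simulateDatabase(smallSpec(), seed = 700)
  cs <- greedyCluster(dbSeqs(db), 0.97, gene = "CO1")
  st <- samplingTruth(db, cs)
  expect_equal(nrow(st), length(dbSeqs(db)))
  expect_equal(sum(st$isMislabeled), sum(dbTruth(db)$isMislabeled))
  expect_true(all(c("accession", "cluster", "label", "isMislabeled")
                  %in% names(st)))
})
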