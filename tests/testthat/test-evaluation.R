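test_that("balanced accuracy is the mean of per-class recalls", {
  expect_equal(balancedAccuracy(c("a", "b", "a"), c("a", "b", "a")), 1)
  # always-majority predictor on binary data: one recall 1, the other 0
  truth <- c(rep("idle", 8), rep("walk", 2))
  expect_equal(balancedAccuracy(truth, rep("idle", 10)), 0.5)
  # confusion counts [[8,2],[4,6]] -> (8/10 + 6/10) / 2 = 0.7
  truth <- c(rep("a", 10), rep("b", 10))
  pred <- c(rep("a", 8), rep("b", 2), rep("a", 4), rep("b", 6))
  expect_equal(balancedAccuracy(truth, pred), 0.7)
  expect_error(balancedAccuracy(character(), character()), "empty")
})

test_that("balanced accuracy invariances hold", {
  set.seed(31)
  truth <- sample(letters[1:3], 60, replace = TRUE)
  pred <- sample(letters[1:3], 60, replace = TRUE)
  relabel <- c(a = "z", b = "x", c = "y")
  expect_equal(balancedAccuracy(relabel[truth], relabel[pred]),
               balancedAccuracy(truth, pred))
  # balanced classes: balanced accuracy equals plain accuracy
  truthBal <- rep(c("a", "b"), each = 30)
  predBal <- sample(c("a", "b"), 60, replace = TRUE)
  expect_equal(balancedAccuracy(truthBal, predBal),
               mean(truthBal == predBal))
})

test_that("F-score matches precision/recall arithmetic and conventions", {
  expect_equal(fScore(c("x", "y"), c("x", "y"), "x"), 1)
  # no predicted positives: 0 by convention
  expect_equal(fScore(c("x", "y"), c("y", "y"), "x"), 0)
  # TP=6, FP=2, FN=4: 2 * (0.75 * 0.6) / (0.75 + 0.6)
  truth <- c(rep("p", 10), rep("n", 10))
  pred <- c(rep("p", 6), rep("n", 4), rep("p", 2), rep("n", 8))
  expect_equal(fScore(truth, pred, "p"), 2 * 0.75 * 0.6 / (0.75 + 0.6),
               tolerance = 1e-12)
  # invariant to the number of true negatives
  truth2 <- c(truth, rep("n", 50))
  pred2 <- c(pred, rep("n", 50))
  expect_equal(fScore(truth2, pred2, "p"), fScore(truth, pred, "p"))
})

test_that("trajectory cosine similarity handles signs and zero targets", {
  tr <- matrix(rnorm(30), 10, 3)
  expect_equal(cosineSimilarity(tr, tr), 1)
  expect_equal(cosineSimilarity(-tr, tr), -1)
  a <- matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE)
  b <- matrix(rep(c(0, 1, 0), 5), ncol = 3, byrow = TRUE)
  expect_equal(cosineSimilarity(a, b), 0)
  # zero-truth windows are skipped
  tru <- rbind(c(0, 0, 0), c(1, 0, 0))
  prd <- rbind(c(5, 5, 5), c(1, 0, 0))
  expect_equal(cosineSimilarity(prd, tru), 1)
  expect_true(is.na(cosineSimilarity(prd, matrix(0, 2, 3))))
})

test_that("model comparison reproduces the Welch t-test", {
  a <- c(0.61, 0.64, 0.66, 0.59, 0.63)
  b <- c(0.52, 0.55, 0.51, 0.56, 0.54)
  # manual Welch formula as the independent check
  sa <- var(a) / length(a); sb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  pManual <- 2 * pt(-abs(tstat), df)
  expect_equal(compareModels(a, b), pManual, tolerance = 1e-12)
  expect_equal(compareModels(a, a), 1)
  # zero within-group variance, different means: p collapses to 0
  expect_equal(compareModels(c(0.6, 0.6), c(0.5, 0.5)), 0)
  expect_error(compareModels(0.5, c(0.4, 0.6)), "at least two")
})

test_that("session evaluation aggregates state, F-score and cosine", {
  ses <- tinySession(minutes = 0.1, task = "sixdof", nChannels = 16L)
  nw <- nWindows(ses)
  steps <- data.frame(window = seq_len(nw),
                      state = stateLabels(ses),
                      lx = trajectoryTargets(ses)[, 1],
                      ly = trajectoryTargets(ses)[, 2],
                      lz = trajectoryTargets(ses)[, 3],
                      rx = trajectoryTargets(ses)[, 4],
                      ry = trajectoryTargets(ses)[, 5],
                      rz = trajectoryTargets(ses)[, 6],
                      satisfaction = satisfactionLabels(ses))
  ev <- evaluateDecoding(steps, ses)
  expect_equal(ev$balancedAccuracy, 1)
  expect_true(all(ev$fscorePerClass[unique(as.character(stateLabels(ses)))]
                  == 1))
  expect_equal(unname(ev$cosinePerHand["left"]), 1)
  expect_equal(ev$nWindows, nw)
})

test_that("whole-trajectory cosine is available as an alternative", {
  tr <- matrix(rnorm(30), 10, 3)
  expect_equal(cosineSimilarity(tr, tr, perWindow = FALSE), 1)
  expect_equal(cosineSimilarity(-tr, tr, perWindow = FALSE), -1)
  p <- as.numeric(tr) + rnorm(30, sd = 0.1)
  manual <- sum(p * as.numeric(tr)) /
    (sqrt(sum(p^2)) * sqrt(sum(as.numeric(tr)^2)))
  expect_equal(cosineSimilarity(matrix(p, 10, 3), tr, perWindow = FALSE),
               manual)
})
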