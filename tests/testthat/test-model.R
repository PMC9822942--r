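# Random-forest scorer: training, determinism, serialization, and
# cross-validated threshold selection.

test_that("a separable toy set is classified perfectly and reproducibly", {
  ex <- toyExamples(nPos = 20, nNeg = 20, seed = 3)
  m <- trainTargetModel(ex, seed = 11L)
  expect_equal(m@nTrees, 13L)
  conf <- predictConfidence(m, ex)
  expect_true(all(conf >= 0 & conf <= 1))
  expect_true(all(conf[ex$label == "positive"] > 0.5))
  expect_true(all(conf[ex$label == "negative"] < 0.5))
  # confidences are vote fractions of a 13-tree forest
  expect_true(all(abs(conf * 13 - round(conf * 13)) < 1e-9))

  m2 <- trainTargetModel(ex, seed = 11L)
  expect_identical(predictConfidence(m2, ex), conf)
  m3 <- trainTargetModel(ex, seed = 12L)
  expect_equal(length(predictConfidence(m3, ex)), nrow(ex))
})

test_that("degenerate and malformed training input is rejected", {
  ex <- toyExamples(10, 10)
  one <- ex[ex$label == "positive", ]
  expect_error(trainTargetModel(one), "degenerate")
  expect_error(trainTargetModel(rbind(ex[1:10, ], ex[11, ])), "degenerate")
  bad <- ex
  bad$seed_match[3] <- NA
  expect_error(trainTargetModel(bad), "incomplete")
})

test_that("prediction validates columns, tolerates order, handles empty input", {
  ex <- toyExamples(10, 10)
  m <- trainTargetModel(ex)
  shuffled <- ex[, rev(colnames(ex))]
  expect_identical(predictConfidence(m, shuffled), predictConfidence(m, ex))
  expect_identical(predictConfidence(m, ex[0, ]), numeric(0))
  expect_error(predictConfidence(m, ex[, -match("seed_match", colnames(ex))]),
               "seed_match")
})

test_that("a saved model round-trips with identical predictions", {
  ex <- toyExamples(15, 15, seed = 9)
  m <- trainTargetModel(ex, seed = 2L)
  path <- withr::local_tempfile(fileext = ".rds")
  saveTargetModel(m, path)
  back <- readTargetModel(path)
  expect_identical(predictConfidence(back, ex), predictConfidence(m, ex))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something-else"), bad)
  expect_error(readTargetModel(bad), "not a phytomir model")
})

test_that("stratified folds balance both classes", {
  pos <- rep(c(TRUE, FALSE), c(25, 40))
  fold <- phytomir:::.stratifiedFolds(pos, 5L, seed = 4L)
  expect_setequal(unique(fold), 1:5)
  posPerFold <- table(fold[pos])
  expect_true(max(posPerFold) - min(posPerFold) <= 1)
  negPerFold <- table(fold[!pos])
  expect_true(max(negPerFold) - min(negPerFold) <= 1)
  expect_identical(fold, phytomir:::.stratifiedFolds(pos, 5L, seed = 4L))
})

test_that("threshold selection returns the smallest precision-clean threshold", {
  # constructed scores: positives >= 0.9, one negative at 0.7, rest <= 0.3
  ex <- toyExamples(nPos = 10, nNeg = 10, seed = 21)
  sf <- function(train, test) ifelse(test$label == "positive", 0.9,
                                     ifelse(seq_len(nrow(test)) == 1, 0.7,
                                            0.3))
  rep <- selectThresholdCv(ex, k = 5L, precisionTarget = 1.0, seed = 1L,
                           scoreFun = sf)
  expect_true(rep@reached)
  expect_equal(rep@threshold, 0.9)
  expect_equal(rep@cvPrecisionMean, 1.0)
  expect_equal(rep@cvRecallMean, 1.0)
})

test_that("threshold selection matches a first-principles oracle", {
  ex <- toyExamples(nPos = 5, nNeg = 5, seed = 33)
  set.seed(77)
  fixed <- round(runif(10), 3)
  sf <- function(train, test) fixed[match(test$mirna_id, ex$mirna_id)]
  rep <- selectThresholdCv(ex, k = 5L, precisionTarget = 0.8, seed = 6L,
                           scoreFun = sf)
  fold <- phytomir:::.stratifiedFolds(ex$label == "positive", 5L, seed = 6L)
  expect_equal(rep@threshold, oracleThreshold(ex, fold, fixed, 0.8))
})

test_that("an unreachable precision target warns and reports reached = FALSE", {
  ex <- toyExamples(nPos = 10, nNeg = 10, seed = 41)
  # negatives always outscore positives: no threshold is precision-clean
  sf <- function(train, test) ifelse(test$label == "positive", 0.2, 0.9)
  expect_warning(rep <- selectThresholdCv(ex, k = 5L, precisionTarget = 1.0,
                                          scoreFun = sf), "not reached")
  expect_false(rep@reached)
  expect_equal(rep@threshold, 0.9)
})

test_that("end-to-end CV on the separable toy set picks a high threshold", {
  ex <- toyExamples(nPos = 25, nNeg = 25, seed = 55)
  rep <- selectThresholdCv(ex, k = 5L, precisionTarget = 1.0, seed = 1L)
  expect_true(rep@reached)
  expect_equal(rep@cvPrecisionMean, 1.0)
  expect_gte(rep@cvRecallMean, 0.9)
  expect_s4_class(rep, "ThresholdReport")
})
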