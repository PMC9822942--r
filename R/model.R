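# The 13-tree random-forest scorer and cross-validated threshold selection.

#' Train the random-forest target scorer
#'
#' Fits a random forest on the 11 duplex features. Only the tree count is
#' pinned (13); all other hyperparameters are the usual forest defaults
#' (unlimited depth, floor(sqrt(11)) = 3 candidate features per split,
#' bootstrap resampling). The RNG seed is set immediately before fitting,
#' so identical data and seed reproduce the forest, and hence every
#' prediction, exactly.
#'
#' @param examples labeled feature data.frame: the 11 features plus a
#'   \code{label} column (\code{"positive"}/\code{"negative"}, logical or
#'   0/1). Both classes must be present with at least 2 examples each.
#' @param nTrees number of trees (default 13).
#' @param seed integer RNG seed (default 1).
#' @return A \linkS4class{TargetModel}.
#' @export
trainTargetModel <- function(examples, nTrees = 13L, seed = 1L) {
  x <- examples[, .FEATURES, drop = FALSE]
  if (anyNA(x)) stop("incomplete feature vectors", call. = FALSE)
  pos <- .asPositive(examples$label)
  if (length(unique(pos)) < 2 || min(table(pos)) < 2)
    stop("degenerate training set: need >= 2 examples per class",
         call. = FALSE)
  y <- factor(ifelse(pos, "positive", "negative"),
              levels = c("negative", "positive"))
  set.seed(as.integer(seed))
  forest <- randomForest::randomForest(x = x, y = y,
                                       ntree = as.integer(nTrees))
  new("TargetModel", forest = forest, featureOrder = .FEATURES,
      nTrees = as.integer(nTrees), seed = as.integer(seed))
}

#' Score examples with a trained model
#'
#' Confidence = fraction of trees voting "positive", in \[0, 1\].
#'
#' @param model A \linkS4class{TargetModel}.
#' @param examples data.frame containing the 11 feature columns (order in
#'   the frame is irrelevant; the model's canonical order is applied).
#' @return Numeric vector of confidences, one per row.
#' @export
predictConfidence <- function(model, examples) {
  miss <- setdiff(model@featureOrder, colnames(examples))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- examples[, model@featureOrder, drop = FALSE]
  if (anyNA(x)) stop("incomplete feature vectors", call. = FALSE)
  if (nrow(x) == 0) return(numeric(0))
  unname(stats::predict(model@forest, newdata = x, type = "vote",
                        norm.votes = TRUE)[, "positive"])
}

#' Save / load a trained model
#'
#' Single-file serialization with a format version tag; loading checks the
#' tag and revalidates the object, and a round trip reproduces predictions
#' exactly.
#'
#' @param model A \linkS4class{TargetModel}.
#' @param path file path.
#' @return \code{saveTargetModel}: \code{path}, invisibly;
#'   \code{readTargetModel}: the model.
#' @export
saveTargetModel <- function(model, path) {
  saveRDS(list(format = "phytomir-model-1", model = model), path)
  invisible(path)
}

#' @rdname saveTargetModel
#' @export
readTargetModel <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "phytomir-model-1"))
    stop("not a phytomir model file: ", path, call. = FALSE)
  methods::validObject(obj$model)
  obj$model
}

# Stratified fold assignment: within each class, folds are dealt by
# shuffling rep(1:k). Deterministic for fixed seed.
.stratifiedFolds <- function(pos, k, seed) {
  fold <- integer(length(pos))
  set.seed(as.integer(seed))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(pos == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Select a confidence threshold by cross-validation
#'
#' Stratified k-fold cross-validation: each fold is scored by a model
#' trained on the remaining folds, and the threshold grid is the set of
#' distinct out-of-fold scores (exact, no binning). For each candidate
#' threshold t, per-fold precision and recall are computed with the rule
#' "score >= t predicts positive" (a fold with no predicted positives
#' counts precision 1, vacuously). The smallest t whose mean fold precision
#' reaches \code{precisionTarget} is selected; if none does, the maximum
#' observed score is returned with \code{reached = FALSE}.
#'
#' @param examples labeled feature data.frame (both classes present in
#'   every fold; folds are stratified).
#' @param k number of folds (default 5).
#' @param precisionTarget required mean cross-validated precision (default
#'   1.0).
#' @param seed RNG seed controlling fold assignment and per-fold model
#'   fits.
#' @param nTrees forest size for the per-fold models (default 13).
#' @param scoreFun optional \code{function(trainExamples, testExamples)}
#'   returning scores for the test rows, replacing the forest (used for
#'   controlled experiments and testing).
#' @return A \linkS4class{ThresholdReport}.
#' @export
selectThresholdCv <- function(examples, k = 5L, precisionTarget = 1.0,
                              seed = 1L, nTrees = 13L, scoreFun = NULL) {
  stopifnot(k >= 2)
  pos <- .asPositive(examples$label)
  k <- as.integer(k)
  fold <- .stratifiedFolds(pos, k, seed)
  scores <- numeric(nrow(examples))
  for (f in seq_len(k)) {
    inTest <- fold == f
    if (is.null(scoreFun)) {
      m <- trainTargetModel(examples[!inTest, , drop = FALSE],
                            nTrees = nTrees, seed = seed + f)
      scores[inTest] <- predictConfidence(m, examples[inTest, , drop = FALSE])
    } else {
      scores[inTest] <- scoreFun(examples[!inTest, , drop = FALSE],
                                 examples[inTest, , drop = FALSE])
    }
  }

  grid <- sort(unique(scores))
  foldStats <- function(t) {
    stats <- vapply(seq_len(k), function(f) {
      inF <- fold == f
      pred <- scores[inF] >= t
      tp <- sum(pred & pos[inF])
      fp <- sum(pred & !pos[inF])
      fn <- sum(!pred & pos[inF])
      c(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
        recall = if (tp + fn == 0) 0 else tp / (tp + fn))
    }, numeric(2))
    list(precision = stats["precision", ], recall = stats["recall", ])
  }

  chosen <- NA_real_
  reached <- FALSE
  for (t in grid) {
    if (mean(foldStats(t)$precision) >= precisionTarget) {
      chosen <- t
      reached <- TRUE
      break
    }
  }
  if (!reached) {
    warning("precision target ", precisionTarget,
            " not reached at any threshold; returning the maximum score")
    chosen <- max(grid)
  }
  fs <- foldStats(chosen)
  new("ThresholdReport", threshold = chosen,
      cvRecallMean = mean(fs$recall), cvRecallSd = stats::sd(fs$recall),
      cvPrecisionMean = mean(fs$precision),
      cvPrecisionSd = stats::sd(fs$precision),
      k = k, reached = reached)
}
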