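#' Scan and alignment parameters
#'
#' Parameters of the miRanda-style complementarity scan: alignment scoring
#' (match/wobble/mismatch, affine gaps), the reporting thresholds on
#' alignment score and hybridization energy, and the bulge slack allowed
#' between miRNA length and site length.
#'
#' @slot minScore minimum alignment score for a candidate site (dimensionless).
#' @slot maxEnergy maximum (i.e. least negative) hybridization free energy,
#'   kcal/mol.
#' @slot allowWobble logical; score and count G:U pairs as paired.
#' @slot matchScore,wobbleScore,mismatchPenalty per-position alignment scores.
#' @slot gapOpen,gapExtend affine gap costs (a gap of length k costs
#'   \code{gapOpen + (k-1) * gapExtend}); both must be <= 0.
#' @slot maxGapSlack maximum difference, in nt, between site length and
#'   miRNA length (bounded bulges).
#' @export
setClass("ScanParams", representation(
  minScore = "numeric", maxEnergy = "numeric", allowWobble = "logical",
  matchScore = "numeric", wobbleScore = "numeric",
  mismatchPenalty = "numeric", gapOpen = "numeric", gapExtend = "numeric",
  maxGapSlack = "integer"
))

setValidity("ScanParams", function(object) {
  msg <- character()
  if (object@matchScore <= 0) msg <- c(msg, "matchScore must be > 0")
  if (object@mismatchPenalty > 0) msg <- c(msg, "mismatchPenalty must be <= 0")
  if (object@gapOpen > 0) msg <- c(msg, "gapOpen must be <= 0")
  if (object@gapExtend > 0) msg <- c(msg, "gapExtend must be <= 0")
  if (object@maxGapSlack < 0) msg <- c(msg, "maxGapSlack must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct scan parameters
#'
#' Defaults are miRanda-like: +5 per Watson-Crick pair, +1 per G:U wobble,
#' -3 per mismatch, affine gaps at -8/-2, candidate threshold 80 on the
#' alignment score and -15 kcal/mol on the duplex energy, and up to 4 nt of
#' bulge slack. No seed weighting is applied anywhere: plant targeting is
#' not seed-restricted and pre-filtering on the seed would discard
#' non-canonical sites.
#'
#' @param minScore,maxEnergy,allowWobble,matchScore,wobbleScore,mismatchPenalty
#'   see \linkS4class{ScanParams}.
#' @param gapOpen,gapExtend,maxGapSlack see \linkS4class{ScanParams}.
#' @return A \linkS4class{ScanParams} object.
#' @examples
#' scanParams(minScore = 90)
#' @export
scanParams <- function(minScore = 80, maxEnergy = -15, allowWobble = TRUE,
                       matchScore = 5, wobbleScore = 1, mismatchPenalty = -3,
                       gapOpen = -8, gapExtend = -2, maxGapSlack = 4L) {
  new("ScanParams", minScore = minScore, maxEnergy = maxEnergy,
      allowWobble = allowWobble, matchScore = matchScore,
      wobbleScore = wobbleScore, mismatchPenalty = mismatchPenalty,
      gapOpen = gapOpen, gapExtend = gapExtend,
      maxGapSlack = as.integer(maxGapSlack))
}

setMethod("show", "ScanParams", function(object) {
  cat("ScanParams: match", object@matchScore,
      "wobble", if (object@allowWobble) object@wobbleScore else "off",
      "mismatch", object@mismatchPenalty,
      "gap", paste0(object@gapOpen, "/", object@gapExtend),
      "| minScore", object@minScore,
      "maxEnergy", object@maxEnergy, "kcal/mol\n")
})

#' A miRNA:mRNA duplex
#'
#' The base-pairing structure and energetics of one candidate interaction:
#' the site interval on the transcript (1-based, inclusive), a pairing state
#' per miRNA position counted 1..L from the 5' end (\code{"WC"},
#' \code{"WOBBLE"} or \code{"UNPAIRED"}), the hybridization free energy and
#' the complementarity alignment score. The duplex is antiparallel: miRNA
#' position 1 pairs near the site's 3' end.
#'
#' @slot mirnaId,transcriptId identifiers.
#' @slot siteStart,siteEnd 1-based inclusive transcript coordinates.
#' @slot pairing character vector, one state per miRNA position.
#' @slot energy hybridization free energy in kcal/mol (<= 0; 0 when no
#'   stable duplex forms).
#' @slot score complementarity alignment score.
#' @export
setClass("Duplex", representation(
  mirnaId = "character", transcriptId = "character",
  siteStart = "integer", siteEnd = "integer",
  pairing = "character", energy = "numeric", score = "numeric"
))

setValidity("Duplex", function(object) {
  msg <- character()
  if (!all(object@pairing %in% c("WC", "WOBBLE", "UNPAIRED")))
    msg <- c(msg, "pairing states must be WC/WOBBLE/UNPAIRED")
  if (length(object@energy) != 1 || object@energy > 0)
    msg <- c(msg, "energy must be a single value <= 0")
  if (!any(object@pairing != "UNPAIRED") && object@energy != 0)
    msg <- c(msg, "energy must be 0 when no position is paired")
  if (object@siteStart > 0 && object@siteEnd < object@siteStart)
    msg <- c(msg, "siteEnd must be >= siteStart")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Duplex", function(object) {
  np <- sum(object@pairing != "UNPAIRED")
  cat(sprintf("Duplex %s : %s [%d, %d]  %d/%d paired  %.2f kcal/mol  score %.1f\n",
              object@mirnaId, object@transcriptId,
              object@siteStart, object@siteEnd,
              np, length(object@pairing), object@energy, object@score))
})

#' Accessors for Duplex objects
#'
#' @param x A \linkS4class{Duplex}.
#' @return \code{pairing}: character vector of per-position pairing states;
#'   \code{siteRange}: integer vector \code{c(start, end)};
#'   \code{duplexScore} and \code{duplexEnergyOf}: single numerics.
#' @name duplex-accessors
NULL

#' @rdname duplex-accessors
#' @export
pairing <- function(x) x@pairing
#' @rdname duplex-accessors
#' @export
siteRange <- function(x) c(x@siteStart, x@siteEnd)
#' @rdname duplex-accessors
#' @export
duplexScore <- function(x) x@score
#' @rdname duplex-accessors
#' @export
duplexEnergyOf <- function(x) x@energy

#' A trained random-forest target scorer
#'
#' Wraps the fitted 13-tree forest together with the feature order it was
#' trained on and the seed that makes refits reproducible. Confidence is
#' the fraction of trees voting "positive".
#'
#' @slot forest the fitted \code{randomForest} object.
#' @slot featureOrder character vector of the 11 feature names.
#' @slot nTrees number of trees (13 by default throughout the package).
#' @slot seed integer seed the forest was fitted under.
#' @export
setClass("TargetModel", representation(
  forest = "ANY", featureOrder = "character",
  nTrees = "integer", seed = "integer"
))

setValidity("TargetModel", function(object) {
  if (!identical(object@featureOrder, .FEATURES))
    "featureOrder must be the canonical 11-feature order (targetFeatureNames())"
  else TRUE
})

setMethod("show", "TargetModel", function(object) {
  cat(sprintf("TargetModel: %d trees, %d features, seed %d\n",
              object@nTrees, length(object@featureOrder), object@seed))
})

#' A precision-recall curve
#'
#' @slot points data.frame with columns \code{threshold}, \code{recall},
#'   \code{precision}, one row per distinct score (descending thresholds,
#'   nondecreasing recall); tied scores flip together.
#' @slot auc area under the curve by step-wise (rectangular) integration
#'   over recall.
#' @export
setClass("PRCurve", representation(points = "data.frame", auc = "numeric"))

setValidity("PRCurve", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0,1]")
  if (is.unsorted(object@points$recall)) msg <- c(msg, "recall must be nondecreasing")
  if (length(msg)) msg else TRUE
})

#' @rdname prCurve
#' @param x A \linkS4class{PRCurve}.
#' @export
prAuc <- function(x) x@auc

#' @rdname prCurve
#' @export
prPoints <- function(x) x@points

setMethod("show", "PRCurve", function(object) {
  cat(sprintf("PRCurve: %d points, AUC = %.4f\n",
              nrow(object@points), object@auc))
})

#' A cross-validated confidence-threshold report
#'
#' @slot threshold selected confidence threshold in \[0,1\].
#' @slot cvRecallMean,cvRecallSd,cvPrecisionMean,cvPrecisionSd fold statistics
#'   at the selected threshold.
#' @slot k number of folds.
#' @slot reached logical; FALSE when no threshold attained the precision
#'   target and the maximum observed score was returned instead.
#' @export
setClass("ThresholdReport", representation(
  threshold = "numeric", cvRecallMean = "numeric", cvRecallSd = "numeric",
  cvPrecisionMean = "numeric", cvPrecisionSd = "numeric",
  k = "integer", reached = "logical"
))

setMethod("show", "ThresholdReport", function(object) {
  cat(sprintf(
    "ThresholdReport (k = %d): threshold %.4f%s | recall %.3f +/- %.3f, precision %.3f +/- %.3f\n",
    object@k, object@threshold,
    if (object@reached) "" else " (precision target not reached)",
    object@cvRecallMean, object@cvRecallSd,
    object@cvPrecisionMean, object@cvPrecisionSd))
})

#' A homology-controlled train/test split
#'
#' @slot train,test labeled example data.frames (11 features + metadata).
#' @slot testSpecies species code held out for testing.
#' @slot threshold miRNA identity threshold (default 0.70) below which a
#'   training miRNA must stay relative to every test miRNA.
#' @slot removed named integer vector of bookkeeping counts: test examples
#'   dropped as feature-duplicates or by the exclusion list, training
#'   examples dropped as homologs.
#' @export
setClass("DatasetSplit", representation(
  train = "data.frame", test = "data.frame",
  testSpecies = "character", threshold = "numeric", removed = "integer"
))

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf(
    "DatasetSplit: %d train / %d test (test species '%s', identity < %.2f)\n",
    nrow(object@train), nrow(object@test), object@testSpecies,
    object@threshold))
  cat("  removed:", paste(names(object@removed), object@removed,
                          sep = "=", collapse = ", "), "\n")
})

#' @rdname makeSplit
#' @param x A \linkS4class{DatasetSplit}.
#' @export
trainExamples <- function(x) x@train

#' @rdname makeSplit
#' @export
testExamples <- function(x) x@test
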