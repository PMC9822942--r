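# End-to-end orchestration: configuration, whole-transcriptome prediction,
# and the four-classifier training-mixture experiment.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Values pinned
#' throughout the package: identity threshold 0.70, 13 trees, 5 CV folds,
#' evaluation threshold 0.5. Precedence is defaults < YAML config file <
#' arguments passed here (the CLI maps its flags onto these arguments).
#'
#' @param file optional YAML file whose top-level keys override defaults
#'   (scan parameters under a \code{scan:} key).
#' @param ... named overrides applied last: any of \code{tol},
#'   \code{flank}, \code{context}, \code{identityThreshold}, \code{nTrees},
#'   \code{cvFolds}, \code{evalThreshold}, \code{seed}, \code{params} (a
#'   \linkS4class{ScanParams}), or individual scan parameter names (e.g.
#'   \code{minScore}).
#' @return Named list of settings with class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(file = NULL, ...) {
  cfg <- list(
    params = scanParams(), tol = c(0.05, 0.10, 0.20),
    flank = 10, context = 70, identityThreshold = 0.70,
    nTrees = 13L, cvFolds = 5L, evalThreshold = 0.5, seed = 1L
  )
  scanArgs <- c("minScore", "maxEnergy", "allowWobble", "matchScore",
                "wobbleScore", "mismatchPenalty", "gapOpen", "gapExtend",
                "maxGapSlack")
  apply1 <- function(cfg, vals) {
    for (nm in names(vals)) {
      if (nm == "scan" || nm %in% scanArgs) {
        upd <- if (nm == "scan") vals$scan else vals[nm]
        for (s in names(upd)) {
          if (!s %in% scanArgs) stop("unknown scan parameter: ", s)
          methods::slot(cfg$params, s) <-
            if (s %in% c("maxGapSlack")) as.integer(upd[[s]]) else upd[[s]]
        }
        methods::validObject(cfg$params)
      } else if (nm %in% names(cfg)) {
        cfg[[nm]] <- vals[[nm]]
      } else {
        stop("unknown configuration key: ", nm, call. = FALSE)
      }
    }
    cfg
  }
  if (!is.null(file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read config files")
    cfg <- apply1(cfg, yaml::read_yaml(file))
  }
  cfg <- apply1(cfg, list(...))
  class(cfg) <- "PipelineConfig"
  cfg
}

.asSeqSet <- function(x, reader = readRnaFasta) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) reader(x) else x
}

#' Predict target sites for all miRNA x transcript pairs
#'
#' For every pair, scans the transcript for candidate sites
#' (\code{\link{scanCandidateSites}}), extracts the 11 features, and scores
#' each site with the trained forest. All candidate sites are reported
#' (nothing is pre-filtered on confidence), sorted by confidence
#' descending; ties by miRNA id, transcript id, then site start. The
#' reported seed is the longest consecutive pairing run: its 5'-most miRNA
#' position, the transcript position its last paired base sits on, and the
#' two subsequences.
#'
#' @param mirnas,transcripts sequence sets (RNAStringSet, named character,
#'   or a FASTA path).
#' @param model A \linkS4class{TargetModel}.
#' @param config A \code{\link{pipelineConfig}} list.
#' @param outPath optional CSV path written via
#'   \code{\link{writePredictions}}.
#' @return Prediction data.frame (invisibly when \code{outPath} is given):
#'   ids, seed indices and sequences, site interval, confidence.
#' @export
runPredict <- function(mirnas, transcripts, model,
                       config = pipelineConfig(), outPath = NULL) {
  mirnas <- .asSeqSet(mirnas, readMirnaFasta)
  transcripts <- .asSeqSet(transcripts)
  mseq <- .seqChar(mirnas)
  tseq <- .seqChar(transcripts)
  if (length(mseq) == 0) stop("no miRNA sequences", call. = FALSE)
  if (length(tseq) == 0) stop("no transcript sequences", call. = FALSE)

  rows <- list()
  for (mid in names(mseq)) {
    for (tid in names(tseq)) {
      hits <- scanCandidateSites(stats::setNames(mseq[mid], mid),
                                 stats::setNames(tseq[tid], tid),
                                 config$params)
      for (h in hits) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, transcript_id = tid,
          site_start = h@siteStart, site_end = h@siteEnd,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(
    mirna_id = character(), transcript_id = character(),
    mirna_seed_index = integer(), mrna_seed_index = integer(),
    mirna_seed_seq = character(), mrna_seed_seq = character(),
    site_start = integer(), site_end = integer(), confidence = numeric(),
    stringsAsFactors = FALSE)
  if (length(rows) == 0) {
    message("no candidate sites found for any pair")
    if (!is.null(outPath)) writePredictions(empty, outPath)
    return(if (is.null(outPath)) empty else invisible(empty))
  }
  sites <- do.call(rbind, rows)
  sf <- .siteFeatures(sites, mseq, tseq, config$params,
                      config$flank, config$context)
  conf <- predictConfidence(model, sf$features)

  seed <- t(vapply(seq_len(nrow(sites)), function(i) {
    run <- longestConsecutivePairings(sf$pairing[[i]])
    if (run["length"] == 0) return(c(idx = 0, lo = 0, hi = 0))
    lo <- run["pos"]
    hi <- lo + run["length"] - 1
    c(idx = unname(lo), lo = unname(lo), hi = unname(hi))
  }, numeric(3)))
  out <- sites
  out$mirna_seed_index <- as.integer(seed[, "idx"])
  out$mirna_seed_seq <- substring(mseq[sites$mirna_id],
                                  seed[, "lo"], seed[, "hi"])
  mrnaSeed <- vapply(seq_len(nrow(sites)), function(i) {
    if (seed[i, "idx"] == 0) return(c(0L, 0L))
    sp <- sf$sitePos[[i]][seed[i, "lo"]:seed[i, "hi"]]
    sp <- sp[sp > 0] + sites$site_start[i] - 1L
    if (length(sp) == 0) return(c(0L, 0L))
    range(sp)
  }, integer(2))
  out$mrna_seed_index <- mrnaSeed[1, ]
  out$mrna_seed_seq <- ifelse(mrnaSeed[1, ] > 0,
                              substring(tseq[sites$transcript_id],
                                        mrnaSeed[1, ], mrnaSeed[2, ]), "")
  out$confidence <- conf
  out <- out[order(-out$confidence, out$mirna_id, out$transcript_id,
                   out$site_start), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(outPath)) {
    writePredictions(out, outPath)
    return(invisible(out))
  }
  out
}

#' Train and evaluate one classifier of the training-mixture experiment
#'
#' Reproduces the four-classifier design at corpus scale: the training pool
#' is assembled from the named example pools according to \code{mixture},
#' the homology-controlled split against \code{testSpecies} is applied
#' (with an embedded leakage audit that aborts if any train/test miRNA
#' pair reaches the identity threshold), a forest is trained, and the test
#' set is scored.
#'
#' @param pools named list of labeled feature data.frames. Required names
#'   per mixture: \code{animal_only} -> \code{animal};
#'   \code{animal_plus_small_plant} -> \code{animal}, \code{small_plant};
#'   \code{animal_plus_plant} -> \code{animal}, \code{plant};
#'   \code{plant_only} -> \code{plant}. The test set is always drawn from
#'   the \code{plant} pool.
#' @param mirnas sequence set resolving every \code{mirna_id} in the pools.
#' @param mixture one of the four mixture names above.
#' @param testSpecies species held out for testing.
#' @param config A \code{\link{pipelineConfig}} list.
#' @return One-row data.frame: mixture, test species, PR-AUC, recall,
#'   precision and accuracy at the evaluation threshold, and train/test
#'   sizes.
#' @export
runExperiment <- function(pools, mirnas, mixture, testSpecies,
                          config = pipelineConfig()) {
  mixture <- match.arg(mixture, c("animal_only", "animal_plus_small_plant",
                                  "animal_plus_plant", "plant_only"))
  need <- switch(mixture,
    animal_only = "animal",
    animal_plus_small_plant = c("animal", "small_plant"),
    animal_plus_plant = c("animal", "plant"),
    plant_only = "plant")
  miss <- setdiff(c(need, "plant"), names(pools))
  if (length(miss))
    stop("missing example pool(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  trainPool <- do.call(rbind, lapply(pools[need], function(p) {
    p[p$species != testSpecies, , drop = FALSE]
  }))
  testPool <- pools$plant[pools$plant$species == testSpecies, , drop = FALSE]
  if (nrow(testPool) == 0)
    stop("test species '", testSpecies, "' absent from the plant pool",
         call. = FALSE)
  examples <- rbind(trainPool, testPool)
  rownames(examples) <- NULL

  split <- makeSplit(examples, mirnas, testSpecies,
                     threshold = config$identityThreshold)
  leak <- auditSplit(split, mirnas)
  if (leak >= config$identityThreshold)
    stop("leakage audit failed: max train/test identity ", round(leak, 3),
         call. = FALSE)

  model <- trainTargetModel(split@train, nTrees = config$nTrees,
                            seed = config$seed)
  scores <- predictConfidence(model, split@test)
  pc <- prCurve(scores, split@test$label)
  mt <- metricsAtThreshold(scores, split@test$label, config$evalThreshold)
  data.frame(
    mixture = mixture, test_species = testSpecies,
    auc = pc@auc, recall = mt$recall, precision = mt$precision,
    accuracy = mt$accuracy,
    n_train = nrow(split@train), n_test = nrow(split@test),
    stringsAsFactors = FALSE)
}
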