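# Homology control: pairwise miRNA identity, CD-HIT-style greedy
# clustering, and leakage-free train/test splitting. Identity uses the
# CD-HIT convention: identical aligned positions over the length of the
# shorter sequence, with the identical-position count maximized over global
# alignments (equivalently, the longest common subsequence).

#' Pairwise sequence identity
#'
#' Number of identical aligned positions in the optimal global alignment,
#' divided by the length of the shorter sequence (CD-HIT's denominator).
#' The identical-position count is maximized over all global alignments,
#' i.e. it is the longest-common-subsequence length, so the measure is
#' symmetric and in \[0, 1\].
#'
#' @param a,b non-empty sequences (character).
#' @return Identity fraction in \[0, 1\].
#' @examples
#' pairwiseIdentity("ACGU", "ACGU")  # 1
#' pairwiseIdentity("AAAA", "CCCC")  # 0
#' @export
pairwiseIdentity <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  .lcsLengthCpp(a, b) / min(nchar(a), nchar(b))
}

#' Greedy incremental clustering of miRNAs at an identity threshold
#'
#' CD-HIT-style: sequences are sorted by length (descending, ties keeping
#' input order); each joins the first existing cluster whose representative
#' (its longest, first-seen member) has identity >= \code{threshold},
#' otherwise it founds a new cluster. Deterministic. Exact pairwise
#' identity replaces CD-HIT's k-mer prefilter — at the sequence counts this
#' package handles, exact computation is affordable and exactly testable.
#'
#' @param mirnas RNAStringSet or named character vector.
#' @param threshold identity threshold in (0, 1\] (default 0.70).
#' @return List of character vectors of ids (or indices when unnamed), one
#'   per cluster; the first id in each cluster is its representative.
#' @export
clusterMirnas <- function(mirnas, threshold = 0.70) {
  seqs <- .seqChar(mirnas)
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  stopifnot(threshold > 0, threshold <= 1)
  ord <- order(-nchar(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwiseIdentity(seqs[[i]], reps[k]) >= threshold) {
        members[[k]] <- c(members[[k]], names(seqs)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, seqs[[i]])
      members[[length(reps)]] <- names(seqs)[i]
    }
  }
  members
}

#' Build a leakage-free train/test split
#'
#' Emulates evaluation on an unannotated species: the test set is every
#' example of \code{testSpecies} (after removing test examples with exactly
#' duplicated 11-feature vectors, keeping the first, and optionally those
#' whose miRNA resembles an exclusion list); the training set is every
#' other example whose miRNA has pairwise identity below \code{threshold}
#' to \emph{every} test miRNA. Identity >= threshold ("greater than 70\%"
#' read conservatively, boundary included) excludes the example.
#'
#' @param examples labeled feature data.frame with columns \code{mirna_id},
#'   \code{species}, the 11 features and \code{label}.
#' @param mirnas sequence set resolving every \code{mirna_id}.
#' @param testSpecies species code to hold out (error if absent).
#' @param threshold identity threshold (default 0.70).
#' @param excludeLike optional sequences (RNAStringSet or character); test
#'   examples whose miRNA has identity >= threshold to any of them are
#'   dropped (mirrors excluding test interactions resembling an already-used
#'   reference species).
#' @return A \linkS4class{DatasetSplit}.
#' @export
makeSplit <- function(examples, mirnas, testSpecies, threshold = 0.70,
                      excludeLike = NULL) {
  stopifnot(is.data.frame(examples), "species" %in% colnames(examples))
  mseq <- .seqChar(mirnas)
  isTest <- examples$species == testSpecies
  if (!any(isTest))
    stop("test species '", testSpecies, "' absent from examples",
         call. = FALSE)
  test <- examples[isTest, , drop = FALSE]

  key <- do.call(paste, c(test[, .FEATURES], sep = "\r"))
  ndup <- sum(duplicated(key))
  test <- test[!duplicated(key), , drop = FALSE]

  nexcl <- 0L
  if (!is.null(excludeLike) && length(excludeLike) > 0) {
    ex <- .seqChar(excludeLike)
    hit <- vapply(mseq[test$mirna_id], function(s) {
      any(vapply(ex, function(x) pairwiseIdentity(s, x) >= threshold,
                 logical(1)))
    }, logical(1))
    nexcl <- sum(hit)
    test <- test[!hit, , drop = FALSE]
  }

  train <- examples[!isTest, , drop = FALSE]
  testSeqs <- unique(mseq[unique(test$mirna_id)])
  trainIds <- unique(train$mirna_id)
  homolog <- vapply(mseq[trainIds], function(s) {
    any(vapply(testSeqs, function(x) pairwiseIdentity(s, x) >= threshold,
               logical(1)))
  }, logical(1))
  nhom <- sum(train$mirna_id %in% trainIds[homolog])
  train <- train[!train$mirna_id %in% trainIds[homolog], , drop = FALSE]

  new("DatasetSplit", train = train, test = test,
      testSpecies = testSpecies, threshold = threshold,
      removed = c(test_duplicates = as.integer(ndup),
                  test_excluded = as.integer(nexcl),
                  train_homologs = as.integer(nhom)))
}

#' Audit a split for sequence-identity leakage
#'
#' Exhaustive all-pairs check: the maximum identity between any training
#' miRNA and any test miRNA.
#'
#' @param split A \linkS4class{DatasetSplit}.
#' @param mirnas sequence set resolving every \code{mirna_id}.
#' @return Maximum cross-split identity (0 when either side is empty).
#' @export
auditSplit <- function(split, mirnas) {
  mseq <- .seqChar(mirnas)
  a <- unique(split@train$mirna_id)
  b <- unique(split@test$mirna_id)
  if (length(a) == 0 || length(b) == 0) return(0)
  max(vapply(mseq[a], function(s) {
    max(vapply(mseq[b], function(x) pairwiseIdentity(s, x), numeric(1)))
  }, numeric(1)))
}
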