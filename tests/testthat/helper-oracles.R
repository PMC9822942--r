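# Independent oracles and small fixture builders shared across the suite.
# Every oracle recomputes its quantity by brute force or through a package
# that is not on the code path it checks.

randRna <- function(n, probs = c(A = .25, C = .25, G = .25, U = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

revComp <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# --- pairing-vector oracles: exhaustive enumeration ------------------------

# longest run of TRUE by checking every (start, length) interval
oracleLongestRun <- function(paired) {
  best <- c(length = 0, pos = 0)
  n <- length(paired)
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(paired[s:e]) && (e - s + 1) > best["length"]) {
        best <- c(length = e - s + 1, pos = s)
      }
    }
  }
  best
}

oraclePairingCounts <- function(paired) {
  L <- length(paired)
  seed <- sum(paired[intersect(2:8, seq_len(L))])
  p3 <- if (L >= 13) sum(paired[13:L]) else 0
  list(seed_match = seed, n_paired = sum(paired), n_paired_3p = p3,
       seed_minus_3p = seed - p3)
}

# --- alignment oracles via Biostrings --------------------------------------

complementarityMatrix <- function(match = 5, wobble = 1, mismatch = -3,
                                  allowWobble = TRUE) {
  b <- c("A", "C", "G", "U")
  m <- matrix(mismatch, 4, 4, dimnames = list(b, b))
  m["A", "U"] <- m["U", "A"] <- m["G", "C"] <- m["C", "G"] <- match
  if (allowWobble) m["G", "U"] <- m["U", "G"] <- wobble
  m
}

# optimal local complementarity score of mirna vs site read 3'->5',
# affine gaps costing |gapOpen| + (k-1)|gapExtend| for length k
oracleLocalScore <- function(mirna, site, params = scanParams()) {
  m <- complementarityMatrix(params@matchScore, params@wobbleScore,
                             params@mismatchPenalty, params@allowWobble)
  rev_site <- paste(rev(strsplit(site, "")[[1]]), collapse = "")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::RNAString(mirna), Biostrings::RNAString(rev_site),
    type = "local", substitutionMatrix = m,
    gapOpening = abs(params@gapOpen) - abs(params@gapExtend),
    gapExtension = abs(params@gapExtend))
  max(0, Biostrings::score(pa))
}

# NW identity: max identical aligned positions (match 1, mismatch/gap 0)
# over the shorter length
oracleIdentity <- function(a, b) {
  m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                       c("A", "C", "G", "U")))
  diag(m) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::RNAString(a), Biostrings::RNAString(b),
    type = "global", substitutionMatrix = m,
    gapOpening = 0, gapExtension = 0)
  Biostrings::score(pa) / min(nchar(a), nchar(b))
}

# --- evaluation oracles ----------------------------------------------------

oracleConfusion <- function(scores, labels, t) {
  pos <- labels == 1 | labels == "positive"
  pred <- scores >= t
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       recall = tp / (tp + fn),
       precision = if (tp + fp == 0) NaN else tp / (tp + fp),
       accuracy = (tp + tn) / length(scores))
}

# step-wise PR-AUC by enumerating every distinct threshold
oraclePrAuc <- function(scores, labels) {
  pos <- labels == 1 | labels == "positive"
  thr <- sort(unique(scores), decreasing = TRUE)
  prevRecall <- 0
  auc <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & pos)
    recall <- tp / sum(pos)
    precision <- tp / sum(pred)
    auc <- auc + (recall - prevRecall) * precision
    prevRecall <- recall
  }
  auc
}

# --- negative-generation oracle --------------------------------------------

# exhaustive enumeration of disjoint CG-matched windows, tolerance ladder,
# energy argmin by direct duplexEnergy calls
oracleNegative <- function(mirna, tseq, s, e, ladder = c(0.05, 0.1, 0.2)) {
  w <- e - s + 1
  n <- nchar(tseq)
  starts <- Filter(function(x) x + w - 1 < s || x > e,
                   seq_len(max(0, n - w + 1)))
  if (length(starts) == 0) return(NULL)
  cgP <- cgDinucleotideFreq(substr(tseq, s, e))
  for (tol in sort(ladder)) {
    surv <- c()
    for (x in starts) {
      win <- substr(tseq, x, x + w - 1)
      if (abs(cgDinucleotideFreq(win) - cgP) <= tol) surv <- c(surv, x)
    }
    if (length(surv) == 0) next
    en <- duplexEnergy(mirna,
                       vapply(surv, function(x) substr(tseq, x, x + w - 1),
                              character(1)))
    best <- surv[which.min(en)]
    return(list(site_start = best, site_end = best + w - 1,
                energy = min(en), tol_used = tol))
  }
  NULL
}

# --- model / CV oracle -----------------------------------------------------

# recompute selectThresholdCv's answer from first principles for a given
# deterministic scoreFun and known fold assignment
oracleThreshold <- function(examples, fold, scores, precisionTarget,
                            k = max(fold)) {
  pos <- examples$label == "positive"
  grid <- sort(unique(scores))
  for (t in grid) {
    prec <- vapply(seq_len(k), function(f) {
      pred <- scores[fold == f] >= t
      p <- pos[fold == f]
      if (sum(pred) == 0) 1 else sum(pred & p) / sum(pred)
    }, numeric(1))
    if (mean(prec) >= precisionTarget) return(t)
  }
  max(grid)
}

# --- tiny labeled feature frames without thermodynamics --------------------

# a directly-constructed feature frame where the two classes differ only in
# seed_match; useful for model tests that need no sequence machinery
toyExamples <- function(nPos = 20, nNeg = 20, seed = 1) {
  set.seed(seed)
  n <- nPos + nNeg
  df <- as.data.frame(matrix(0, n, 11))
  colnames(df) <- targetFeatureNames()
  df$folding_energy <- -20
  df$accessibility <- 0.5
  df$au_content <- 0.5
  df$me_motif <- 0.5
  df$site_length <- 21
  df$seed_match <- c(rep(7, nPos), rep(0, nNeg))
  df$n_paired <- df$seed_match + 4
  df$longest_run <- pmax(1, df$seed_match)
  df$longest_run_pos <- 2
  df$n_paired_3p <- 2
  df$seed_minus_3p <- df$seed_match - df$n_paired_3p
  # tiny jitter so rows are not exact duplicates
  df$au_content <- df$au_content + stats::runif(n, -0.01, 0.01)
  df$label <- c(rep("positive", nPos), rep("negative", nNeg))
  df$species <- "gma"
  df$mirna_id <- paste0("m", seq_len(n))
  df
}
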