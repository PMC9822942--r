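# The miRanda-like stage: complementarity alignment of a miRNA against a
# candidate site and the transcript scan built on it.

# Raw alignment of mirnaSeq (5'->3') vs siteSeq read 3'->5'. Returns the
# C++ result with pairing recoded to WC/WOBBLE/UNPAIRED.
.alignCore <- function(mirnaSeq, siteSeq, params) {
  res <- .alignCoreCpp(mirnaSeq, siteSeq,
                       params@matchScore, params@wobbleScore,
                       params@mismatchPenalty, params@gapOpen,
                       params@gapExtend, params@allowWobble)
  res$pairing <- c("UNPAIRED", "WC", "WOBBLE")[res$pairing + 1L]
  res
}

#' Align a miRNA against a candidate target site
#'
#' Optimal local complementarity alignment of the miRNA (5' to 3') against
#' the site read 3' to 5' (antiparallel duplex), scored with
#' match/wobble/mismatch and affine-gap parameters. The result is
#' deterministic for fixed inputs and parameters: ties in the optimum are
#' broken toward the 5'-most position on both strands.
#'
#' @param mirnaSeq,siteSeq RNA sequences (character or XString-coercible).
#' @param params A \linkS4class{ScanParams} object.
#' @param mirnaId,transcriptId identifiers stored in the result.
#' @param siteOffset added to the reported site coordinates (0 when
#'   \code{siteSeq} is the whole reference, \code{windowStart - 1} when it
#'   is a window of a longer transcript).
#' @param computeEnergy compute the hybridization energy of the site
#'   sequence via \code{\link{duplexEnergy}} (requires RNAduplex).
#' @return A \linkS4class{Duplex}. With no positive-scoring alignment the
#'   pairing vector is all-UNPAIRED, the score is 0 and the site interval
#'   is \code{[0, 0]}.
#' @examples
#' \dontrun{
#' d <- alignDuplex("UGGAGUGUGACAAUGGUGUUUG",
#'                  "CAAACACCAUUGUCACACUCCA")
#' sum(pairing(d) != "UNPAIRED")  # 22: perfect complementarity
#' }
#' @export
alignDuplex <- function(mirnaSeq, siteSeq, params = scanParams(),
                        mirnaId = "miRNA", transcriptId = "site",
                        siteOffset = 0L, computeEnergy = TRUE) {
  a <- .normalizeRna(as.character(mirnaSeq), "miRNA sequence")
  b <- .normalizeRna(as.character(siteSeq), "site sequence")
  res <- .alignCore(a, b, params)
  paired <- any(res$pairing != "UNPAIRED")
  energy <- if (computeEnergy && paired) duplexEnergy(a, b) else 0
  off <- if (res$site_start > 0) as.integer(siteOffset) else 0L
  new("Duplex", mirnaId = mirnaId, transcriptId = transcriptId,
      siteStart = as.integer(res$site_start) + off,
      siteEnd = as.integer(res$site_end) + off,
      pairing = res$pairing, energy = energy, score = res$score)
}

#' Scan a transcript for candidate miRNA target sites
#'
#' Slides a window of width miRNA length + \code{maxGapSlack} along the
#' transcript (stride 1), aligns the miRNA against every window, keeps
#' hits with alignment score >= \code{minScore} and hybridization energy
#' <= \code{maxEnergy}, and merges overlapping hits keeping the best one
#' (highest score, then lowest energy, then smallest start) — plant mRNAs
#' typically carry a single site per miRNA, so one duplex per cluster is
#' reported. Results are sorted by site start and deterministic.
#'
#' @param mirna,transcript single sequences: length-1 RNAStringSet, named
#'   character, or plain character (ids default to \code{"miRNA"} /
#'   \code{"transcript"}).
#' @param params A \linkS4class{ScanParams}.
#' @return List of \linkS4class{Duplex} objects; empty when the transcript
#'   is shorter than the miRNA or nothing passes the thresholds.
#' @export
scanCandidateSites <- function(mirna, transcript, params = scanParams()) {
  mseq <- .seqChar(mirna)[1]
  tseq <- .seqChar(transcript)[1]
  mid <- names(.seqChar(mirna))[1] %||% "miRNA"
  tid <- names(.seqChar(transcript))[1] %||% "transcript"
  mseq <- .normalizeRna(mseq, "miRNA sequence")
  tseq <- .normalizeRna(tseq, "transcript sequence")
  L <- nchar(mseq)
  Tn <- nchar(tseq)
  if (Tn < L) return(list())

  w <- min(Tn, L + params@maxGapSlack)
  starts <- seq_len(Tn - w + 1L)
  hits <- vector("list", length(starts))
  nhit <- 0L
  seen <- character(0)
  for (s in starts) {
    res <- .alignCore(mseq, substring(tseq, s, s + w - 1L), params)
    if (res$score < params@minScore || res$site_start == 0) next
    ss <- s + res$site_start - 1L
    se <- s + res$site_end - 1L
    len <- se - ss + 1L
    if (len < L - params@maxGapSlack || len > L + params@maxGapSlack) next
    key <- paste(ss, se, res$score)
    if (key %in% seen) next  # neighboring windows re-find the same duplex
    seen <- c(seen, key)
    nhit <- nhit + 1L
    hits[[nhit]] <- list(start = ss, end = se, score = res$score,
                         pairing = res$pairing)
  }
  if (nhit == 0L) return(list())
  hits <- hits[seq_len(nhit)]

  energy <- duplexEnergy(mseq, substring(tseq,
                                         vapply(hits, `[[`, 0L, "start"),
                                         vapply(hits, `[[`, 0L, "end")))
  keep <- energy <= params@maxEnergy
  hits <- hits[keep]
  energy <- energy[keep]
  if (length(hits) == 0L) return(list())

  ord <- order(-vapply(hits, `[[`, 0, "score"), energy,
               vapply(hits, `[[`, 0L, "start"))
  hits <- hits[ord]
  energy <- energy[ord]
  kept <- logical(length(hits))
  for (i in seq_along(hits)) {
    ok <- TRUE
    for (j in which(kept)) {
      if (hits[[i]]$start <= hits[[j]]$end && hits[[j]]$start <= hits[[i]]$end) {
        ok <- FALSE
        break
      }
    }
    kept[i] <- ok
  }
  hits <- hits[kept]
  energy <- energy[kept]
  ord <- order(vapply(hits, `[[`, 0L, "start"))
  mapply(function(h, e) {
    new("Duplex", mirnaId = mid, transcriptId = tid,
        siteStart = as.integer(h$start), siteEnd = as.integer(h$end),
        pairing = h$pairing, energy = e, score = h$score)
  }, hits[ord], energy[ord], SIMPLIFY = FALSE)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || is.na(a)) b else a
}
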