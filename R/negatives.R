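# Negative exemplar generation: for each documented positive interaction,
# pick the most plausible decoy window on the same mRNA — non-overlapping,
# CG-dinucleotide-matched, and minimum hybridization energy — so the
# classifier must learn more than "does some window pair at all".

#' CG dinucleotide frequency
#'
#' Count of \code{"CG"} dinucleotides (overlapping scan) divided by
#' (length - 1).
#'
#' @param seq RNA sequence of length >= 2 (character).
#' @return Fraction in \[0, 1\].
#' @examples
#' cgDinucleotideFreq("CGCGCG")  # 0.6
#' @export
cgDinucleotideFreq <- function(seq) {
  seq <- .normalizeRna(as.character(seq), "sequence")
  n <- nchar(seq)
  if (n < 2) stop("sequence must have length >= 2", call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  sum(chars[-n] == "C" & chars[-1] == "G") / (n - 1)
}

# All windows of width w in a transcript of length n that do not overlap
# [s, e]. Returns integer starts (stride 1).
.disjointWindows <- function(n, w, s, e) {
  starts <- seq_len(max(0L, n - w + 1L))
  starts[starts + w - 1L < s | starts > e]
}

#' Generate the negative exemplar for one positive interaction
#'
#' Among all transcript windows of the positive site's length that (a) do
#' not overlap the positive site and (b) have CG dinucleotide frequency
#' within \code{tol} of the positive site's, returns the window with the
#' lowest hybridization energy against the miRNA (ties toward the smaller
#' start). \code{tol} may be a ladder of tolerances, tried strictly in
#' order until at least one window survives; if the ladder is exhausted (or
#' the transcript has no disjoint window at all) the result is \code{NULL}.
#'
#' @param mirnaSeq,transcriptSeq RNA sequences (character).
#' @param siteStart,siteEnd 1-based inclusive coordinates of the positive
#'   site.
#' @param tol absolute CG-frequency tolerance ladder (default
#'   \code{c(0.05, 0.10, 0.20)}).
#' @return \code{NULL}, or a list with \code{site_start}, \code{site_end},
#'   \code{cg_freq}, \code{energy} and \code{tol_used}.
#' @export
generateNegative <- function(mirnaSeq, transcriptSeq, siteStart, siteEnd,
                             tol = c(0.05, 0.10, 0.20)) {
  mseq <- .normalizeRna(as.character(mirnaSeq), "miRNA sequence")
  tseq <- .normalizeRna(as.character(transcriptSeq), "transcript")
  n <- nchar(tseq)
  w <- siteEnd - siteStart + 1L
  stopifnot(siteStart >= 1, siteEnd >= siteStart, siteEnd <= n)

  starts <- .disjointWindows(n, w, siteStart, siteEnd)
  if (length(starts) == 0) return(NULL)
  cgPos <- cgDinucleotideFreq(substring(tseq, siteStart, siteEnd))
  cgWin <- vapply(substring(tseq, starts, starts + w - 1L),
                  cgDinucleotideFreq, numeric(1), USE.NAMES = FALSE)

  for (t in sort(tol)) {
    ok <- abs(cgWin - cgPos) <= t
    if (!any(ok)) next
    cand <- starts[ok]
    energy <- duplexEnergy(mseq, substring(tseq, cand, cand + w - 1L))
    best <- which(energy == min(energy))[1]  # candidates are start-ordered
    return(list(site_start = cand[best], site_end = cand[best] + w - 1L,
                cg_freq = cgWin[ok][best], energy = energy[best],
                tol_used = t))
  }
  NULL
}

#' Build the negative set matching a table of positives
#'
#' Applies \code{\link{generateNegative}} to every positive record: at most
#' one negative per positive, on the same transcript against the same
#' miRNA, labeled \code{"negative"}. Positives whose transcript offers no
#' surviving window contribute nothing (so the negative set is at most as
#' large as the positive set); unresolvable ids are skipped. Both cases are
#' reported in a message and in the \code{"skipped"} attribute.
#'
#' @param positives interaction data.frame (\code{label == "positive"} rows
#'   are used).
#' @param mirnas,transcripts sequence sets (RNAStringSet or named character).
#' @param tol CG tolerance ladder, see \code{\link{generateNegative}}.
#' @return Interaction data.frame of negatives, in the order of the
#'   positives that produced them.
#' @export
buildNegativeSet <- function(positives, mirnas, transcripts,
                             tol = c(0.05, 0.10, 0.20)) {
  mseq <- .seqChar(mirnas)
  tseq <- .seqChar(transcripts)
  pos <- positives[positives$label == "positive", , drop = FALSE]
  rows <- vector("list", nrow(pos))
  skipped <- 0L
  for (i in seq_len(nrow(pos))) {
    mid <- pos$mirna_id[i]
    tid <- pos$transcript_id[i]
    if (!mid %in% names(mseq) || !tid %in% names(tseq)) {
      skipped <- skipped + 1L
      next
    }
    neg <- generateNegative(mseq[[mid]], tseq[[tid]],
                            pos$site_start[i], pos$site_end[i], tol)
    if (is.null(neg)) {
      skipped <- skipped + 1L
      next
    }
    rows[[i]] <- data.frame(
      mirna_id = mid, transcript_id = tid,
      site_start = neg$site_start, site_end = neg$site_end,
      label = "negative", stringsAsFactors = FALSE
    )
  }
  if (skipped > 0)
    message(skipped, " positive(s) yielded no negative exemplar")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(mirna_id = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      label = character(), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
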