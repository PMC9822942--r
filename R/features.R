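# The 11 duplex/site features. Feature order is fixed package-wide
# (targetFeatureNames()); the forest, CSV serializations and prediction
# code all rely on it.

#' Longest run of consecutive paired positions
#'
#' @param pairing character vector of per-miRNA-position states
#'   (\code{"WC"}, \code{"WOBBLE"}, \code{"UNPAIRED"}); wobble counts as
#'   paired.
#' @return Named numeric \code{c(length=, pos=)}: run length in nt and the
#'   1-based miRNA position where the run starts (ties broken toward the 5'
#'   end); \code{c(0, 0)} when nothing is paired.
#' @examples
#' longestConsecutivePairings(c("WC", "WC", "UNPAIRED", "WC", "WC", "WOBBLE"))
#' @export
longestConsecutivePairings <- function(pairing) {
  if (length(pairing) == 0) stop("empty pairing vector", call. = FALSE)
  paired <- pairing != "UNPAIRED"
  r <- rle(paired)
  if (!any(r$values)) return(c(length = 0, pos = 0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # which.max takes the first tie
  c(length = r$lengths[best], pos = starts[best])
}

#' AU content around a target site
#'
#' Fraction of A/U characters in the site extended by \code{flank} nt on
#' each side, clipped at the transcript ends. AU-rich context correlates
#' with site efficacy (weak local structure).
#'
#' @param transcriptSeq RNA sequence (character).
#' @param siteStart,siteEnd 1-based inclusive coordinates.
#' @param flank nt added on each side (default 10).
#' @return Fraction in \[0, 1\].
#' @export
auContent <- function(transcriptSeq, siteStart, siteEnd, flank = 10) {
  seq <- .normalizeRna(as.character(transcriptSeq), "transcript")
  n <- nchar(seq)
  stopifnot(siteStart >= 1, siteEnd >= siteStart, siteEnd <= n)
  win <- substring(seq, max(1, siteStart - flank), min(n, siteEnd + flank))
  mean(strsplit(win, "")[[1]] %in% c("A", "U"))
}

# Reference match(m)/editing(e) profile: paired at miRNA positions 2-8 and
# 13-16, unpaired elsewhere (clipped to the miRNA length).
.meProfile <- function(L) {
  prof <- rep(FALSE, L)
  prof[intersect(c(2:8, 13:16), seq_len(L))] <- TRUE
  prof
}

#' m/e motif score of a pairing vector
#'
#' Fraction of miRNA positions whose paired/unpaired state agrees with a
#' fixed reference profile (paired at positions 2-8 and 13-16, unpaired
#' elsewhere) — i.e. 1 minus the normalized Hamming distance to the
#' profile. The profile captures the classic match/editing architecture of
#' a functional duplex (seed plus 3' supplementary block) and is
#' deliberately simple and deterministic.
#'
#' @inheritParams longestConsecutivePairings
#' @return Score in \[0, 1\].
#' @export
meMotif <- function(pairing) {
  if (length(pairing) == 0) stop("empty pairing vector", call. = FALSE)
  paired <- pairing != "UNPAIRED"
  mean(paired == .meProfile(length(pairing)))
}

# Pairing-derived counts shared by extractFeatures and featureMatrix.
.pairingCounts <- function(pairing) {
  L <- length(pairing)
  paired <- pairing != "UNPAIRED"
  run <- longestConsecutivePairings(pairing)
  seed <- sum(paired[intersect(2:8, seq_len(L))])
  p3 <- if (L >= 13) sum(paired[13:L]) else 0
  c(seed_match = seed, n_paired = sum(paired),
    longest_run = unname(run["length"]), longest_run_pos = unname(run["pos"]),
    n_paired_3p = p3, seed_minus_3p = seed - p3)
}

#' Extract the 11-value feature vector for one duplex
#'
#' Features, in canonical order: hybridization (folding) energy, seed match
#' (paired positions among miRNA positions 2-8), site accessibility, AU
#' content, m/e motif score, total paired positions, site length, longest
#' consecutive pairing run and its 5'-most miRNA position, paired positions
#' in the miRNA 3' region (positions 13..L), and seed match minus the 3'
#' count. G:U wobble counts as paired throughout.
#'
#' @param duplex A \linkS4class{Duplex}.
#' @param mirna,transcript the sequences the duplex refers to (length-1
#'   named character or RNAStringSet); names, when present, must match the
#'   duplex ids.
#' @param flank AU-content flank in nt (default 10).
#' @param context accessibility context in nt per side (default 70).
#' @return Named numeric vector of length 11 in \code{targetFeatureNames()}
#'   order.
#' @export
extractFeatures <- function(duplex, mirna, transcript, flank = 10,
                            context = 70) {
  mseq <- .seqChar(mirna)
  tseq <- .seqChar(transcript)
  if (!is.null(names(mseq)) && !duplex@mirnaId %in% names(mseq))
    stop("miRNA id '", duplex@mirnaId, "' not found", call. = FALSE)
  if (!is.null(names(tseq)) && !duplex@transcriptId %in% names(tseq))
    stop("transcript id '", duplex@transcriptId, "' not found", call. = FALSE)
  mseq <- if (is.null(names(mseq))) mseq[1] else mseq[[duplex@mirnaId]]
  tseq <- if (is.null(names(tseq))) tseq[1] else tseq[[duplex@transcriptId]]

  counts <- .pairingCounts(duplex@pairing)
  s <- duplex@siteStart
  e <- duplex@siteEnd
  noSite <- s == 0
  out <- c(
    folding_energy = duplex@energy,
    seed_match = unname(counts["seed_match"]),
    accessibility = if (noSite) 1 else accessibility(tseq, s, e, context),
    au_content = if (noSite) 0 else auContent(tseq, s, e, flank),
    me_motif = meMotif(duplex@pairing),
    n_paired = unname(counts["n_paired"]),
    site_length = if (noSite) 0 else e - s + 1,
    longest_run = unname(counts["longest_run"]),
    longest_run_pos = unname(counts["longest_run_pos"]),
    n_paired_3p = unname(counts["n_paired_3p"]),
    seed_minus_3p = unname(counts["seed_minus_3p"])
  )
  out[.FEATURES]
}

# Batched feature computation for a table of (mirna_id, transcript_id,
# site_start, site_end): one C++ alignment per row, one RNAduplex call and
# one RNAplfold call for the whole batch. Returns list(features, pairing,
# score, energy, siteSeq).
.siteFeatures <- function(sites, mirnas, transcripts, params = scanParams(),
                          flank = 10, context = 70) {
  mseq <- .seqChar(mirnas)
  tseq <- .seqChar(transcripts)
  n <- nrow(sites)
  siteSeq <- substring(tseq[sites$transcript_id], sites$site_start,
                       sites$site_end)
  aligns <- lapply(seq_len(n), function(i) {
    .alignCore(mseq[[sites$mirna_id[i]]], siteSeq[i], params)
  })
  energy <- if (n > 0) {
    e <- duplexEnergy(mseq[sites$mirna_id], siteSeq)
    # a duplex with nothing paired carries zero energy by convention
    e[vapply(aligns, function(a) all(a$pairing == "UNPAIRED"), logical(1))] <- 0
    e
  } else numeric(0)

  tlen <- nchar(tseq)[sites$transcript_id]
  lo <- pmax(1, sites$site_start - context)
  hi <- pmin(tlen, sites$site_end + context)
  acc <- .accessibilityBatch(substring(tseq[sites$transcript_id], lo, hi),
                             sites$site_start - lo + 1,
                             sites$site_end - lo + 1)
  au <- vapply(seq_len(n), function(i) {
    auContent(tseq[[sites$transcript_id[i]]], sites$site_start[i],
              sites$site_end[i], flank)
  }, numeric(1))

  feats <- t(vapply(seq_len(n), function(i) {
    counts <- .pairingCounts(aligns[[i]]$pairing)
    c(folding_energy = energy[i],
      seed_match = unname(counts["seed_match"]),
      accessibility = acc[i],
      au_content = au[i],
      me_motif = meMotif(aligns[[i]]$pairing),
      n_paired = unname(counts["n_paired"]),
      site_length = sites$site_end[i] - sites$site_start[i] + 1,
      longest_run = unname(counts["longest_run"]),
      longest_run_pos = unname(counts["longest_run_pos"]),
      n_paired_3p = unname(counts["n_paired_3p"]),
      seed_minus_3p = unname(counts["seed_minus_3p"]))
  }, numeric(11)))
  colnames(feats) <- .FEATURES
  list(features = as.data.frame(feats),
       pairing = lapply(aligns, `[[`, "pairing"),
       sitePos = lapply(aligns, `[[`, "site_pos"),
       score = vapply(aligns, `[[`, numeric(1), "score"),
       energy = energy, siteSeq = siteSeq)
}

#' Feature matrix for a table of interaction records
#'
#' Computes the 11 features for every (miRNA, site) row of an interaction
#' table, re-aligning each site and batching all energy and accessibility
#' calls into single ViennaRNA invocations. Metadata columns of
#' \code{sites} (ids, coordinates, label, species) are carried through.
#'
#' @param sites data.frame with columns \code{mirna_id},
#'   \code{transcript_id}, \code{site_start}, \code{site_end} (plus any
#'   metadata, e.g. \code{label}).
#' @param mirnas,transcripts sequence sets (RNAStringSet or named character).
#' @param params \linkS4class{ScanParams} used for the per-site alignment.
#' @param flank,context see \code{\link{extractFeatures}}.
#' @return data.frame: the columns of \code{sites} followed by the 11
#'   features in canonical order.
#' @export
featureMatrix <- function(sites, mirnas, transcripts, params = scanParams(),
                          flank = 10, context = 70) {
  sf <- .siteFeatures(sites, mirnas, transcripts, params, flank, context)
  cbind(sites, sf$features, row.names = NULL)
}

#' Write / read a labeled feature matrix
#'
#' CSV round-trip of the output of \code{\link{featureMatrix}}: metadata
#' columns plus the 11 features, header row naming the features in
#' canonical order.
#'
#' @param x feature data.frame.
#' @param path CSV file.
#' @return \code{writeFeatureMatrix}: \code{path}, invisibly;
#'   \code{readFeatureMatrix}: data.frame.
#' @export
writeFeatureMatrix <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.FEATURES, colnames(x))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x
}
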