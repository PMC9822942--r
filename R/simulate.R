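# Synthetic corpora with planted binding sites. The generator emulates the
# structure of curated plant interaction sets: one planted site per
# positive transcript (plant mRNAs typically carry a single site), a
# minority of non-canonical sites (>= 2 seed mismatches), and cross-species
# miRNA homolog families that exercise the leakage controls.

#' Specification of a synthetic corpus
#'
#' @slot nMirna,nTranscript counts; each transcript carries exactly one
#'   planted site for one miRNA (miRNAs are recycled over transcripts).
#' @slot mirnaLenRange mature miRNA length range, nt (default 20-24).
#' @slot transcriptLenRange transcript length range, nt (default 150-300,
#'   a desk-scale stand-in for a site-bearing mRNA region).
#' @slot siteMismatchRate per-position mutation rate of the planted site
#'   relative to the perfect reverse complement (default 0.05).
#' @slot noncanonicalFraction fraction of planted sites forced to carry
#'   >= 2 mismatches in the positions pairing the miRNA seed (2-8);
#'   plant-style corpora only (default 0.10).
#' @slot homologFraction fraction of miRNAs that are cross-species homolog
#'   copies at 80-95\% identity (default 0.20).
#' @slot speciesLabels species codes cycled over miRNAs.
#' @slot background \code{"uniform"} (i.i.d. ACGU) or \code{"au_rich"}
#'   (A/U at 0.35 each, mimicking AU-rich 3' UTRs).
#' @slot siteStyle \code{"plant"} (near-full complementarity along the
#'   miRNA) or \code{"animal"} (complementarity only opposite miRNA
#'   positions 1-9, the canonical-seed regime).
#' @slot seed RNG seed; the corpus is fully reproducible from it.
#' @export
setClass("CorpusSpec", representation(
  nMirna = "integer", nTranscript = "integer",
  mirnaLenRange = "integer", transcriptLenRange = "integer",
  siteMismatchRate = "numeric", noncanonicalFraction = "numeric",
  homologFraction = "numeric", speciesLabels = "character",
  background = "character", siteStyle = "character", seed = "integer"
))

setValidity("CorpusSpec", function(object) {
  msg <- character()
  frac <- c(object@siteMismatchRate, object@noncanonicalFraction,
            object@homologFraction)
  if (any(frac < 0 | frac > 1)) msg <- c(msg, "fractions must be in [0,1]")
  if (any(c(object@mirnaLenRange, object@transcriptLenRange) <= 0))
    msg <- c(msg, "lengths must be positive")
  if (object@transcriptLenRange[1] < object@mirnaLenRange[2])
    msg <- c(msg, "shortest transcript must fit the longest miRNA site")
  if (!object@background %in% c("uniform", "au_rich"))
    msg <- c(msg, "background must be 'uniform' or 'au_rich'")
  if (!object@siteStyle %in% c("plant", "animal"))
    msg <- c(msg, "siteStyle must be 'plant' or 'animal'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorpusSpec", function(object) {
  cat(sprintf(
    "CorpusSpec: %d miRNAs x %d transcripts, %s sites on %s background, seed %d\n",
    object@nMirna, object@nTranscript, object@siteStyle, object@background,
    object@seed))
})

#' @rdname CorpusSpec-class
#' @param nMirna,nTranscript,mirnaLenRange,transcriptLenRange see slots.
#' @param siteMismatchRate,noncanonicalFraction,homologFraction see slots.
#' @param speciesLabels,background,siteStyle,seed see slots.
#' @return A \linkS4class{CorpusSpec}.
#' @export
corpusSpec <- function(nMirna = 60L, nTranscript = 300L,
                       mirnaLenRange = c(20L, 24L),
                       transcriptLenRange = c(150L, 300L),
                       siteMismatchRate = 0.05,
                       noncanonicalFraction = 0.10,
                       homologFraction = 0.20,
                       speciesLabels = c("gma", "osa"),
                       background = "uniform", siteStyle = "plant",
                       seed = 42L) {
  new("CorpusSpec", nMirna = as.integer(nMirna),
      nTranscript = as.integer(nTranscript),
      mirnaLenRange = as.integer(mirnaLenRange),
      transcriptLenRange = as.integer(transcriptLenRange),
      siteMismatchRate = siteMismatchRate,
      noncanonicalFraction = noncanonicalFraction,
      homologFraction = homologFraction,
      speciesLabels = speciesLabels, background = background,
      siteStyle = siteStyle, seed = as.integer(seed))
}

.randomSeq <- function(n, background = "uniform") {
  probs <- if (background == "au_rich") c(A = 0.35, C = 0.15, G = 0.15,
                                          U = 0.35)
           else c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# Substitute the bases at `at` with uniformly chosen different bases.
.mutate <- function(seq, at) {
  if (length(at) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (i in at) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "U"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic corpus with planted binding sites
#'
#' Draws miRNAs (with planted cross-species homolog families), background
#' transcripts, and plants exactly one target site per transcript at
#' recorded coordinates: the mutated reverse complement of the miRNA
#' (plant style), or a sequence complementary only opposite miRNA
#' positions 1-9 (animal style). Non-canonical plant sites carry two
#' forced mismatches in the seed-pairing positions. Fully reproducible
#' from the spec's seed.
#'
#' @param spec A \linkS4class{CorpusSpec}.
#' @return List with \code{mirnas} and \code{transcripts}
#'   (\link[Biostrings]{RNAStringSet} with a \code{species} metadata
#'   column) and \code{positives} (interaction data.frame with
#'   \code{species} and \code{noncanonical} columns).
#' @export
generateCorpus <- function(spec) {
  methods::validObject(spec)
  set.seed(spec@seed)
  nm <- spec@nMirna
  nHom <- round(spec@homologFraction * nm)
  nInd <- nm - nHom
  ids <- sprintf("mir%03d", seq_len(nm))
  species <- rep_len(spec@speciesLabels, nm)

  lens <- sample(seq(spec@mirnaLenRange[1], spec@mirnaLenRange[2]),
                 nm, replace = TRUE)
  seqs <- character(nm)
  hom_of <- rep(NA_character_, nm)
  for (i in seq_len(nInd)) seqs[i] <- .randomSeq(lens[i])
  for (i in seq_len(nHom)) {
    j <- nInd + i
    src <- sample(seq_len(nInd), 1)
    target <- stats::runif(1, 0.80, 0.95)
    L <- nchar(seqs[src])
    seqs[j] <- .mutate(seqs[src], sample(L, round((1 - target) * L)))
    lens[j] <- L
    hom_of[j] <- ids[src]
    if (length(spec@speciesLabels) > 1) {
      species[j] <- sample(setdiff(spec@speciesLabels, species[src]), 1)
    }
  }
  mirnas <- Biostrings::RNAStringSet(stats::setNames(seqs, ids))
  S4Vectors::mcols(mirnas)$species <- species
  S4Vectors::mcols(mirnas)$homolog_of <- hom_of

  nt <- spec@nTranscript
  tids <- sprintf("tx%04d", seq_len(nt))
  mirFor <- rep_len(seq_len(nm), nt)
  tseqs <- character(nt)
  pos <- data.frame(mirna_id = ids[mirFor], transcript_id = tids,
                    site_start = 0L, site_end = 0L, label = "positive",
                    species = species[mirFor],
                    noncanonical = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nt)) {
    m <- seqs[mirFor[i]]
    L <- nchar(m)
    tlen <- sample(seq(spec@transcriptLenRange[1],
                       spec@transcriptLenRange[2]), 1)
    site <- .revComp(m)
    if (spec@siteStyle == "animal") {
      # complementarity only opposite miRNA positions 1-9 (canonical seed)
      bg <- .randomSeq(L, spec@background)
      site <- paste0(substring(bg, 1, L - 9), substring(site, L - 8, L))
      mut <- which(stats::runif(L - 9) < spec@siteMismatchRate)
      site <- .mutate(site, mut)  # background-region churn only
    } else {
      noncanon <- stats::runif(1) < spec@noncanonicalFraction
      mut <- which(stats::runif(L) < spec@siteMismatchRate)
      if (noncanon) {
        # site position j pairs miRNA position L - j + 1; seed = miRNA 2-8
        seedSitePos <- L - (2:8) + 1
        seedSitePos <- seedSitePos[seedSitePos >= 1]
        mut <- union(mut, sample(seedSitePos, 2))
        pos$noncanonical[i] <- TRUE
      }
      site <- .mutate(site, mut)
    }
    at <- sample(tlen - nchar(site) + 1, 1)
    bg <- .randomSeq(tlen, spec@background)
    tseqs[i] <- paste0(substring(bg, 1, at - 1), site,
                       substring(bg, at + nchar(site), tlen))
    pos$site_start[i] <- at
    pos$site_end[i] <- at + nchar(site) - 1L
  }
  transcripts <- Biostrings::RNAStringSet(stats::setNames(tseqs, tids))
  S4Vectors::mcols(transcripts)$species <- species[mirFor]

  list(mirnas = mirnas, transcripts = transcripts, positives = pos)
}

#' Turn a corpus into labeled, featurized examples
#'
#' Wires the corpus through the negative generator and the feature
#' extractor: one positive per planted site, at most one matched negative
#' per positive, all 11 features computed with batched thermodynamics.
#'
#' @param corpus output of \code{\link{generateCorpus}}.
#' @param tol CG tolerance ladder for negatives.
#' @param params \linkS4class{ScanParams} for the per-site alignment.
#' @param flank,context feature windows, see \code{\link{extractFeatures}}.
#' @return Labeled feature data.frame (metadata + 11 features), positives
#'   first.
#' @export
corpusToExamples <- function(corpus, tol = c(0.05, 0.10, 0.20),
                             params = scanParams(), flank = 10,
                             context = 70) {
  cols <- c("mirna_id", "transcript_id", "site_start", "site_end", "label")
  neg <- buildNegativeSet(corpus$positives, corpus$mirnas,
                          corpus$transcripts, tol)
  sites <- rbind(corpus$positives[, cols], neg[, cols])
  sp <- S4Vectors::mcols(corpus$mirnas)$species
  names(sp) <- names(corpus$mirnas)
  sites$species <- unname(sp[sites$mirna_id])
  sites$noncanonical <- c(corpus$positives$noncanonical,
                          rep(NA, nrow(neg)))
  featureMatrix(sites, corpus$mirnas, corpus$transcripts, params,
                flank, context)
}
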