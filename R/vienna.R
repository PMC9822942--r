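# Thermodynamics via the ViennaRNA command-line tools. RNAduplex gives the
# intermolecular nearest-neighbor MFE (no intramolecular structure, which is
# exactly the per-duplex "folding energy" feature); RNAplfold gives
# equilibrium unpaired probabilities for site accessibility.

.viennaCheck <- function(tool) {
  if (Sys.which(tool) == "")
    stop("ViennaRNA tool '", tool, "' not found on PATH", call. = FALSE)
}

#' Hybridization free energy of miRNA:site duplexes
#'
#' Minimum free energy of intermolecular hybridization under the
#' nearest-neighbor model (ViennaRNA \command{RNAduplex}), with no
#' intramolecular structure. Energies are clamped at 0: a value of 0 means
#' no stable duplex can form (including sequence pairs with no
#' complementarity at all). Vectorized over pairs; a single tool invocation
#' is used for the whole batch.
#'
#' @param mirnaSeq,siteSeq character vectors of RNA sequences (recycled to
#'   a common length).
#' @return Numeric vector of energies in kcal/mol, all <= 0.
#' @examples
#' \dontrun{
#' duplexEnergy("GGGGG", "CCCCC") < duplexEnergy("AAAAA", "UUUUU")
#' }
#' @export
duplexEnergy <- function(mirnaSeq, siteSeq) {
  n <- max(length(mirnaSeq), length(siteSeq))
  a <- .normalizeRna(rep_len(as.character(mirnaSeq), n), "miRNA sequence")
  b <- .normalizeRna(rep_len(as.character(siteSeq), n), "site sequence")
  if (n == 0) return(numeric(0))
  .viennaCheck("RNAduplex")
  inp <- paste0(as.vector(rbind(a, b)), collapse = "\n")
  out <- system2("RNAduplex", stdout = TRUE, stderr = FALSE, input = inp)
  out <- out[grepl("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out)]
  if (length(out) != n)
    stop("RNAduplex returned ", length(out), " results for ", n, " pairs")
  e <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", out))
  # 100000.00 is RNAduplex's sentinel for "no duplex possible"
  e[e >= 99999] <- 0
  pmin(e, 0)
}

# Mean unpaired probability over [siteStart, siteEnd] of each context
# sequence, from RNAplfold base-pair probabilities (-u 1, window spanning
# the full context). One tool invocation per batch; runs in a temp dir
# because RNAplfold writes per-record output files.
.accessibilityBatch <- function(contextSeqs, siteStarts, siteEnds,
                                foldWindow = 80L, maxPairSpan = 40L) {
  n <- length(contextSeqs)
  if (n == 0) return(numeric(0))
  .viennaCheck("RNAplfold")
  ids <- paste0("q", seq_len(n))
  fa <- paste0(">", ids, "\n", contextSeqs, collapse = "\n")
  dir <- tempfile("plfold")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE)
  status <- system2("RNAplfold",
                    c("-u", "1", "-W", foldWindow, "-L", maxPairSpan),
                    input = fa, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("RNAplfold failed (exit ", status, ")")
  vapply(seq_len(n), function(i) {
    tab <- utils::read.table(paste0(ids[i], "_lunp"), comment.char = "#")
    mean(tab[siteStarts[i]:siteEnds[i], 2])
  }, numeric(1))
}

#' Accessibility of a target site
#'
#' Probability that site positions are unpaired in the equilibrium ensemble
#' of the local transcript context: the site plus \code{context} nt on each
#' side (clipped at transcript ends) is folded intramolecularly with
#' RNAplfold's local model (folding window \code{foldWindow}, maximum pair
#' span \code{maxPairSpan} — the standard mRNA accessibility setting) and
#' the per-position unpaired probabilities over the site are averaged. By
#' construction the value does not depend on sequence beyond the context
#' window.
#'
#' @param transcriptSeq RNA sequence (character).
#' @param siteStart,siteEnd 1-based inclusive site coordinates.
#' @param context nt of flanking sequence folded on each side (default 70).
#' @param foldWindow,maxPairSpan RNAplfold local-folding window and maximum
#'   base-pair span, nt (defaults 80 and 40).
#' @return Mean unpaired probability in \[0, 1\].
#' @export
accessibility <- function(transcriptSeq, siteStart, siteEnd, context = 70,
                          foldWindow = 80L, maxPairSpan = 40L) {
  seq <- .normalizeRna(as.character(transcriptSeq), "transcript")
  n <- nchar(seq)
  stopifnot(siteStart >= 1, siteEnd >= siteStart, siteEnd <= n)
  lo <- max(1, siteStart - context)
  hi <- min(n, siteEnd + context)
  .accessibilityBatch(substring(seq, lo, hi),
                      siteStart - lo + 1, siteEnd - lo + 1,
                      foldWindow, maxPairSpan)
}
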