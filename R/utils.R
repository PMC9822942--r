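# Internal helpers: sequence normalization and label handling.

# Canonical order of the 11 duplex features. Every feature matrix, trained
# model and serialized CSV uses exactly this order.
.FEATURES <- c(
  "folding_energy", "seed_match", "accessibility", "au_content", "me_motif",
  "n_paired", "site_length", "longest_run", "longest_run_pos",
  "n_paired_3p", "seed_minus_3p"
)

#' Names of the eleven duplex features, in canonical order
#'
#' @return Character vector of length 11.
#' @examples
#' targetFeatureNames()
#' @export
targetFeatureNames <- function() .FEATURES

# Uppercase, DNA->RNA (T->U); errors on residual non-ACGU characters.
# `what` names the offending record in the error.
.normalizeRna <- function(seq, what = "sequence") {
  nm <- names(seq)
  seq <- chartr("t", "u", chartr("T", "U", toupper(as.character(seq))))
  names(seq) <- nm
  bad <- grepl("[^ACGU]", seq)
  if (any(bad)) {
    offender <- if (!is.null(names(seq))) names(seq)[bad][1] else which(bad)[1]
    stop(sprintf("%s '%s' contains non-ACGU characters after normalization",
                 what, offender), call. = FALSE)
  }
  if (any(!nzchar(seq))) stop(sprintf("empty %s", what), call. = FALSE)
  seq
}

.revComp <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Accepts "positive"/"negative", logical, or 0/1; returns logical (TRUE = positive).
.asPositive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("positive", "negative")))
    stop("labels must be 'positive'/'negative', logical, or 0/1")
  labels == "positive"
}

# Seq accessor tolerant of RNAStringSet / named character.
.seqChar <- function(x) {
  out <- as.character(x)
  names(out) <- names(x)  # as.character() drops names on character input
  out
}

.speciesOf <- function(x) {
  if (methods::is(x, "XStringSet")) {
    mc <- S4Vectors::mcols(x)
    if (!is.null(mc) && "species" %in% colnames(mc))
      return(as.character(mc$species))
  }
  rep(NA_character_, length(x))
}
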