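#' Read RNA sequences from FASTA
#'
#' Reads a multi-record FASTA file, takes the first whitespace-delimited
#' token of each header as the id, uppercases, converts DNA T to RNA U, and
#' rejects records still containing non-ACGU characters (pairing and energy
#' are undefined on ambiguity codes). Record order is preserved.
#'
#' @param path FASTA file.
#' @param species optional species code stored in \code{mcols(x)$species}
#'   (single value, recycled).
#' @param lengthWarnRange optional \code{c(lo, hi)}; a warning (not an
#'   error) is issued for records outside it.
#' @return An \link[Biostrings]{RNAStringSet} named by record id, with a
#'   \code{species} metadata column.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">m1 some description", "acgu"), fa)
#' readRnaFasta(fa, species = "ath")
#' @export
readRnaFasta <- function(path, species = NA_character_,
                         lengthWarnRange = NULL) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("no records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate id '", dup[1], "' in ", path, call. = FALSE)
  seqs <- .normalizeRna(stats::setNames(as.character(raw), ids), "record")
  if (!is.null(lengthWarnRange)) {
    out <- nchar(seqs) < lengthWarnRange[1] | nchar(seqs) > lengthWarnRange[2]
    if (any(out))
      warning(sum(out), " record(s) outside the expected length range [",
              lengthWarnRange[1], ", ", lengthWarnRange[2], "], e.g. '",
              ids[out][1], "'", call. = FALSE)
  }
  x <- Biostrings::RNAStringSet(seqs)
  S4Vectors::mcols(x)$species <- rep(as.character(species), length(x))
  x
}

#' @rdname readRnaFasta
#' @details \code{readMirnaFasta} is \code{readRnaFasta} with a length
#'   warning outside \[16, 30\] nt (mature plant miRNAs are typically 20-24
#'   nt; outliers are loaded but flagged).
#' @export
readMirnaFasta <- function(path, species = NA_character_) {
  readRnaFasta(path, species = species, lengthWarnRange = c(16L, 30L))
}

#' Write RNA sequences to FASTA
#'
#' @param x An \link[Biostrings]{RNAStringSet} or named character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRnaFasta <- function(x, path) {
  if (!methods::is(x, "XStringSet")) x <- Biostrings::RNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a labeled interaction table
#'
#' Reads a TSV with header columns \code{mirna_id}, \code{transcript_id},
#' \code{site_start}, \code{site_end}, \code{label} (TarDB/CLASH-style
#' export, 1-based inclusive coordinates). Records whose ids do not resolve
#' against the supplied sequence sets are skipped with a message (source
#' databases routinely list mRNAs that can no longer be retrieved);
#' malformed coordinates are an error naming the offending line.
#'
#' @param path TSV file.
#' @param mirnas,transcripts RNAStringSet or named character vectors the
#'   ids must resolve against.
#' @return data.frame of interaction records, with attribute
#'   \code{"skipped"} giving the number of unresolvable records.
#' @export
readInteractions <- function(path, mirnas, transcripts) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "transcript_id", "site_start", "site_end", "label")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  mseq <- .seqChar(mirnas)
  tseq <- .seqChar(transcripts)
  # data lines are 1 header line down from the data.frame row index
  lineno <- seq_len(nrow(tab)) + 1L

  resolvable <- tab$mirna_id %in% names(mseq) &
    tab$transcript_id %in% names(tseq)
  skipped <- sum(!resolvable)
  if (skipped > 0)
    message(skipped, " interaction record(s) skipped: unresolvable ids")
  tab <- tab[resolvable, , drop = FALSE]
  lineno <- lineno[resolvable]

  s <- suppressWarnings(as.integer(tab$site_start))
  e <- suppressWarnings(as.integer(tab$site_end))
  tlen <- nchar(tseq)[tab$transcript_id]
  bad <- is.na(s) | is.na(e) | s < 1 | e < s | e > tlen
  if (any(bad))
    stop("malformed coordinates at line ", lineno[bad][1], " of ", path,
         call. = FALSE)
  if (!all(tab$label %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'", call. = FALSE)

  out <- data.frame(
    mirna_id = tab$mirna_id, transcript_id = tab$transcript_id,
    site_start = s, site_end = e, label = tab$label,
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- skipped
  out
}

#' Write an interaction table
#'
#' @param records interaction data.frame as returned by
#'   \code{\link{readInteractions}}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeInteractions <- function(records, path) {
  cols <- c("mirna_id", "transcript_id", "site_start", "site_end", "label")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a prediction report
#'
#' CSV with one row per scored site: ids, the seed location (the 5'-most
#' position of the longest consecutive pairing run) on the miRNA and on the
#' mRNA, the corresponding seed sequences, the site interval and the forest
#' confidence (4 decimals). An empty prediction set writes the header only.
#'
#' @param rows data.frame with columns \code{mirna_id}, \code{transcript_id},
#'   \code{mirna_seed_index}, \code{mrna_seed_index}, \code{mirna_seed_seq},
#'   \code{mrna_seed_seq}, \code{site_start}, \code{site_end},
#'   \code{confidence}.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(rows, path) {
  cols <- c("mirna_id", "transcript_id", "mirna_seed_index",
            "mrna_seed_index", "mirna_seed_seq", "mrna_seed_seq",
            "site_start", "site_end", "confidence")
  if (nrow(rows) == 0) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  miss <- setdiff(cols, colnames(rows))
  if (length(miss))
    stop("missing prediction column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- rows[, cols]
  out$confidence <- sprintf("%.4f", as.numeric(rows$confidence))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
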