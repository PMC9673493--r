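#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`, so downstream
#' code can assume the alphabet `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet]. Names are the first
#'   whitespace-delimited token of each header; full headers are kept in
#'   the `description` metadata column.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1])
  seqs <- chartr("u", "t", tolower(as.character(raw)))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id: ", ids[nchar(seqs) == 0L][1])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- sub("^\\S+\\s*", "", headers)
  out
}

#' Write DNA sequences to a FASTA file
#'
#' @param records Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param line_width Sequence line wrap width in bases.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  if (length(records) == 0L) stop("refusing to write an empty FASTA")
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  if (is.null(names(records))) stop("records must be named")
  Biostrings::writeXStringSet(records, filepath = path, width = line_width)
  invisible(path)
}

#' Read a FASTQ file of reads with Phred+33 qualities
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
}

#' Write reads and qualities to a FASTQ file
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0L) stop("refusing to write an empty FASTQ")
  Biostrings::writeQualityScaledXStringSet(reads, filepath = path)
  invisible(path)
}

#' Per-read accuracy from base qualities
#'
#' Accuracy of a read is `1 - mean(10^(-Q/10))` over its bases, i.e. one
#' minus the mean per-base error probability — the quantity HiFi "read
#' accuracy" refers to (not the mean of Q itself).
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @return Numeric vector of accuracies in `[0, 1]`.
#' @export
read_accuracy <- function(reads) {
  if (!methods::is(reads, "QualityScaledXStringSet")) {
    stop("reads must carry qualities (QualityScaledDNAStringSet)")
  }
  qs <- methods::as(Biostrings::quality(reads), "IntegerList")
  vapply(qs, function(q) 1 - mean(10^(-q / 10)), numeric(1))
}

#' Filter HiFi reads on length and accuracy
#'
#' Keeps reads strictly longer than `min_length_bp` with accuracy strictly
#' above `min_accuracy` (defaults: over 2 kb and over 99%).
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param min_length_bp Length threshold in bp (strict `>`).
#' @param min_accuracy Accuracy threshold as a fraction (strict `>`).
#' @return A list with `reads` (the kept subset) and `summary`, a one-row
#'   data.frame of kept/removed read and base counts.
#' @export
filter_reads <- function(reads, min_length_bp = 2000, min_accuracy = 0.99) {
  if (!methods::is(reads, "QualityScaledXStringSet")) {
    stop("reads must carry qualities (QualityScaledDNAStringSet)")
  }
  len <- Biostrings::width(reads)
  acc <- read_accuracy(reads)
  keep <- len > min_length_bp & acc > min_accuracy
  summary <- data.frame(
    n_input = length(reads),
    n_kept = sum(keep),
    n_removed = sum(!keep),
    bases_input = sum(as.numeric(len)),
    bases_kept = sum(as.numeric(len[keep])),
    bases_removed = sum(as.numeric(len[!keep]))
  )
  list(reads = reads[keep], summary = summary)
}
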