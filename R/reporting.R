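# Run-level statistics and the percentage arithmetic used in reporting.

#' Aggregate per-group sequencing-run statistics into a totals row
#'
#' Read and base counts are exact integer sums of the per-group values.
#' N50 is computed only when raw pooled read lengths are supplied (it is
#' not additive, so it is never derived from per-group N50s); the same
#' holds for the median quality.
#'
#' @param per_group_stats data.frame with columns `n_reads`, `n_bases`
#'   (one row per group, e.g. per gut compartment).
#' @param read_lengths Optional numeric vector of pooled raw read lengths.
#' @param read_qualities Optional numeric vector of pooled per-read
#'   median Phred qualities.
#' @return One-row data.frame: `label`, `n_reads`, `n_bases`, `n50_bp`,
#'   `median_q` (the last two NA unless raw values were given).
#' @export
aggregate_run_stats <- function(per_group_stats, read_lengths = NULL,
                                read_qualities = NULL) {
  if (nrow(per_group_stats) == 0L) stop("need at least one group")
  if (any(per_group_stats$n_reads < 0) || any(per_group_stats$n_bases < 0)) {
    stop("negative counts")
  }
  n50 <- if (!is.null(read_lengths)) n50_length(read_lengths) else NA_real_
  data.frame(
    label = "All",
    n_reads = sum(as.numeric(per_group_stats$n_reads)),
    n_bases = sum(as.numeric(per_group_stats$n_bases)),
    n50_bp = n50,
    median_q = if (!is.null(read_qualities)) median(read_qualities)
               else NA_real_)
}

#' N50 of a set of lengths
#'
#' The length at which, walking lengths in descending order, the
#' cumulative sum first reaches half of the total.
#'
#' @param lengths Numeric vector of read/contig lengths.
#' @return The N50 length.
#' @export
n50_length <- function(lengths) {
  if (length(lengths) == 0L) stop("no lengths")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Count/percentage composition summary of classification labels
#'
#' @param labels Character vector, one classification label per genome.
#' @return data.frame `label`, `count`, `percent` (1 decimal, descending
#'   count then label).
#' @export
composition_summary <- function(labels) {
  if (length(labels) == 0L) stop("no labels")
  tab <- table(labels)
  out <- data.frame(label = names(tab), count = as.integer(tab))
  out$percent <- percent_round(out$count, length(labels), 1L)
  out <- out[order(-out$count, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rounded percentage with round-half-up semantics
#'
#' `round-half-up(100 * numerator / denominator)` at the requested number
#' of decimals. Round-half-up (not banker's rounding) is the convention
#' of reported ratios like "246 (53%)".
#'
#' @param numerator,denominator Counts (vectorised; denominator > 0).
#' @param decimals Decimal places (default 0).
#' @return Numeric percentage(s).
#' @export
percent_round <- function(numerator, denominator, decimals = 0L) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  x <- 100 * numerator / denominator
  scale <- 10^decimals
  floor(x * scale + 0.5) / scale
}
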