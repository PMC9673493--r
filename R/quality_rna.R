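# MIMAG-style quality ranking and the RNA-completeness criterion.

#' CheckM quality score
#'
#' `completeness - 5 * contamination`, the scalar used to rank genome
#' assemblies within a dereplication cluster.
#'
#' @param completeness Percent in \[0, 100\].
#' @param contamination Percent >= 0.
#' @return Numeric score (vectorised).
#' @export
checkm_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100)) {
    stop("completeness must lie in [0, 100]")
  }
  if (any(contamination < 0)) stop("contamination must be >= 0")
  completeness - 5 * contamination
}

#' Quality rank of genome assemblies
#'
#' Ranks: `near_complete` (completeness >= 90, contamination < 5),
#' `high_quality` (>= 70, < 10), `medium_quality` (>= 50, < 10), else
#' `fail`. Completeness bounds are inclusive, contamination bounds strict
#' by default; `contamination_inclusive = TRUE` switches the
#' contamination comparisons to `<=` (both conventions circulate for
#' these tiers).
#'
#' @param metadata Metadata data.frame with `completeness` and
#'   `contamination` (and `genome_id`).
#' @param contamination_inclusive Use `<=` instead of `<` on contamination.
#' @return data.frame `genome_id`, `score`, `rank`.
#' @export
quality_rank <- function(metadata, contamination_inclusive = FALSE) {
  md <- metadata
  lt <- if (contamination_inclusive) `<=` else `<`
  rank <- ifelse(md$completeness >= 90 & lt(md$contamination, 5),
                 "near_complete",
          ifelse(md$completeness >= 70 & lt(md$contamination, 10),
                 "high_quality",
          ifelse(md$completeness >= 50 & lt(md$contamination, 10),
                 "medium_quality", "fail")))
  data.frame(genome_id = md$genome_id,
             score = checkm_score(md$completeness, md$contamination),
             rank = rank)
}

#' Find full-length rRNA operons in a set of annotations
#'
#' rRNA features are chained into maximal same-contig, same-strand runs
#' with inter-feature gaps <= `max_gap_bp`; a chain is an operon call iff
#' it contains at least one full-length copy of each of the 5S, 16S and
#' 23S genes.
#'
#' @param annotations Annotation data.frame (see [read_annotations()]).
#' @param max_gap_bp Maximum gap between consecutive rRNA genes in a
#'   chain (default 5000; typical bacterial operons span ~5–7 kb total).
#' @return data.frame with one row per operon: `contig_id`, `strand`,
#'   `start`, `end`, `span_bp`, `n_features`.
#' @export
find_rrna_operons <- function(annotations, max_gap_bp = 5000) {
  ann <- validate_annotations(annotations)
  rr <- ann[grepl("^rRNA_", ann$feature_type), , drop = FALSE]
  if (nrow(rr) == 0L) {
    return(data.frame(contig_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      span_bp = integer(), n_features = integer()))
  }
  out <- list()
  for (key in unique(paste(rr$contig_id, rr$strand))) {
    grp <- rr[paste(rr$contig_id, rr$strand) == key, , drop = FALSE]
    grp <- grp[order(grp$start), , drop = FALSE]
    gap <- grp$start[-1] - grp$end[-nrow(grp)]
    chain <- cumsum(c(0L, as.integer(gap > max_gap_bp)))
    for (ch in unique(chain)) {
      sub <- grp[chain == ch, , drop = FALSE]
      full <- sub$feature_type[sub$full_length]
      if (all(c("rRNA_5S", "rRNA_16S", "rRNA_23S") %in% full)) {
        out[[length(out) + 1L]] <- data.frame(
          contig_id = sub$contig_id[1], strand = sub$strand[1],
          start = min(sub$start), end = max(sub$end),
          span_bp = max(sub$end) - min(sub$start) + 1L,
          n_features = nrow(sub))
      }
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(contig_id = character(), strand = character(),
               start = integer(), end = integer(), span_bp = integer(),
               n_features = integer())
  rownames(res) <- NULL
  res
}

#' RNA-completeness of a genome's annotations
#'
#' A genome is "RNA complete" when it has at least one full-length rRNA
#' operon encoding all three rRNA types (5S, 16S, 23S) AND at least
#' `min_trna` full-length tRNA genes — by default 18 total copies
#' (`trna_mode = "copies"`); `"distinct_isotypes"` instead counts
#' distinct amino-acid isotypes, the MIMAG-flavoured variant.
#'
#' @param annotations Annotation data.frame for one genome.
#' @param min_trna tRNA threshold (default 18).
#' @param trna_mode `"copies"` or `"distinct_isotypes"`.
#' @param max_gap_bp Passed to [find_rrna_operons()].
#' @return List: `rna_complete` (logical), `operon_count`, `trna_count`,
#'   `operon_ok`, `trna_ok`.
#' @export
rna_complete <- function(annotations, min_trna = 18L,
                         trna_mode = c("copies", "distinct_isotypes"),
                         max_gap_bp = 5000) {
  trna_mode <- match.arg(trna_mode)
  ann <- validate_annotations(annotations)
  operons <- find_rrna_operons(ann, max_gap_bp)
  tr <- ann[ann$feature_type == "tRNA" & ann$full_length, , drop = FALSE]
  trna_count <- if (trna_mode == "copies") nrow(tr)
                else length(unique(tr$isotype[!is.na(tr$isotype)]))
  operon_ok <- nrow(operons) >= 1L
  trna_ok <- trna_count >= min_trna
  list(rna_complete = operon_ok && trna_ok,
       operon_count = nrow(operons), trna_count = trna_count,
       operon_ok = operon_ok, trna_ok = trna_ok)
}
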