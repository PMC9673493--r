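# Novelty calling against reference genome sets (by ANI) and reference
# 16S sets (by alignment identity).

#' Call genome novelty against a reference set by ANI
#'
#' For each query, `best_ani` is the maximum symmetrised ANI over the
#' references (minimum of the two directional estimates, as in
#' dereplication). A query matches a reference strain when its best ANI
#' is strictly above `strain_threshold` (99 by default) and a species
#' when strictly above `species_threshold` (95); otherwise it is called
#' a novel strain / novel species. Queries with no mapped reference are
#' novel at both levels.
#'
#' @param query_genomes,reference_genomes Named DNAStringSets.
#' @param strain_threshold,species_threshold Percent ANI thresholds
#'   (strict `>` for a match).
#' @param ... Passed to [estimate_ani()].
#' @return data.frame: `genome_id`, `best_reference_id`, `best_ani`,
#'   `novel_strain`, `novel_species`.
#' @export
genome_novelty <- function(query_genomes, reference_genomes,
                           strain_threshold = 99, species_threshold = 95,
                           ...) {
  qids <- names(query_genomes)
  if (length(reference_genomes) == 0L) {
    warning("empty reference set: all queries called novel")
    return(data.frame(genome_id = qids, best_reference_id = NA_character_,
                      best_ani = NA_real_, novel_strain = TRUE,
                      novel_species = TRUE))
  }
  rows <- lapply(qids, function(qi) {
    best <- NA_real_; best_ref <- NA_character_
    for (ri in names(reference_genomes)) {
      fwd <- estimate_ani(query_genomes[qi], reference_genomes[ri], ...)$ani
      rev <- estimate_ani(reference_genomes[ri], query_genomes[qi], ...)$ani
      vals <- c(fwd, rev)
      vals <- vals[!is.na(vals)]
      sym <- if (length(vals)) min(vals) else NA_real_
      if (!is.na(sym) && (is.na(best) || sym > best)) {
        best <- sym; best_ref <- ri
      }
    }
    data.frame(genome_id = qi, best_reference_id = best_ref,
               best_ani = best,
               novel_strain = !(isTRUE(best > strain_threshold)),
               novel_species = !(isTRUE(best > species_threshold)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best 16S identity of a query against a reference 16S set
#'
#' Best local alignment identity (matches / alignment columns) under
#' match +1, mismatch −1, gap opening −2, gap extension −1. Alignments
#' shorter than 100 columns are discarded; with no surviving alignment
#' the identity is undefined (`NA`).
#'
#' @param query_16s Single 16S sequence (character / DNAString /
#'   length-1 DNAStringSet).
#' @param reference_16s_set Named DNAStringSet of reference 16S genes.
#' @param min_alignment_columns Minimum alignment length (default 100).
#' @return List: `best_identity` (percent or NA), `best_reference_id`.
#' @export
best_16s_identity <- function(query_16s, reference_16s_set,
                              min_alignment_columns = 100L) {
  q <- toupper(as.character(query_16s)[1])
  if (is.na(q) || nchar(q) == 0L) stop("empty 16S query")
  best <- NA_real_; best_ref <- NA_character_
  for (ri in names(reference_16s_set)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = q, subject = toupper(as.character(reference_16s_set[[ri]])),
      type = "local", substitutionMatrix = dna_score_matrix(1, -1),
      gapOpening = 2, gapExtension = 1)
    if (Biostrings::nchar(aln) < min_alignment_columns) next
    idy <- Biostrings::pid(aln, type = "PID1")
    if (is.na(best) || idy > best) { best <- idy; best_ref <- ri }
  }
  list(best_identity = best, best_reference_id = best_ref)
}

#' 16S-based taxon novelty call
#'
#' Identity strictly below 95% (or undefined) indicates a novel genus,
#' between 95% and strictly below 97% a novel species, and at or above
#' 97% a known species — the conventional 16S demarcation thresholds.
#'
#' @param best_identity Percent identity in \[0, 100\], or NA.
#' @return One of `"novel_genus"`, `"novel_species"`, `"known_species"`.
#' @export
taxon_novelty_16s <- function(best_identity) {
  vapply(best_identity, function(x) {
    if (is.na(x) || x < 95) "novel_genus"
    else if (x < 97) "novel_species"
    else "known_species"
  }, character(1))
}
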