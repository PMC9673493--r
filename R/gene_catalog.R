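# Nonredundant gene catalogs: CD-HIT-EST-style greedy incremental
# clustering (identity > 95% of alignment columns, local alignment
# covering > 90% of the shorter gene) and catalog-vs-catalog overlap at
# the >=95% / >=90% criteria.

# Best local alignment of two genes; returns identity (percent of
# alignment columns) and the fraction of the shorter sequence covered by
# the aligned span.
gene_local_alignment <- function(a, b) {
  shorter_is_a <- nchar(a) <= nchar(b)
  pat <- if (shorter_is_a) a else b
  sub <- if (shorter_is_a) b else a
  aln <- Biostrings::pairwiseAlignment(
    pattern = pat, subject = sub, type = "local",
    substitutionMatrix = dna_score_matrix(1, -1),
    gapOpening = 2, gapExtension = 1)
  span <- Biostrings::nchar(aln) -
    Biostrings::nindel(aln)@insertion[, "WidthSum"]
  list(identity = Biostrings::pid(aln, type = "PID1"),
       coverage_of_shorter = span / nchar(pat))
}

# k-mer word sets for the prefilter
word_set <- function(x, word_size) unique(seq_kmers(x, word_size))

#' Greedy incremental clustering of genes
#'
#' Genes are processed by descending length (ties by id). Each gene is
#' compared against existing cluster representatives that share at least
#' one word of `word_size` bases, in representative creation order, and
#' joins the FIRST representative whose best local alignment reaches
#' `min_identity` (matches / alignment columns) with an aligned span of
#' at least `min_coverage_of_shorter` of the shorter sequence; otherwise
#' it founds a new cluster. This mirrors CD-HIT-EST under
#' `-c 0.95 -n 10 -G 0 -aS 0.9`. `join = "best"` instead joins the
#' qualifying representative with the highest identity.
#'
#' @param genes Named DNAStringSet (or named character vector).
#' @param min_identity Identity threshold as a fraction (default 0.95).
#' @param min_coverage_of_shorter Coverage threshold (default 0.90).
#' @param word_size Prefilter word length (default 10).
#' @param join `"first"` (CD-HIT semantics, default) or `"best"`.
#' @param prefilter Disable to force all-representative comparison
#'   (used for oracle checks).
#' @return List of clusters, each `list(representative, members)`;
#'   the representative is the longest member (founder).
#' @export
greedy_cluster_genes <- function(genes, min_identity = 0.95,
                                 min_coverage_of_shorter = 0.90,
                                 word_size = 10L,
                                 join = c("first", "best"),
                                 prefilter = TRUE) {
  join <- match.arg(join)
  if (length(genes) == 0L) return(list())
  gseq <- as_named_chr(genes)
  assert_dna(gseq, "genes")
  ord <- order(-nchar(gseq), names(gseq))
  gseq <- gseq[ord]
  reps <- character(0)       # representative ids, creation order
  rep_words <- list()
  members <- list()
  for (gid in names(gseq)) {
    s <- gseq[[gid]]
    w <- if (prefilter) word_set(s, word_size) else NULL
    joined <- NA_character_
    best_idy <- -Inf
    for (ri in seq_along(reps)) {
      if (prefilter && !any(w %in% rep_words[[ri]])) next
      hit <- gene_local_alignment(s, gseq[[reps[ri]]])
      ok <- hit$identity >= min_identity * 100 &&
        hit$coverage_of_shorter >= min_coverage_of_shorter
      if (!ok) next
      if (join == "first") { joined <- reps[ri]; break }
      if (hit$identity > best_idy) { best_idy <- hit$identity
                                     joined <- reps[ri] }
    }
    if (is.na(joined)) {
      reps <- c(reps, gid)
      if (prefilter) rep_words[[length(reps)]] <- w
      members[[gid]] <- gid
    } else {
      members[[joined]] <- c(members[[joined]], gid)
    }
  }
  lapply(reps, function(r) list(representative = r,
                                members = members[[r]]))
}

#' Structure-completeness ratio of a gene set
#'
#' Fraction of genes whose partial flags are `"00"`, i.e. whose predicted
#' open reading frame has both its start and stop edge.
#'
#' @param partial_flags Character vector of 2-digit codes (named by gene
#'   id or not); NA is an error.
#' @return Fraction in \[0, 1\].
#' @export
structure_completeness_ratio <- function(partial_flags) {
  if (length(partial_flags) == 0L) stop("no genes given")
  if (anyNA(partial_flags)) stop("missing partial flags")
  mean(partial_flags == "00")
}

#' Compare two gene catalogs at identity/coverage criteria
#'
#' A gene of catalog A is shared iff ANY gene of catalog B aligns to it
#' with identity >= `min_identity` and aligned span >=
#' `min_coverage_of_shorter` of the shorter sequence (inclusive
#' comparisons); and symmetrically for B.
#'
#' @param catalog_a,catalog_b Named DNAStringSets (or named character).
#' @param min_identity Fraction, default 0.95 (inclusive).
#' @param min_coverage_of_shorter Fraction, default 0.90 (inclusive).
#' @param word_size Prefilter word length (default 10).
#' @return List: `shared_a`, `unique_a`, `shared_b`, `unique_b` (counts),
#'   and `pairs` (data.frame of matched pairs with identity and coverage).
#' @export
compare_catalogs <- function(catalog_a, catalog_b, min_identity = 0.95,
                             min_coverage_of_shorter = 0.90,
                             word_size = 10L) {
  a <- as_named_chr(catalog_a)
  b <- if (length(catalog_b)) as_named_chr(catalog_b) else character(0)
  words_b <- lapply(b, word_set, word_size = word_size)
  shared_a <- logical(length(a)); names(shared_a) <- names(a)
  shared_b <- logical(length(b)); names(shared_b) <- names(b)
  pairs <- list()
  for (ai in names(a)) {
    wa <- word_set(a[[ai]], word_size)
    for (bi in names(b)) {
      if (!any(wa %in% words_b[[bi]])) next
      hit <- gene_local_alignment(a[[ai]], b[[bi]])
      if (hit$identity >= min_identity * 100 &&
          hit$coverage_of_shorter >= min_coverage_of_shorter) {
        shared_a[ai] <- TRUE
        shared_b[bi] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene_a = ai, gene_b = bi, identity = hit$identity,
          coverage_of_shorter = hit$coverage_of_shorter)
      }
    }
  }
  list(shared_a = sum(shared_a), unique_a = sum(!shared_a),
       shared_b = sum(shared_b), unique_b = sum(!shared_b),
       pairs = do.call(rbind, pairs) %||%
         data.frame(gene_a = character(), gene_b = character(),
                    identity = numeric(), coverage_of_shorter = numeric()))
}
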