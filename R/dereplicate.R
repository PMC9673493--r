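# Genome dereplication: directional ANI estimates are symmetrised (min
# of the two directions, conservative), converted to distances by
# (100 - identity)/100, clustered by complete-linkage agglomeration with
# a stop distance (0.01 for strain level / 0.05 for species level), and
# each cluster is reduced to its best representative: circular beats
# noncircular, then larger CheckM score (completeness - 5*contamination),
# then larger assembly, then lexicographic id.

#' Symmetric distance matrix from directional ANI estimates
#'
#' Identity of a pair is the minimum of the two directional ANIs when
#' both are defined, the defined one if only one is, and undefined
#' otherwise; undefined pairs get the maximal distance 1.0 (the pair is
#' below the estimator's detectability floor). Distance is
#' `(100 - identity) / 100`.
#'
#' @param genomes Genome ids (character), or a named DNAStringSet whose
#'   names are used.
#' @param estimates data.frame of directional estimates from
#'   [estimate_ani()] / [estimate_ani_matrix()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
build_distance_matrix <- function(genomes, estimates) {
  ids <- if (is.character(genomes) && is.null(names(genomes))) genomes
         else names(genomes)
  if (is.null(ids)) stop("cannot determine genome ids")
  unknown <- setdiff(unique(c(estimates$query_id, estimates$reference_id)),
                     ids)
  if (length(unknown)) stop("estimate names unknown genome: ", unknown[1])
  n <- length(ids)
  ident <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(estimates))) {
    ident[estimates$query_id[i], estimates$reference_id[i]] <-
      estimates$ani[i]
  }
  d <- matrix(1, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) { d[a, b] <- 0; next }
      vals <- c(ident[a, b], ident[b, a])
      vals <- vals[!is.na(vals)]
      if (length(vals)) d[a, b] <- (100 - min(vals)) / 100
    }
  }
  d
}

#' Complete-linkage agglomerative clustering with a stop distance
#'
#' Repeatedly merges the closest pair of clusters — inter-cluster
#' distance being the maximum pairwise member distance — while that
#' closest distance is strictly below `stop_distance`. Ties are broken by
#' the lexicographically smallest pair of cluster labels (a cluster's
#' label is its smallest member id), making the result reproducible and
#' invariant to input order. With the strict `<`, two genomes at exactly
#' 99.0% ANI (distance 0.01) are NOT merged at the strain level, so
#' retained representatives may share up to 99% ANI.
#'
#' @param d Symmetric distance matrix with dimnames (see
#'   [build_distance_matrix()]).
#' @param stop_distance Merge while the minimum inter-cluster distance is
#'   `< stop_distance`; in (0, 1].
#' @return List of clusters, each a character vector of member ids,
#'   sorted by label; carries `stop_distance` as an attribute.
#' @export
cluster_complete_linkage <- function(d, stop_distance) {
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  if (stop_distance <= 0 || stop_distance > 1) {
    stop("stop_distance must lie in (0, 1]")
  }
  ids <- rownames(d)
  ord <- order(ids)
  d <- d[ord, ord, drop = FALSE]
  ids <- ids[ord]
  clusters <- as.list(ids)
  labels <- ids
  cd <- d  # complete-linkage distances between current clusters
  while (length(clusters) > 1L) {
    off <- cd
    diag(off) <- Inf
    m <- min(off)
    if (!(m < stop_distance)) break
    hits <- which(off == m, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # sort each candidate pair's labels before lexicographic tie-break:
    # cluster positions do not track label order once merges accumulate
    pair_labels <- cbind(pmin(labels[hits[, 1]], labels[hits[, 2]]),
                         pmax(labels[hits[, 1]], labels[hits[, 2]]))
    pick <- order(pair_labels[, 1], pair_labels[, 2])[1]
    i <- hits[pick, 1]; j <- hits[pick, 2]
    # Lance-Williams update for complete linkage: max of the two rows
    newrow <- pmax(cd[i, ], cd[j, ])[-c(i, j)]
    keep <- setdiff(seq_along(clusters), c(i, j))
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    clusters <- c(clusters[keep], list(merged))
    labels <- c(labels[keep], min(merged))
    cd <- rbind(cbind(cd[keep, keep, drop = FALSE], newrow),
                c(newrow, 0))
  }
  o <- order(labels)
  out <- clusters[o]
  attr(out, "stop_distance") <- stop_distance
  out
}

#' Pick the representative genome of a cluster
#'
#' Ordering: circular before noncircular, then larger CheckM score
#' (completeness − 5 × contamination), then larger assembly size, then
#' lexicographically smallest id.
#'
#' @param member_ids Character vector of genome ids.
#' @param metadata Metadata data.frame (see [read_genome_metadata()]).
#' @return The representative genome id.
#' @export
select_representative <- function(member_ids, metadata) {
  miss <- setdiff(member_ids, metadata$genome_id)
  if (length(miss)) stop("no metadata for genome: ", miss[1])
  md <- metadata[match(member_ids, metadata$genome_id), , drop = FALSE]
  score <- checkm_score(md$completeness, md$contamination)
  ord <- order(-as.integer(md$is_circular), -score,
               -as.numeric(md$assembly_size), md$genome_id)
  md$genome_id[ord[1]]
}

#' Dereplicate a genome set at a stop distance
#'
#' Composes all-pairs ANI estimation, distance-matrix construction,
#' complete-linkage clustering and representative selection. Stop
#' distance 0.01 gives the strain-level nonredundant set (retained pairs
#' <= 99% ANI), 0.05 the species-level set (<= 95% ANI); non-representative
#' members are the redundancy that is removed.
#'
#' @param genomes Named DNAStringSet of genome sequences.
#' @param metadata Metadata data.frame covering all genomes.
#' @param stop_distance Clustering stop distance (0.01 strain / 0.05 species).
#' @param estimates Optional precomputed directional estimates
#'   (from [estimate_ani_matrix()]); computed when NULL.
#' @param ... Passed on to [estimate_ani_matrix()].
#' @return List with `clusters` (a data.frame: `genome_id`, `cluster_id`,
#'   `representative`, `is_representative`), `representatives` (ids) and
#'   `distance` (the matrix used).
#' @export
dereplicate <- function(genomes, metadata, stop_distance,
                        estimates = NULL, ...) {
  ids <- names(genomes)
  if (length(ids) == 1L) {
    return(list(
      clusters = data.frame(genome_id = ids, cluster_id = 1L,
                            representative = ids, is_representative = TRUE),
      representatives = ids,
      distance = matrix(0, 1, 1, dimnames = list(ids, ids))))
  }
  if (is.null(estimates)) estimates <- estimate_ani_matrix(genomes, ...)
  d <- build_distance_matrix(genomes, estimates)
  cl <- cluster_complete_linkage(d, stop_distance)
  reps <- vapply(cl, select_representative, character(1),
                 metadata = metadata)
  tab <- do.call(rbind, lapply(seq_along(cl), function(i) {
    data.frame(genome_id = cl[[i]], cluster_id = i,
               representative = reps[i],
               is_representative = cl[[i]] == reps[i])
  }))
  rownames(tab) <- NULL
  list(clusters = tab, representatives = unname(reps), distance = d)
}
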