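# Independent reference implementations and small fixture builders used
# across the suite. The oracles deliberately recompute everything from
# first principles (no shared code with the package internals they check).

# Internal generator primitives reused when building fixtures.
with_seed <- magcurate:::with_seed
random_dna <- magcurate:::random_dna

# Naive complete-linkage agglomeration: at every step recompute every
# inter-cluster distance as the maximum over original member pairs, merge
# the closest pair while it is strictly below the stop distance, ties by
# lexicographically smallest (label_i, label_j) with label = min member.
naive_complete_linkage <- function(d, stop_distance) {
  ids <- sort(rownames(d))
  clusters <- as.list(ids)
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dist_ij <- max(d[clusters[[i]], clusters[[j]], drop = FALSE])
        lab <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        cand <- list(dist = dist_ij, i = i, j = j, lab = lab)
        if (is.null(best) || cand$dist < best$dist ||
            (cand$dist == best$dist &&
             (cand$lab[1] < best$lab[1] ||
              (cand$lab[1] == best$lab[1] && cand$lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    if (!(best$dist < stop_distance)) break
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  clusters[order(vapply(clusters, min, character(1)))]
}

# Canonical form of a partition (list of member vectors) for comparison.
canon_partition <- function(p) {
  sort(unname(vapply(p, function(x) paste(sort(x), collapse = "|"),
                     character(1))))
}

# Random symmetric distance matrix with zero diagonal; some entries are
# duplicated on purpose so tie-breaking is exercised.
random_distance_matrix <- function(n) {
  ids <- sprintf("g%02d", sample(seq_len(2L * n), n))
  vals <- sample(seq(0, 1, by = 0.01), n * (n - 1) / 2, replace = TRUE)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  d[upper.tri(d)] <- vals
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# Closed-form identity of two equal-length sequences under the
# positional (gapless) alignment — exact for substitution-only mutants.
hamming_identity <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(av) == length(bv))
  100 * mean(av == bv)
}

# Naive greedy gene clustering: same rule as the package (longest first,
# join first representative meeting both criteria) but re-derived here
# with no word prefilter and its own bookkeeping.
naive_greedy_clusters <- function(genes, min_identity = 0.95,
                                  min_coverage = 0.90) {
  seqs <- if (is.character(genes)) genes else as.character(genes)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  score_mat <- {
    b <- c("A", "C", "G", "T", "N")
    m <- matrix(-1, 5, 5, dimnames = list(b, b)); diag(m) <- 1
    m["N", ] <- 0; m[, "N"] <- 0
    m
  }
  for (gid in names(seqs)) {
    joined <- NA_character_
    for (r in reps) {
      shorter <- if (nchar(seqs[[gid]]) <= nchar(seqs[[r]])) seqs[[gid]]
                 else seqs[[r]]
      longer <- if (nchar(seqs[[gid]]) <= nchar(seqs[[r]])) seqs[[r]]
                else seqs[[gid]]
      aln <- Biostrings::pairwiseAlignment(
        pattern = shorter, subject = longer, type = "local",
        substitutionMatrix = score_mat, gapOpening = 2, gapExtension = 1)
      idy <- Biostrings::pid(aln, type = "PID1")
      span <- Biostrings::nchar(aln) -
        Biostrings::nindel(aln)@insertion[, "WidthSum"]
      if (idy >= min_identity * 100 &&
          span / nchar(shorter) >= min_coverage) {
        joined <- r
        break
      }
    }
    if (is.na(joined)) {
      reps <- c(reps, gid)
      members[[gid]] <- gid
    } else {
      members[[joined]] <- c(members[[joined]], gid)
    }
  }
  lapply(reps, function(r) members[[r]])
}

# In-code FASTQ fixture: reads with uniform quality Q over given lengths.
make_reads <- function(lengths, quals) {
  seqs <- vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  qstr <- vapply(seq_along(lengths), function(i) {
    paste(rep(rawToChar(as.raw(33L + quals[i])), lengths[i]), collapse = "")
  }, character(1))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, paste0("read", seq_along(seqs)))),
    Biostrings::PhredQuality(qstr))
}

# Small annotation table builder.
feat <- function(contig, start, end, type, strand = "+", full = TRUE,
                 isotype = NA_character_, partial = NA_character_) {
  data.frame(contig_id = contig, start = start, end = end, strand = strand,
             feature_type = type, full_length = full, isotype = isotype,
             partial_flags = partial)
}
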