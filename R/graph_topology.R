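# Topology triage of assembly-graph components into the three contig
# classes seen in long-read metagenome graphs:
#   circular — a single segment closed onto itself by a self-link with
#              matching orientation signs, i.e. a complete replicon;
#   tangled  — a component whose undirected link structure contains a
#              cycle, the signature of several co-assembled strains of
#              one species sharing genomic segments;
#   linear   — an acyclic component (incomplete assembly).
# Connectivity deliberately ignores link orientation: the classes are
# topological, not walk-constrained. A single segment whose only link is
# a (+,-) self-link joins the sequence to its own reverse complement and
# is conservatively called linear, not circular.

#' Classify assembly-graph components into circular / tangled / linear
#'
#' Components are connected components of the undirected segment
#' adjacency. A component is `circular` if it is a single segment whose
#' only incident link is a self-link with equal orientation signs
#' (`(+,+)` or `(-,-)`); `tangled` if its undirected multigraph of
#' segments contains any cycle (multi-edges and self-links included);
#' otherwise `linear`.
#'
#' @param graph An `assembly_graph`.
#' @return data.frame with one row per component: `component_id`,
#'   `class`, `n_segments`, `segment_ids` (comma separated),
#'   `total_length` and length-weighted `mean_depth`.
#' @export
classify_components <- function(graph) {
  seg <- graph$segments
  if (nrow(seg) == 0L) {
    return(data.frame(component_id = character(), class = character(),
                      n_segments = integer(), segment_ids = character(),
                      total_length = numeric(), mean_depth = numeric()))
  }
  lk <- graph$links
  ig <- igraph::graph_from_data_frame(
    d = lk[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seg$id))
  comp <- igraph::components(ig)$membership
  self_same <- lk$from == lk$to & lk$from_orient == lk$to_orient
  self_any <- lk$from == lk$to

  rows <- lapply(sort(unique(comp)), function(ci) {
    members <- sort(names(comp)[comp == ci])
    sub <- seg[match(members, seg$id), , drop = FALSE]
    in_comp <- lk$from %in% members  # links stay within a component
    n_links <- sum(in_comp)
    cls <- if (length(members) == 1L && n_links == 1L &&
               sum(self_same & in_comp) == 1L) {
      "circular"
    } else {
      # undirected multigraph has a cycle iff #edges >= #vertices for a
      # connected component (self-loops and parallel edges each count)
      if (n_links >= length(members)) "tangled" else "linear"
    }
    # a lone (+,-) self-link folds the segment on its reverse complement:
    # not a circular chromosome, and not strain tangling either
    if (length(members) == 1L && sum(self_same & in_comp) == 0L &&
        sum(self_any & in_comp) == n_links) {
      cls <- "linear"
    }
    w <- as.numeric(sub$length)
    data.frame(component_id = sprintf("comp%04d", ci), class = cls,
               n_segments = length(members),
               segment_ids = paste(members, collapse = ","),
               total_length = sum(w),
               mean_depth = sum(w * sub$depth) / sum(w))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-segment depth table
#'
#' One row per segment, ordered by descending length then id — the depth
#' file consumed by abundance-aware binning.
#'
#' @param graph An `assembly_graph`.
#' @return data.frame with `segment_id`, `length`, `depth`.
#' @export
depth_table <- function(graph) {
  seg <- graph$segments
  if (nrow(seg) == 0L) {
    return(data.frame(segment_id = character(), length = integer(),
                      depth = numeric()))
  }
  if (all(seg$depth == 0)) {
    warning("all segment depths are 0 (no depth tags in the source graph?)")
  }
  ord <- order(-as.numeric(seg$length), seg$id)
  out <- data.frame(segment_id = seg$id[ord], length = seg$length[ord],
                    depth = seg$depth[ord])
  rownames(out) <- NULL
  out
}

#' Export component sequences grouped by topology class
#'
#' Writes `circular.fasta`, `tangled.fasta` and `linear.fasta` plus one
#' FASTA per tangled component (`tangled_<component_id>.fasta`) so each
#' tangled component can be fed to a reassembly step on its own.
#'
#' @param graph An `assembly_graph` whose segments carry sequences.
#' @param calls Output of [classify_components()] on the same graph.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
export_by_class <- function(graph, calls, out_dir) {
  seg <- graph$segments
  missing_seq <- seg$id[is.na(seg$sequence)]
  if (length(missing_seq)) {
    stop("segment without sequence cannot be exported: ", missing_seq[1])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- setNames(as.character(seg$sequence), seg$id)
  paths <- character(0)
  for (cls in c("circular", "tangled", "linear")) {
    sel <- calls[calls$class == cls, , drop = FALSE]
    ids <- unlist(strsplit(sel$segment_ids, ",", fixed = TRUE))
    p <- file.path(out_dir, paste0(cls, ".fasta"))
    if (length(ids)) {
      write_fasta(Biostrings::DNAStringSet(seqs[ids]), p)
      paths[[cls]] <- p
    }
  }
  tang <- calls[calls$class == "tangled", , drop = FALSE]
  for (i in seq_len(nrow(tang))) {
    ids <- strsplit(tang$segment_ids[i], ",", fixed = TRUE)[[1]]
    p <- file.path(out_dir, sprintf("tangled_%s.fasta", tang$component_id[i]))
    write_fasta(Biostrings::DNAStringSet(seqs[ids]), p)
    paths[[paste0("tangled_", tang$component_id[i])]] <- p
  }
  paths
}
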