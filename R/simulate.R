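# Synthetic multi-strain communities with known ground truth.
#
# The generator emulates the statistical structure the curation pipeline
# assumes: species ancestors are independent random genomes (so between-
# species identity is random background, well below the 95% species
# threshold), strains diverge from their ancestor by per-site
# substitutions at rate (100 - intra_species_ani)/100 plus sparse short
# indels, graph components realise the three assembly topologies, rRNA
# operons / tRNA complements are positional fixtures, and gene families
# carry a known redundancy structure. None of it models sequencing error
# or real gene sequences; it is ground truth for parameter recovery.

AA_CODES <- c("A","C","D","E","F","G","H","I","K","L",
              "M","N","P","Q","R","S","T","V","W","Y")

#' Mutate a DNA sequence by substitutions and (optionally) short indels
#'
#' Substitutions hit each site independently at `sub_rate` and always
#' change the base. Indel events occur at `indel_rate` per site, half
#' insertions half deletions, lengths uniform on 1..`indel_max_len`.
#' Uses the current RNG stream (callers fix the seed).
#'
#' @param x Character DNA sequence.
#' @param sub_rate Per-site substitution probability.
#' @param indel_rate Per-site indel event probability (0 disables indels).
#' @param indel_max_len Maximum indel length.
#' @return Mutated character sequence.
#' @export
mutate_sequence <- function(x, sub_rate, indel_rate = 0, indel_max_len = 5L) {
  bases <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(bases)
  hit <- which(runif(n) < sub_rate)
  if (length(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  if (indel_rate > 0) {
    ev <- which(runif(n) < indel_rate)
    if (length(ev)) {
      pieces <- as.list(bases)
      for (pos in ev) {
        len <- sample.int(indel_max_len, 1L)
        if (runif(1) < 0.5) {  # insertion after pos
          pieces[[pos]] <- c(pieces[[pos]],
                             sample(DNA_BASES, len, replace = TRUE))
        } else {               # deletion of up to len bases from pos
          drop <- pos:min(n, pos + len - 1L)
          for (d in drop) pieces[[d]] <- character(0)
        }
      }
      bases <- unlist(pieces)
    }
  }
  paste(bases, collapse = "")
}

#' Simulate a multi-strain community with controlled ANI structure
#'
#' Each species gets an independent random ancestor genome; its strains
#' are derived by per-site substitution at rate
#' `(100 - intra_species_ani)/100` plus short indels at one tenth of that
#' rate (`indels = FALSE` gives the substitution-only variant whose
#' identity to the ancestor has a closed form). With a single strain per
#' species the strain IS the ancestor. Abundances are lognormal,
#' normalised to sum to 1.
#'
#' @param n_species Number of species.
#' @param strains_per_species Strains per species (scalar or vector).
#' @param genome_length_bp Ancestor genome length.
#' @param intra_species_ani Target strain-to-ancestor ANI, percent in (95, 100).
#' @param inter_species_ani_max Upper bound on between-species ANI
#'   (must be < 95; independent random ancestors give ~background identity).
#' @param seed Integer seed fixing all randomness.
#' @param indels Include short indels (default TRUE).
#' @return List with `genomes` (named [Biostrings::DNAStringSet]),
#'   `ancestors` (one per species) and `truth` (genome table, species /
#'   strain partitions, abundances).
#' @export
simulate_genomes <- function(n_species, strains_per_species,
                             genome_length_bp = 50000L,
                             intra_species_ani = 99.3,
                             inter_species_ani_max = 90,
                             seed = 1L, indels = TRUE) {
  if (intra_species_ani <= 95 || intra_species_ani >= 100) {
    stop("intra_species_ani must lie in (95, 100)")
  }
  if (inter_species_ani_max >= 95) stop("inter_species_ani_max must be < 95")
  if (intra_species_ani <= inter_species_ani_max) {
    stop("intra_species_ani must exceed inter_species_ani_max")
  }
  n_strains <- rep_len(as.integer(strains_per_species), n_species)
  sub_rate <- (100 - intra_species_ani) / 100
  indel_rate <- if (indels) sub_rate / 10 else 0

  with_seed(seed, {
    ancestors <- vapply(seq_len(n_species), function(i) {
      random_dna(genome_length_bp)
    }, character(1))
    names(ancestors) <- sprintf("sp%02d", seq_len(n_species))

    rows <- list()
    seqs <- character(0)
    for (i in seq_len(n_species)) {
      sp <- names(ancestors)[i]
      for (j in seq_len(n_strains[i])) {
        gid <- sprintf("%s_st%02d", sp, j)
        seqs[[gid]] <- if (n_strains[i] == 1L) {
          ancestors[[i]]
        } else {
          mutate_sequence(ancestors[[i]], sub_rate, indel_rate)
        }
        rows[[gid]] <- data.frame(genome_id = gid, species_id = sp,
                                  strain_id = gid,
                                  target_ani_to_species_ancestor =
                                    if (n_strains[i] == 1L) 100
                                    else intra_species_ani)
      }
    }
    genome_tbl <- do.call(rbind, rows)
    rownames(genome_tbl) <- NULL
    ab <- exp(stats::rnorm(nrow(genome_tbl), mean = 0, sd = 1))
    ab <- ab / sum(ab)
    names(ab) <- genome_tbl$genome_id

    list(
      genomes = setNames(Biostrings::DNAStringSet(unlist(seqs)), names(seqs)),
      ancestors = setNames(Biostrings::DNAStringSet(ancestors),
                           names(ancestors)),
      truth = list(
        genomes = genome_tbl,
        species_partition = split(genome_tbl$genome_id,
                                  genome_tbl$species_id),
        strain_partition = split(genome_tbl$genome_id,
                                 genome_tbl$strain_id),
        abundances = ab
      )
    )
  })
}

cut_points <- function(n, k) {
  # k roughly equal pieces of an n bp sequence; returns start/end table
  bounds <- round(seq(0, n, length.out = k + 1L))
  data.frame(start = bounds[-(k + 1L)] + 1L, end = bounds[-1L])
}

#' Simulate an assembly graph realising planned component topologies
#'
#' Topologies follow the three assembly-graph classes: `circular` (one
#' segment closed by a (+,+) self-link), `tangled` (the strains of one
#' species cut into 4–8 segments sharing a common segment, wired so the
#' component contains a multi-segment cycle) and `linear` (1–3 segments
#' in a simple path). Segment depth is `abundance * depth_scale`.
#'
#' @param genomes Named DNAStringSet (or named character) of genomes.
#' @param topology_plan Named character vector, one of
#'   `"circular"`, `"tangled"`, `"linear"` per genome. All strains of a
#'   tangled species must be planned tangled.
#' @param abundances Named numeric abundances (summing to 1).
#' @param seed Integer seed.
#' @param species Named map genome_id -> species_id; defaults to each
#'   genome being its own species (tangled then impossible).
#' @param depth_scale Community depth at abundance 1 (default 300).
#' @return List with `graph` (an `assembly_graph`) and `truth`
#'   (data.frame component_id / class / segment ids, comma separated).
#' @export
simulate_graph <- function(genomes, topology_plan, abundances, seed = 1L,
                           species = NULL, depth_scale = 300) {
  gseq <- as_named_chr(genomes)
  ids <- names(gseq)
  if (!setequal(names(topology_plan), ids)) {
    stop("topology_plan must name every genome exactly once")
  }
  if (!all(topology_plan %in% c("circular", "tangled", "linear"))) {
    stop("topology classes are circular, tangled, linear")
  }
  if (is.null(species)) species <- setNames(ids, ids)
  ab <- abundances[ids]
  if (anyNA(ab)) stop("abundances must cover every genome")

  with_seed(seed, {
    segs <- list()
    links <- list()
    truth <- list()
    add_seg <- function(id, sequence, depth) {
      segs[[id]] <<- data.frame(id = id, length = nchar(sequence),
                                depth = depth, sequence = sequence)
    }
    add_link <- function(from, fo, to, to_o) {
      links[[length(links) + 1L]] <<-
        data.frame(from = from, from_orient = fo, to = to, to_orient = to_o,
                   overlap = "0M")
    }

    tangled_species <- unique(species[names(topology_plan)[
      topology_plan == "tangled"]])
    for (sp in tangled_species) {
      members <- ids[species[ids] == sp]
      if (length(members) < 2L) {
        stop("tangled topology needs >= 2 strains in species ", sp)
      }
      if (!all(topology_plan[members] == "tangled")) {
        stop("all strains of species ", sp, " must share the tangled plan")
      }
      # shared segment from the first strain's head; per-strain chains of
      # the remainder, both ends wired back to the shared segment
      n_strains <- length(members)
      lo <- ceiling(3 / n_strains)            # keeps 1 + S*per >= 4
      hi <- max(lo, floor(7 / n_strains))     # ... and <= 8 when possible
      per_strain <- sample(seq(lo, hi), 1L)
      shared_len <- max(500L, round(nchar(gseq[[members[1]]]) * 0.15))
      shared_id <- paste0(sp, "_shared")
      add_seg(shared_id, substr(gseq[[members[1]]], 1L, shared_len),
              sum(ab[members]) * depth_scale)
      comp_ids <- shared_id
      for (m in members) {
        body <- substr(gseq[[m]], shared_len + 1L, nchar(gseq[[m]]))
        cp <- cut_points(nchar(body), per_strain)
        prev <- shared_id
        for (p in seq_len(nrow(cp))) {
          sid <- sprintf("%s_p%d", m, p)
          add_seg(sid, substr(body, cp$start[p], cp$end[p]),
                  ab[[m]] * depth_scale)
          add_link(prev, "+", sid, "+")
          prev <- sid
          comp_ids <- c(comp_ids, sid)
        }
        add_link(prev, "+", shared_id, "+")  # closes the strain's cycle
      }
      truth[[sp]] <- data.frame(component_id = sp, class = "tangled",
                                segment_ids = paste(comp_ids, collapse = ","))
    }

    for (g in ids[topology_plan[ids] == "circular"]) {
      sid <- paste0(g, "_c")
      add_seg(sid, gseq[[g]], ab[[g]] * depth_scale)
      add_link(sid, "+", sid, "+")
      truth[[g]] <- data.frame(component_id = g, class = "circular",
                               segment_ids = sid)
    }

    for (g in ids[topology_plan[ids] == "linear"]) {
      k <- sample(1:3, 1L)
      cp <- cut_points(nchar(gseq[[g]]), k)
      sids <- sprintf("%s_l%d", g, seq_len(k))
      for (p in seq_len(k)) {
        add_seg(sids[p], substr(gseq[[g]], cp$start[p], cp$end[p]),
                ab[[g]] * depth_scale)
        if (p > 1L) add_link(sids[p - 1L], "+", sids[p], "+")
      }
      truth[[g]] <- data.frame(component_id = g, class = "linear",
                               segment_ids = paste(sids, collapse = ","))
    }

    graph <- assembly_graph(do.call(rbind, unname(segs)),
                            if (length(links)) do.call(rbind, links) else NULL)
    truth_df <- do.call(rbind, unname(truth))
    rownames(truth_df) <- NULL
    list(graph = graph, truth = truth_df)
  })
}

#' Simulate rRNA operon and tRNA annotations for one genome
#'
#' Each intact operon places full-length 16S (1.5 kb), 23S (2.9 kb) and
#' 5S (0.12 kb) genes on one strand with inter-gene gaps up to 500 bp.
#' With `operon_intact = FALSE` every operon is broken: one of its three
#' genes is dropped or flagged `full_length = FALSE`. tRNA genes (72 bp)
#' are placed outside operons with isotypes cycling through the 20 amino
#' acids.
#'
#' @param genome A single named sequence (character or DNAStringSet) or an
#'   integer genome length.
#' @param n_operons Number of rRNA operons (0–6).
#' @param n_trnas Number of tRNA genes (0–80).
#' @param operon_intact Logical; FALSE breaks every operon.
#' @param seed Integer seed.
#' @param contig_id Contig name when `genome` is a bare length.
#' @return Annotation data.frame (see [read_annotations()]).
#' @export
simulate_annotations <- function(genome, n_operons, n_trnas,
                                 operon_intact = TRUE, seed = 1L,
                                 contig_id = "contig1") {
  if (is.numeric(genome)) {
    glen <- as.integer(genome)
  } else {
    gseq <- as_named_chr(genome)
    if (length(gseq) != 1L) stop("one genome at a time")
    glen <- nchar(gseq[[1]])
    contig_id <- names(gseq)
  }
  if (n_operons < 0L || n_operons > 6L) stop("n_operons must be in [0, 6]")
  if (n_trnas < 0L || n_trnas > 80L) stop("n_trnas must be in [0, 80]")

  rlen <- c(rRNA_16S = 1500L, rRNA_23S = 2900L, rRNA_5S = 120L)
  with_seed(seed, {
    feats <- list()
    occupied <- matrix(numeric(0), ncol = 2)
    if (n_operons > 0L) {
      span_max <- sum(rlen) + 2L * 500L
      bin <- cut_points(glen, n_operons)
      if (any(bin$end - bin$start + 1L < span_max + 200L)) {
        stop("genome too short for ", n_operons, " rRNA operons")
      }
      for (o in seq_len(n_operons)) {
        strand <- sample(c("+", "-"), 1L)
        gaps <- sample(50:500, 2L, replace = TRUE)
        pos <- bin$start[o] +
          sample.int(bin$end[o] - bin$start[o] - span_max - 100L, 1L)
        broken_gene <- if (!operon_intact) sample(names(rlen), 1L) else NA
        drop_it <- !operon_intact && runif(1) < 0.5
        cur <- pos
        for (gi in seq_along(rlen)) {
          type <- names(rlen)[gi]
          st <- cur; en <- cur + rlen[[gi]] - 1L
          cur <- en + 1L + gaps[min(gi, 2L)]
          if (identical(type, broken_gene) && drop_it) next
          feats[[length(feats) + 1L]] <- data.frame(
            contig_id = contig_id, start = st, end = en, strand = strand,
            feature_type = type,
            full_length = !identical(type, broken_gene),
            isotype = NA_character_, partial_flags = NA_character_)
        }
        occupied <- rbind(occupied, c(pos, cur))
      }
    }
    if (n_trnas > 0L) {
      tlen <- 72L
      cand <- sample.int(glen - tlen, min(glen - tlen, n_trnas * 30L))
      free <- vapply(cand, function(s) {
        !any(s <= occupied[, 2] & s + tlen - 1L >= occupied[, 1])
      }, logical(1))
      cand <- cand[free]
      # greedy non-overlapping placement
      cand <- sort(cand)
      chosen <- integer(0)
      last_end <- -1L
      for (s in cand) {
        if (s > last_end) { chosen <- c(chosen, s); last_end <- s + tlen - 1L }
        if (length(chosen) == n_trnas) break
      }
      if (length(chosen) < n_trnas) {
        stop("genome too short to place ", n_trnas, " tRNA genes")
      }
      chosen <- sample(chosen)  # decouple isotype cycle from position
      for (i in seq_len(n_trnas)) {
        feats[[length(feats) + 1L]] <- data.frame(
          contig_id = contig_id, start = chosen[i],
          end = chosen[i] + tlen - 1L,
          strand = sample(c("+", "-"), 1L), feature_type = "tRNA",
          full_length = TRUE,
          isotype = AA_CODES[(i - 1L) %% 20L + 1L],
          partial_flags = NA_character_)
      }
    }
    ann <- if (length(feats)) do.call(rbind, feats) else empty_annotations()
    if (nrow(ann) && any(ann$end > glen)) stop("feature exceeds genome length")
    rownames(ann) <- NULL
    validate_annotations(ann)
  })
}

#' Simulate gene families with known redundancy structure
#'
#' Families are independent random ancestor genes; members are derived by
#' substitutions at rate `(100 - within_family_identity)/100` and end
#' trimming of up to 10% of the length (so members align over the full
#' shorter sequence). Between-family identity is random background
#' (< 80%). A `partial_fraction` of genes get a partial structure flag.
#'
#' @param n_families Number of gene families.
#' @param members_per_family Members per family.
#' @param within_family_identity Percent, must exceed 95 so the 95%
#'   clustering criterion recovers the families unambiguously.
#' @param partial_fraction Fraction of genes flagged structurally partial.
#' @param seed Integer seed.
#' @param base_length_bp Ancestor gene length (default 900).
#' @return List with `genes` (named DNAStringSet), `partial_flags` (named
#'   character, `"00"` = complete) and `truth` (list of member-id vectors,
#'   one per family).
#' @export
simulate_gene_families <- function(n_families, members_per_family,
                                   within_family_identity = 98,
                                   partial_fraction = 0, seed = 1L,
                                   base_length_bp = 900L) {
  if (within_family_identity <= 95) {
    stop("within_family_identity must exceed 95 for unambiguous truth")
  }
  # each member diverges from the ancestor at half the pairwise rate, so
  # member-vs-member identity lands near the requested value
  sub_rate <- (100 - within_family_identity) / 200
  with_seed(seed, {
    seqs <- character(0)
    truth <- list()
    for (f in seq_len(n_families)) {
      anc_len <- round(base_length_bp * runif(1, 0.9, 1.1))
      anc <- random_dna(anc_len)
      fam <- sprintf("fam%02d", f)
      members <- character(0)
      for (m in seq_len(members_per_family)) {
        gid <- sprintf("%s_m%02d", fam, m)
        s <- if (m == 1L) anc else mutate_sequence(anc, sub_rate)
        trim <- round(nchar(s) * runif(1, 0, 0.10))
        left <- sample.int(trim + 1L, 1L) - 1L
        s <- substr(s, left + 1L, nchar(s) - (trim - left))
        seqs[[gid]] <- s
        members <- c(members, gid)
      }
      truth[[fam]] <- members
    }
    n_genes <- length(seqs)
    n_partial <- round(partial_fraction * n_genes)
    flags <- rep("00", n_genes)
    if (n_partial > 0L) {
      flags[sample.int(n_genes, n_partial)] <-
        sample(c("01", "10", "11"), n_partial, replace = TRUE)
    }
    names(flags) <- names(seqs)
    list(genes = setNames(Biostrings::DNAStringSet(unlist(seqs)), names(seqs)),
         partial_flags = flags, truth = truth)
  })
}

#' Simulate a full community and write its files to a directory
#'
#' Convenience wrapper used by the `magcurate simulate` command: generates
#' genomes, an assembly graph, per-genome annotations, gene families and a
#' metadata table, and writes `genomes.fasta`, `graph.gfa`,
#' `annotations.gff3`, `genes.fasta`, `metadata.tsv` and `truth.json`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_species,strains_per_species,genome_length_bp,intra_species_ani
#'   Passed to [simulate_genomes()].
#' @param seed Integer seed.
#' @return Invisibly, the list of generated objects.
#' @export
simulate_community <- function(out_dir, n_species = 3L,
                               strains_per_species = 2L,
                               genome_length_bp = 20000L,
                               intra_species_ani = 99.3, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genomes(n_species, strains_per_species, genome_length_bp,
                          intra_species_ani, seed = seed)
  truth <- sim$truth
  ids <- truth$genomes$genome_id
  species <- setNames(truth$genomes$species_id, ids)
  # one tangled species when strains allow, one circular genome per other
  # species, remaining strains linear
  plan <- setNames(rep("linear", length(ids)), ids)
  sp_ids <- unique(species)
  if (strains_per_species >= 2L) {
    plan[species == sp_ids[1]] <- "tangled"
  }
  for (sp in sp_ids[-1]) plan[which(species == sp)[1]] <- "circular"
  g <- simulate_graph(sim$genomes, plan, truth$abundances, seed = seed + 1L,
                      species = species)
  # annotation load scaled to what the genome can hold: each operon needs
  # ~6 kb, tRNAs 72 bp each with slack for random placement
  n_op_max <- max(1L, (genome_length_bp - 4000L) %/% 7000L)
  ann <- do.call(rbind, lapply(seq_along(ids), function(i) {
    n_op <- 1L + i %% n_op_max
    trna_cap <- max(0L, (genome_length_bp - n_op * 6200L) %/% 216L)
    simulate_annotations(sim$genomes[ids[i]], n_operons = n_op,
                         n_trnas = min(35L + (i * 7L) %% 31L, trna_cap),
                         seed = seed + 10L + i)
  }))
  fam <- simulate_gene_families(8L, 4L, 98, partial_fraction = 0.05,
                                seed = seed + 2L)
  md <- with_seed(seed + 3L, data.frame(
    genome_id = ids,
    is_circular = unname(plan[ids] == "circular"),
    assembly_size = nchar(as.character(sim$genomes[ids])),
    n_contigs = ifelse(plan[ids] == "circular", 1L, 2L),
    completeness = round(runif(length(ids), 70, 100), 2),
    contamination = round(runif(length(ids), 0, 8), 2),
    compartment = "synthetic"
  ))
  write_fasta(sim$genomes, file.path(out_dir, "genomes.fasta"))
  write_gfa(g$graph, file.path(out_dir, "graph.gfa"))
  write_annotations(ann, file.path(out_dir, "annotations.gff3"))
  write_fasta(fam$genes, file.path(out_dir, "genes.fasta"))
  write_genome_metadata(md, file.path(out_dir, "metadata.tsv"))
  jsonlite::write_json(
    list(genomes = truth$genomes,
         abundances = as.list(truth$abundances),
         topology = as.list(plan),
         gene_families = fam$truth,
         partial_flags = as.list(fam$partial_flags)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(genomes = sim, graph = g, annotations = ann,
                 gene_families = fam, metadata = md, topology_plan = plan))
}
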