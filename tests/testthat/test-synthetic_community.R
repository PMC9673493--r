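test_that("simulated strains hit their target divergence from the ancestor", {
  sim <- simulate_genomes(2, 2, genome_length_bp = 50000,
                          intra_species_ani = 99.3, seed = 21,
                          indels = FALSE)
  for (row in seq_len(nrow(sim$truth$genomes))) {
    gid <- sim$truth$genomes$genome_id[row]
    sp <- sim$truth$genomes$species_id[row]
    idy <- hamming_identity(as.character(sim$genomes[[gid]]),
                            as.character(sim$ancestors[[sp]]))
    expect_lt(abs(idy - 99.3), 0.3)
  }
})

test_that("strain pairs within a species stay above twice the divergence", {
  # two strains each 0.7% from the ancestor are ~1.4% apart in
  # substitutions plus ~0.4% of alignment columns from indels; with
  # sampling noise on a 5 kb genome the pairwise DP identity must still
  # stay well above the 2% strain-separation floor
  sim <- simulate_genomes(1, 2, genome_length_bp = 5000,
                          intra_species_ani = 99.3, seed = 8)
  aln <- Biostrings::pairwiseAlignment(
    sim$genomes[[1]], sim$genomes[[2]], type = "global")
  expect_gte(Biostrings::pid(aln, type = "PID1"), 97.5)
})

test_that("single-strain species reproduce their ancestors exactly", {
  sim <- simulate_genomes(3, 1, 2000, 99.3, seed = 5)
  expect_identical(unname(as.character(sim$genomes)),
                   unname(as.character(sim$ancestors)))
  expect_true(all(sim$truth$genomes$target_ani_to_species_ancestor == 100))
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_genomes(2, 2, 3000, 99.0, seed = 77)
  b <- simulate_genomes(2, 2, 3000, 99.0, seed = 77)
  expect_identical(as.character(a$genomes), as.character(b$genomes))
  expect_identical(a$truth$abundances, b$truth$abundances)
  fa <- simulate_gene_families(3, 3, 98, 0.2, seed = 13)
  fb <- simulate_gene_families(3, 3, 98, 0.2, seed = 13)
  expect_identical(as.character(fa$genes), as.character(fb$genes))
  expect_identical(fa$partial_flags, fb$partial_flags)
  an_a <- simulate_annotations(30000L, 2, 20, seed = 9)
  an_b <- simulate_annotations(30000L, 2, 20, seed = 9)
  expect_identical(an_a, an_b)
})

test_that("realized identity is monotone in the substitution rate", {
  anc <- with_seed(31, random_dna(20000))
  idents <- vapply(c(0.005, 0.02, 0.05), function(r) {
    hamming_identity(anc, with_seed(32, mutate_sequence(anc, r)))
  }, numeric(1))
  expect_true(all(diff(idents) < 0))
})

test_that("mutation engine rejects nothing it should not and abundances sum to 1", {
  expect_error(simulate_genomes(2, 2, 1000, 94, seed = 1), "intra_species_ani")
  expect_error(simulate_genomes(2, 2, 1000, 96, inter_species_ani_max = 97,
                                seed = 1), "inter")
  sim <- simulate_genomes(3, 2, 1000, 99.0, seed = 2)
  expect_equal(sum(sim$truth$abundances), 1)
  parts <- unlist(sim$truth$species_partition)
  expect_setequal(parts, sim$truth$genomes$genome_id)
})

test_that("simulated graphs realise the planned topologies by construction", {
  sim <- simulate_genomes(3, 2, 4000, 99.0, seed = 41)
  ids <- names(sim$genomes)
  sp <- setNames(sim$truth$genomes$species_id, ids)
  plan <- setNames(c("tangled", "tangled", "circular", "linear", "linear",
                     "circular"), ids)
  g <- simulate_graph(sim$genomes, plan, sim$truth$abundances, seed = 42,
                      species = sp)
  expect_setequal(g$truth$class, c("tangled", "circular", "linear"))
  tangled_segs <- strsplit(
    g$truth$segment_ids[g$truth$class == "tangled"], ",")[[1]]
  expect_gte(length(tangled_segs), 4L)
  expect_lte(length(tangled_segs), 9L)
  # every genome's sequence is fully represented in its component
  expect_error(
    simulate_graph(sim$genomes,
                   setNames(rep("tangled", 6), ids)[1:6],
                   sim$truth$abundances, seed = 1,
                   species = setNames(ids, ids)),
    "tangled")
})

test_that("annotation generator honours operon and tRNA specifications", {
  ann <- simulate_annotations(40000L, n_operons = 4, n_trnas = 50, seed = 6)
  expect_equal(nrow(find_rrna_operons(ann)), 4L)
  expect_equal(sum(ann$feature_type == "tRNA"), 50L)
  expect_true(rna_complete(ann)$rna_complete)
  broken <- simulate_annotations(40000L, n_operons = 1, n_trnas = 50,
                                 operon_intact = FALSE, seed = 6)
  expect_false(rna_complete(broken)$rna_complete)
  few <- simulate_annotations(40000L, n_operons = 1, n_trnas = 17, seed = 6)
  expect_false(rna_complete(few)$rna_complete)
  expect_error(simulate_annotations(6000L, n_operons = 4, n_trnas = 0,
                                    seed = 1), "too short")
})

test_that("gene families carry the planned redundancy and partial flags", {
  fam <- simulate_gene_families(10, 5, 98, partial_fraction = 0.2, seed = 7)
  expect_length(fam$genes, 50L)
  expect_length(fam$truth, 10L)
  expect_equal(sum(fam$partial_flags != "00"), 10L)
  singletons <- simulate_gene_families(4, 1, 98, seed = 3)
  expect_true(all(lengths(singletons$truth) == 1L))
  expect_error(simulate_gene_families(2, 2, 95, seed = 1), "exceed 95")
})

test_that("community writer emits the full file set with consistent truth", {
  out <- withr::local_tempdir()
  sim <- simulate_community(out, n_species = 2, strains_per_species = 2,
                            genome_length_bp = 12000, seed = 19)
  files <- c("genomes.fasta", "graph.gfa", "annotations.gff3",
             "genes.fasta", "metadata.tsv", "truth.json")
  expect_true(all(file.exists(file.path(out, files))))
  genomes <- read_fasta(file.path(out, "genomes.fasta"))
  md <- read_genome_metadata(file.path(out, "metadata.tsv"))
  expect_setequal(names(genomes), md$genome_id)
  truth <- jsonlite::read_json(file.path(out, "truth.json"))
  expect_setequal(names(truth$topology), md$genome_id)
})
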