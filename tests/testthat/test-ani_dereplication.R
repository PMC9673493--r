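test_that("a genome against itself gives ANI 100 with all fragments mapped", {
  g <- with_seed(1, random_dna(9000))
  est <- estimate_ani(c(g1 = g), c(g1 = g))
  expect_equal(est$ani, 100)
  expect_equal(est$fragments_mapped, est$fragments_total)
  expect_equal(est$fragments_total, 3L)
})

test_that("ANI tracks the exact positional identity on substitution-only mutants", {
  anc <- with_seed(2, random_dna(24000))
  for (rate in c(0.005, 0.02)) {
    mut <- with_seed(3, mutate_sequence(anc, rate))
    est <- estimate_ani(c(q = mut), c(r = anc))
    oracle <- mean(vapply(seq_len(nchar(mut) %/% 3000), function(i) {
      lo <- (i - 1) * 3000 + 1
      hamming_identity(substr(mut, lo, lo + 2999), substr(anc, lo, lo + 2999))
    }, numeric(1)))
    expect_lt(abs(est$ani - oracle), 0.3)
  }
})

test_that("unrelated genomes yield no mapped fragments and undefined ANI", {
  a <- with_seed(4, random_dna(12000))
  b <- with_seed(5, random_dna(12000))
  est <- estimate_ani(c(a = a), c(b = b))
  expect_true(is.na(est$ani))
  expect_equal(est$fragments_mapped, 0L)
})

test_that("reverse-complemented genomes still map", {
  g <- with_seed(6, random_dna(9000))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  est <- estimate_ani(c(q = rc), c(r = g))
  expect_equal(est$ani, 100)
})

test_that("estimator input validation catches short and non-DNA queries", {
  expect_error(estimate_ani(c(q = "ACGT"), c(r = with_seed(1, random_dna(4000)))),
               "shorter than one fragment")
  bad <- paste(rep("ACGX", 1000), collapse = "")
  expect_error(estimate_ani(c(q = bad), c(r = with_seed(1, random_dna(4000)))),
               "non-DNA")
})

test_that("distance matrix symmetrises by the minimum directional ANI", {
  est <- data.frame(query_id = c("a", "b"), reference_id = c("b", "a"),
                    ani = c(99.5, 99.1), fragments_total = 5L,
                    fragments_mapped = 5L)
  d <- build_distance_matrix(c("a", "b"), est)
  expect_equal(d["a", "b"], 0.009)
  expect_equal(d["b", "a"], 0.009)
  expect_equal(diag(d), c(a = 0, b = 0))
  # one-sided estimate is used as is; absent pairs get distance 1
  est2 <- data.frame(query_id = "a", reference_id = "b", ani = 98,
                     fragments_total = 5L, fragments_mapped = 4L)
  d2 <- build_distance_matrix(c("a", "b", "c"), est2)
  expect_equal(d2["a", "b"], 0.02)
  expect_equal(d2["a", "c"], 1)
  est_bad <- data.frame(query_id = "zz", reference_id = "b", ani = 98)
  expect_error(build_distance_matrix(c("a", "b"), est_bad), "unknown genome")
})

test_that("complete linkage obeys the documented stop semantics", {
  ids <- c("A", "B", "C")
  d <- matrix(c(0, 0.005, 0.04,
                0.005, 0, 0.04,
                0.04, 0.04, 0), 3, dimnames = list(ids, ids))
  expect_identical(canon_partition(cluster_complete_linkage(d, 0.01)),
                   c("A|B", "C"))
  expect_identical(canon_partition(cluster_complete_linkage(d, 0.05)),
                   "A|B|C")
  # a pair at exactly the stop distance is NOT merged (strict <)
  d2 <- matrix(c(0, 0.01, 0.01, 0), 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_length(cluster_complete_linkage(d2, 0.01), 2L)
  one <- matrix(0, 1, 1, dimnames = list("solo", "solo"))
  expect_identical(canon_partition(cluster_complete_linkage(one, 0.05)),
                   "solo")
  d3 <- d; d3[1, 2] <- 0.3
  expect_error(cluster_complete_linkage(d3, 0.05), "symmetric")
})

test_that("clustering matches the naive agglomerative oracle on random inputs", {
  set.seed(123)
  for (trial in seq_len(60)) {
    n <- sample(2:12, 1)
    d <- random_distance_matrix(n)
    stop_d <- sample(c(0.01, 0.05, 0.2, 0.5), 1)
    got <- cluster_complete_linkage(d, stop_d)
    want <- naive_complete_linkage(d, stop_d)
    expect_identical(canon_partition(got), canon_partition(want))
  }
})

test_that("clustering agrees with hclust/cutree away from ties and boundaries", {
  # independent cross-check: with all-distinct distances and a stop value
  # strictly between merge heights, complete-linkage dendrogram cutting
  # must produce the same partition
  set.seed(7)
  n <- 9
  ids <- paste0("g", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  d[upper.tri(d)] <- sample(seq(0.01, 0.99, length.out = n * (n - 1) / 2))
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  h <- stats::hclust(stats::as.dist(d), method = "complete")
  stop_d <- 0.3
  stopifnot(!any(abs(h$height - stop_d) < 1e-9))
  want <- split(ids, stats::cutree(h, h = stop_d))
  got <- cluster_complete_linkage(d, stop_d)
  expect_identical(canon_partition(got), canon_partition(want))
})

test_that("representative selection prefers circular, then score, then size", {
  md <- data.frame(
    genome_id = c("A", "B", "C", "D"),
    is_circular = c(TRUE, FALSE, TRUE, TRUE),
    assembly_size = c(2.4e6, 3e6, 2.4e6, 2.6e6),
    n_contigs = c(1L, 4L, 1L, 1L),
    completeness = c(80, 95, 90, 90),
    contamination = c(0, 0, 0, 0))
  # circular beats the higher-scoring noncircular
  expect_identical(select_representative(c("A", "B"), md), "A")
  # among circulars the larger CheckM score wins
  expect_identical(select_representative(c("A", "C"), md), "C")
  # equal score: larger assembly wins
  expect_identical(select_representative(c("C", "D"), md), "D")
  expect_error(select_representative(c("A", "nope"), md), "no metadata")
})

test_that("dereplication recovers species and strain partitions from truth", {
  sim <- simulate_genomes(3, 2, genome_length_bp = 15000,
                          intra_species_ani = 99.3, seed = 71)
  md <- data.frame(genome_id = names(sim$genomes),
                   is_circular = rep(c(TRUE, FALSE), 3),
                   assembly_size = 15000, n_contigs = rep(c(1L, 2L), 3),
                   completeness = 90 + seq_len(6), contamination = 0.5)
  est <- estimate_ani_matrix(sim$genomes)
  species <- dereplicate(sim$genomes, md, 0.05, estimates = est)
  strains <- dereplicate(sim$genomes, md, 0.01, estimates = est)
  got_species <- split(species$clusters$genome_id, species$clusters$cluster_id)
  expect_identical(canon_partition(got_species),
                   canon_partition(sim$truth$species_partition))
  expect_length(strains$representatives, 6L)
  # circular member of each species pair is its representative
  expect_true(all(md$is_circular[match(species$representatives,
                                       md$genome_id)]))

  # representatives at strain level pairwise share <= 99% ANI
  d <- species$distance
  reps <- strains$representatives
  expect_true(all(d[reps, reps][upper.tri(diag(length(reps)))] >= 0.01))

  # idempotence: dereplicating the representatives returns them unchanged
  again <- dereplicate(sim$genomes[species$representatives],
                       md[md$genome_id %in% species$representatives, ],
                       0.05)
  expect_setequal(again$representatives, species$representatives)

  # order invariance: permuting the genomes leaves the result unchanged
  perm <- rev(names(sim$genomes))
  species_perm <- dereplicate(sim$genomes[perm], md, 0.05,
                              estimates = est)
  expect_setequal(species_perm$representatives, species$representatives)

  # single genome dereplicates to itself
  solo <- dereplicate(sim$genomes[1], md[1, ], 0.05)
  expect_identical(solo$representatives, names(sim$genomes)[1])
})
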