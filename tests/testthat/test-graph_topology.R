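seg_df <- function(ids, len = 100L, depth = 10) {
  data.frame(id = ids, length = len, depth = depth,
             sequence = vapply(len, function(n)
               paste(rep("A", n), collapse = ""), character(1)))
}
link_df <- function(from, fo, to, to_o) {
  data.frame(from = from, from_orient = fo, to = to, to_orient = to_o,
             overlap = "0M")
}

test_that("a self-closing segment is circular, orientation mismatch is not", {
  g <- assembly_graph(seg_df("s1"), link_df("s1", "+", "s1", "+"))
  expect_identical(classify_components(g)$class, "circular")
  g2 <- assembly_graph(seg_df("s1"), link_df("s1", "-", "s1", "-"))
  expect_identical(classify_components(g2)$class, "circular")
  # (+,-) joins the sequence to its reverse complement: not a replicon
  g3 <- assembly_graph(seg_df("s1"), link_df("s1", "+", "s1", "-"))
  expect_identical(classify_components(g3)$class, "linear")
})

test_that("cycles make a component tangled; paths and singletons are linear", {
  segs <- seg_df(paste0("s", 1:5), len = c(500L, 400L, 300L, 200L, 100L))
  links <- rbind(link_df("s1", "+", "s2", "+"),
                 link_df("s2", "+", "s3", "+"),
                 link_df("s3", "+", "s1", "+"),
                 link_df("s3", "+", "s4", "+"),
                 link_df("s4", "+", "s5", "+"))
  calls <- classify_components(assembly_graph(segs, links))
  expect_identical(calls$class, "tangled")
  expect_equal(calls$n_segments, 5L)

  path <- classify_components(assembly_graph(
    seg_df(paste0("p", 1:3)),
    rbind(link_df("p1", "+", "p2", "+"), link_df("p2", "+", "p3", "+"))))
  expect_identical(path$class, "linear")
  lone <- classify_components(assembly_graph(seg_df("iso")))
  expect_identical(lone$class, "linear")
  expect_equal(nrow(classify_components(assembly_graph(seg_df(character(0),
                                                              integer(0),
                                                              numeric(0))))),
               0L)
})

test_that("components partition the segments and survive relabeling", {
  set.seed(10)
  segs <- seg_df(paste0("s", 1:7), len = sample(100:500, 7))
  links <- rbind(link_df("s1", "+", "s2", "+"),
                 link_df("s2", "+", "s1", "+"),   # parallel pair: cycle
                 link_df("s3", "+", "s4", "+"),
                 link_df("s5", "+", "s5", "+"))
  g <- assembly_graph(segs, links)
  calls <- classify_components(g)
  all_ids <- unlist(strsplit(calls$segment_ids, ","))
  expect_setequal(all_ids, segs$id)
  expect_equal(anyDuplicated(all_ids), 0L)

  # relabel segments and permute link order: class multiset is unchanged
  relabel <- setNames(paste0("z", 7:1), segs$id)
  segs2 <- segs; segs2$id <- unname(relabel[segs$id])
  links2 <- links[sample(nrow(links)), ]
  links2$from <- unname(relabel[links2$from])
  links2$to <- unname(relabel[links2$to])
  calls2 <- classify_components(assembly_graph(segs2, links2))
  expect_identical(sort(table(calls$class)), sort(table(calls2$class)))
})

test_that("mean depth is length-weighted and the depth table is ordered", {
  segs <- seg_df(c("a", "b"), len = c(100L, 300L), depth = c(10, 30))
  g <- assembly_graph(segs, link_df("a", "+", "b", "+"))
  calls <- classify_components(g)
  expect_equal(calls$mean_depth, (100 * 10 + 300 * 30) / 400)
  tab <- depth_table(g)
  expect_identical(tab$segment_id, c("b", "a"))
  g0 <- assembly_graph(data.frame(id = "x", sequence = "ACGT"))
  expect_warning(depth_table(g0), "depth")
})

test_that("classification recovers the generator's planned classes", {
  sim <- simulate_genomes(3, 2, 4000, 99.0, seed = 51)
  ids <- names(sim$genomes)
  sp <- setNames(sim$truth$genomes$species_id, ids)
  plan <- setNames(c("tangled", "tangled", "circular", "linear", "circular",
                     "linear"), ids)
  g <- simulate_graph(sim$genomes, plan, sim$truth$abundances, seed = 52,
                      species = sp)
  calls <- classify_components(g$graph)
  truth_by_segs <- setNames(g$truth$class, g$truth$segment_ids)
  key <- vapply(strsplit(calls$segment_ids, ","), function(x)
    paste(sort(x), collapse = ","), character(1))
  truth_key <- vapply(strsplit(g$truth$segment_ids, ","), function(x)
    paste(sort(x), collapse = ","), character(1))
  expect_setequal(key, truth_key)
  expect_identical(calls$class[match(truth_key, key)], g$truth$class)
})

test_that("per-class export writes class FASTAs and per-component tangles", {
  sim <- simulate_genomes(2, 2, 3000, 99.0, seed = 61)
  ids <- names(sim$genomes)
  sp <- setNames(sim$truth$genomes$species_id, ids)
  plan <- setNames(c("tangled", "tangled", "circular", "linear"), ids)
  g <- simulate_graph(sim$genomes, plan, sim$truth$abundances, seed = 62,
                      species = sp)
  calls <- classify_components(g$graph)
  out <- withr::local_tempdir()
  paths <- export_by_class(g$graph, calls, out)
  expect_true(file.exists(paths[["circular"]]))
  expect_length(read_fasta(paths[["circular"]]), 1L)
  tangled_files <- grep("^tangled_comp", names(paths), value = TRUE)
  expect_length(tangled_files, 1L)
  # segments without sequences cannot be exported
  g$graph$segments$sequence[1] <- NA_character_
  expect_error(export_by_class(g$graph, calls, out), "without sequence")
})
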