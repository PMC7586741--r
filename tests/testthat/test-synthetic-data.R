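test_that("toy genomes respect bounds, determinism and expected total length", {
  g1 <- generate_toy_genome(1, 500, seed = 3)
  expect_equal(nrow(g1), 1)
  expect_gte(g1$length, 500)

  expect_identical(generate_toy_genome(20, 5000, seed = 11),
                   generate_toy_genome(20, 5000, seed = 11))
  expect_false(identical(generate_toy_genome(20, 5000, seed = 11),
                         generate_toy_genome(20, 5000, seed = 12)))

  g <- generate_toy_genome(50, 20000, seed = 1)
  expect_true(abs(sum(g$length) - 1e6) / 1e6 < 0.3)

  expect_error(generate_toy_genome(0, 5000, seed = 1))
  expect_error(generate_toy_genome(5, 100, seed = 1))
})

test_that("genome sequences match declared lengths", {
  g <- generate_toy_genome(4, 1500, seed = 5, with_sequences = TRUE)
  seqs <- attr(g, "sequences")
  expect_identical(unname(nchar(seqs[g$contig])), g$length)
  expect_true(all(strsplit(seqs[[1]], "")[[1]] %in% c("A", "C", "G", "T")))
})

test_that("annotations are in-bounds, disjoint, and honor degenerate arguments", {
  genome <- generate_toy_genome(10, 100000, seed = 2)

  empty <- generate_annotation(genome, 0, seed = 2)
  expect_equal(nrow(empty), 0)

  ann <- generate_annotation(genome, 100, 2000, te_fraction = 0, seed = 2)
  genes <- ann[ann$type == "gene", ]
  expect_equal(nrow(genes), 100)
  expect_false(any(ann$type == "transposable_element"))

  # brute-force pairwise overlap scan
  for (ctg in unique(genes$contig)) {
    gg <- genes[genes$contig == ctg, ]
    if (nrow(gg) < 2) next
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }

  # within contig bounds
  joined <- merge(ann, genome, by = "contig")
  expect_true(all(joined$start >= 0 & joined$end <= joined$length))

  with_te <- generate_annotation(genome, 50, 2000, te_fraction = 0.2, seed = 2)
  tes <- with_te[with_te$type == "transposable_element", ]
  expect_gt(nrow(tes), 0)
  # TEs avoid gene bodies
  genes2 <- with_te[with_te$type == "gene", ]
  for (i in seq_len(nrow(tes))) {
    expect_equal(brute_overlap_count(genes2, tes$contig[i],
                                     tes$start[i], tes$end[i]), 0)
  }

  expect_error(generate_annotation(genome, 1e6, 2000, seed = 2),
               "cannot pack")
})

test_that("fragment generation is deterministic, in bounds and density-faithful", {
  st <- toy_study(seed = 4)
  frags <- st$fragments[[1]]
  expect_gt(nrow(frags), 0)
  joined <- merge(frags, st$genome, by = "contig")
  expect_true(all(joined$start >= 0 & joined$end <= joined$length &
                    joined$start < joined$end))

  st2 <- toy_study(seed = 4)
  expect_identical(frags, st2$fragments[[1]])

  empty <- generate_fragments(st$genome, st$annotation, st$truth,
                              n_fragments = 0, seed = 4)
  # no background and no extras only when fold extras are also zero;
  # with n_fragments = 0 the background rate is 0 so extras are 0 too
  expect_equal(nrow(empty[[1]]), 0)

  bad_truth <- ground_truth(marked_genes = "no_such_gene")
  expect_error(generate_fragments(st$genome, st$annotation, bad_truth,
                                  n_fragments = 10, seed = 1),
               "not in annotation")
})

test_that("null design (fold 1) leaves marked and unmarked genes indistinguishable", {
  genome <- generate_toy_genome(10, 100000, seed = 9)
  annotation <- generate_annotation(genome, 200, 1000, seed = 9)
  gene_ids <- annotation$feature_id
  marked <- withr::with_seed(1, sample(gene_ids, 100))
  truth <- ground_truth(marked_genes = marked, enrichment_fold = 1)
  frags <- generate_fragments(genome, annotation, truth,
                              n_fragments = 20000, seed = 9)[[1]]
  cov_m <- gene_overlap_counts(frags, annotation, marked)
  cov_u <- gene_overlap_counts(frags, annotation, setdiff(gene_ids, marked))
  p <- wilcox.test(cov_m, cov_u)$p.value
  expect_gt(p, 0.01)
})

test_that("planted enrichment produces the designed coverage contrast across seeds", {
  ok <- vapply(1:20, function(s) {
    st <- toy_study(seed = 100 + s, n_contigs = 5, mean_len = 40000,
                    n_genes = 20, n_marked = 3, enrichment_fold = 8,
                    n_fragments = 3000)
    frags <- st$fragments[[1]]
    marked <- st$truth$marked_genes[[1]]
    m <- mean(gene_overlap_counts(frags, st$annotation, marked))
    u <- mean(gene_overlap_counts(frags, st$annotation,
                                  setdiff(st$gene_ids, marked)))
    m >= 4 * u
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("expression designs hit their closed-form extremes and separate entropies", {
  genome <- generate_toy_genome(5, 100000, seed = 6)
  annotation <- generate_annotation(genome, 100, 1000, seed = 6)
  ids <- annotation$feature_id
  truth <- ground_truth(marked_genes = ids[1], enrichment_fold = 2,
                        specific_genes = ids[1:50], broad_genes = ids[51:100])

  noiseless <- generate_expression(annotation, 8, truth, seed = 6,
                                   leakage = 0, noise_sd = 0)
  m <- as.matrix(noiseless[, -1])
  broad_row <- m[match(ids[60], noiseless$gene_id), ]
  expect_true(all(broad_row == broad_row[1]))
  spec_row <- m[match(ids[10], noiseless$gene_id), ]
  expect_equal(sum(spec_row > 0), 1)

  noisy <- generate_expression(annotation, 8, truth, seed = 6)
  ent <- expression_entropy(noisy)
  mean_spec <- mean(ent$entropy[ent$gene_id %in% ids[1:50]])
  mean_broad <- mean(ent$entropy[ent$gene_id %in% ids[51:100]])
  expect_lt(mean_spec, mean_broad)
})

test_that("functional maps honor orphan fraction and plant term enrichment", {
  genome <- generate_toy_genome(5, 100000, seed = 8)
  annotation <- generate_annotation(genome, 100, 1000, seed = 8)
  truth <- ground_truth(marked_genes = annotation$feature_id[1:20],
                        enrichment_fold = 2,
                        planted_go_terms = "GO:0000001")

  all_orphans <- generate_functional_maps(annotation, 10, truth, seed = 8,
                                          orphan_fraction = 1)
  expect_equal(nrow(all_orphans$homology), 0)

  maps <- generate_functional_maps(annotation, 10, truth, seed = 8,
                                   orphan_fraction = 0.1, odds_ratio = 10)
  expect_true(all(maps$go$ref_gene_id %in% maps$homology$ref_gene_id))
  targets_hom <- maps$homology$ref_gene_id[
    maps$homology$gene_id %in% truth$marked_genes[[1]]]
  planted_rate_target <- mean(
    targets_hom %in% maps$go$ref_gene_id[maps$go$go_id == "GO:0000001"])
  planted_rate_other <- mean(
    setdiff(maps$homology$ref_gene_id, targets_hom) %in%
      maps$go$ref_gene_id[maps$go$go_id == "GO:0000001"])
  expect_gt(planted_rate_target, planted_rate_other)
})

test_that("fixed seed reproduces byte-identical output files", {
  st <- toy_study(seed = 13, n_contigs = 3, n_genes = 6, n_fragments = 500)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fragments_bed(st$fragments[[1]], file.path(d1, "f.bed"))
  st_again <- toy_study(seed = 13, n_contigs = 3, n_genes = 6,
                        n_fragments = 500)
  write_fragments_bed(st_again$fragments[[1]], file.path(d2, "f.bed"))
  expect_identical(unname(tools::md5sum(file.path(d1, "f.bed"))),
                   unname(tools::md5sum(file.path(d2, "f.bed"))))
})
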