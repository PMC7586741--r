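test_that("gene regions extend by 500 bp and clip at contig bounds", {
  genome <- tibble::tibble(contig = "c1", length = 3000L)
  ann <- tibble::tibble(feature_id = c("g1", "g2"), contig = "c1",
                        start = c(200L, 2000L), end = c(1200L, 2900L),
                        type = "gene")
  r <- gene_regions(ann, genome)
  expect_equal(r$start, c(0L, 1500L))
  expect_equal(r$end, c(1700L, 3000L))
  expect_equal(r$length_ext, c(1700L, 1500L))
})

test_that("enrichment calls follow half-open overlap and match brute force", {
  genome <- tibble::tibble(contig = "c1", length = 100000L)
  ann <- tibble::tibble(feature_id = "g1", contig = "c1",
                        start = 1000L, end = 3000L, type = "gene")
  r <- gene_regions(ann, genome)  # region [500, 3500)
  abutting <- tibble::tibble(contig = "c1", start = 3500L, end = 4000L,
                             width = 500L, n_bins = 1L, min_q = 1e-30)
  expect_false(assign_enriched_genes(r, abutting)$enriched)
  inside <- dplyr::mutate(abutting, start = 3499L)
  expect_true(assign_enriched_genes(r, inside)$enriched)
  expect_false(assign_enriched_genes(r, abutting[0, ])$enriched)

  # 200 genes, 40 random peaks: all-pairs scan oracle
  genome2 <- generate_toy_genome(10, 100000, seed = 41)
  ann2 <- generate_annotation(genome2, 200, 1000, seed = 41)
  regions <- gene_regions(ann2, genome2)
  peaks <- withr::with_seed(41, {
    idx <- sample.int(nrow(genome2), 40, replace = TRUE, prob = genome2$length)
    s <- floor(runif(40) * (genome2$length[idx] - 1000))
    tibble::tibble(contig = genome2$contig[idx], start = as.integer(s),
                   end = as.integer(s + 1000L))
  })
  got <- assign_enriched_genes(regions, peaks)
  oracle <- vapply(seq_len(nrow(regions)), function(i) {
    brute_overlap_count(peaks, regions$contig[i],
                        regions$start[i], regions$end[i]) > 0
  }, logical(1))
  expect_equal(got$enriched, oracle)
})

test_that("FPKB follows its closed form and an independent recomputation", {
  genome <- tibble::tibble(contig = "c1", length = 10000L)
  region <- tibble::tibble(gene_id = "g1", contig = "c1",
                           start = 1000L, end = 4000L, length_ext = 3000L)
  frags <- tibble::tibble(contig = "c1", start = rep(1500L, 30),
                          end = rep(1800L, 30))
  got <- quantify_fpkb(frags, region, n_total = 1e7)
  expect_equal(got$fpkb, 30 / 3 / 0.01)  # 1000

  none <- quantify_fpkb(frags[0, ], region, n_total = 1e7)
  expect_equal(none$fpkb, 0)

  expect_warning(zero <- quantify_fpkb(frags[0, ], region, n_total = 0),
                 "n_total")
  expect_equal(zero$fpkb, 0)

  st <- toy_study(seed = 42, n_fragments = 3000)
  regions <- gene_regions(st$annotation, st$genome)
  frags2 <- st$fragments[[1]]
  got2 <- quantify_fpkb(frags2, regions)
  oracle <- vapply(seq_len(nrow(regions)), function(i) {
    k <- brute_overlap_count(frags2, regions$contig[i],
                             regions$start[i], regions$end[i])
    k / (regions$length_ext[i] / 1000) / (nrow(frags2) / 1e9)
  }, numeric(1))
  expect_equal(got2$fpkb, oracle, tolerance = 1e-9)
})

test_that("FPKB is invariant to doubling both counts and depth", {
  st <- toy_study(seed = 43, n_fragments = 2000)
  regions <- gene_regions(st$annotation, st$genome)
  frags <- st$fragments[[1]]
  doubled <- dplyr::bind_rows(frags, frags)
  a <- quantify_fpkb(frags, regions)$fpkb
  b <- quantify_fpkb(doubled, regions)$fpkb
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("fold-change calls respect the inclusive threshold and the pseudocount", {
  mk <- function(fpkb) tibble::tibble(gene_id = paste0("g", seq_along(fpkb)),
                                      fpkb = fpkb)
  # exact inclusive boundary: (3 + 1) / (1 + 1) = 2
  fc <- pairwise_fold_calls(mk(1), mk(3), pseudo = 1)
  expect_equal(fc$gained, "g1")
  fc2 <- pairwise_fold_calls(mk(5.1), mk(10), pseudo = 1e-9)
  expect_equal(length(fc2$gained), 0)
  fc3 <- pairwise_fold_calls(mk(0), mk(10), pseudo = 0.1)
  expect_equal(fc3$gained, "g1")

  # gained and lost are disjoint on random data
  withr::with_seed(44, {
    a <- mk(rexp(200, 1 / 50))
    b <- mk(rexp(200, 1 / 50))
  })
  fc4 <- pairwise_fold_calls(a, b, pseudo = 1)
  expect_equal(length(intersect(fc4$gained, fc4$lost)), 0)
  expect_equal(nrow(tidy(fc4)), 200)
  expect_equal(glance(fc4)$n_gained, length(fc4$gained))
})

test_that("marked-set algebra matches enumeration", {
  s <- paste0("g", 1:10)
  same <- set_difference_marked(s, s)
  expect_equal(length(same$a_only), 0)
  expect_equal(length(same$b_only), 0)
  disj <- set_difference_marked(s[1:5], s[6:10])
  expect_equal(length(disj$both), 0)

  withr::with_seed(45, {
    universe <- paste0("g", 1:500)
    a <- sample(universe, 200)
    b <- sample(universe, 150)
  })
  d <- set_difference_marked(a, b)
  oracle_a_only <- sum(vapply(universe, function(g) {
    g %in% a && !(g %in% b)
  }, logical(1)))
  expect_equal(length(d$a_only), oracle_a_only)
  expect_equal(length(d$a_only) + length(d$both), length(unique(a)))
})

test_that("exclusive intersection cells partition the union", {
  n <- 25
  s <- paste0("g", seq_len(n))
  identical5 <- setNames(replicate(5, s, simplify = FALSE), paste0("t", 1:5))
  ic <- intersection_counts(identical5)
  expect_equal(nrow(ic), 1)
  expect_equal(ic$n, n)
  expect_equal(ic$degree, 5L)

  disj <- list(a = paste0("g", 1:5), b = paste0("h", 1:7))
  ic2 <- intersection_counts(disj)
  expect_equal(sort(ic2$n), c(5L, 7L))
  expect_equal(attr(ic2, "core_size"), 0L)

  withr::with_seed(46, {
    universe <- paste0("g", 1:1000)
    sets <- setNames(lapply(1:5, function(i) sample(universe, 300)),
                     paste0("t", 1:5))
  })
  ic3 <- intersection_counts(sets)
  expect_equal(sum(ic3$n), length(unique(unlist(sets))))
  # bitmask enumeration oracle
  mask <- vapply(universe, function(g) {
    sum(2^(which(vapply(sets, function(s) g %in% s, logical(1))) - 1))
  }, numeric(1))
  mask <- mask[mask > 0]
  oracle_cells <- table(mask)
  key_of <- function(bits) paste(names(sets)[bits], collapse = "&")
  for (m in names(oracle_cells)) {
    bits <- which(bitwAnd(as.integer(m), 2^(0:4)) > 0)
    expect_equal(ic3$n[ic3$combination == key_of(bits)],
                 as.integer(oracle_cells[[m]]))
  }
})

test_that("the paired signal test matches the hand formula and its conventions", {
  same <- paired_t_signal(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(2, 4, 6, 8); b <- a - c(1, 2, 3, 4)
  got <- paired_t_signal(a, b)
  d <- c(1, 2, 3, 4)
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(got$t, t_oracle, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_oracle), 3), tolerance = 1e-12)
  # agreement with the reference implementation on non-degenerate input
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  degen <- paired_t_signal(c(1, 2, 3), c(3, 4, 5))
  expect_true(is.infinite(degen$t))
  expect_equal(degen$p, 0)
  expect_true(degen$degenerate)
  expect_true(glance(degen)$degenerate)

  expect_error(paired_t_signal(1, 1), "at least 2")
})
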