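test_that("coverage tracks normalize by total fragments", {
  genome <- tibble::tibble(contig = "c1", length = 100L)
  one <- tibble::tibble(contig = "c1", start = 10L, end = 20L)
  tr <- build_coverage(one, genome)
  v <- as.numeric(tr$coverage[["c1"]])
  expect_equal(v[11:20], rep(1, 10))
  expect_equal(sum(v), 10)

  two <- dplyr::bind_rows(one, one)
  tr2 <- build_coverage(two, genome)
  expect_equal(as.numeric(tr2$coverage[["c1"]])[11:20], rep(1, 10))

  expect_error(build_coverage(one[0, ], genome), "empty")
})

test_that("coverage matches a per-bp brute-force scan and integrates correctly", {
  genome <- tibble::tibble(contig = "c1", length = 5000L)
  frags <- withr::with_seed(71, {
    s <- sample.int(4800L, 200, replace = TRUE) - 1L
    tibble::tibble(contig = "c1", start = s,
                   end = pmin(s + sample.int(400L, 200, replace = TRUE), 5000L))
  })
  tr <- build_coverage(frags, genome)
  v <- as.numeric(tr$coverage[["c1"]])
  oracle <- numeric(5000)
  for (i in seq_len(nrow(frags))) {
    idx <- (frags$start[i] + 1):frags$end[i]
    oracle[idx] <- oracle[idx] + 1
  }
  expect_equal(v, oracle / nrow(frags))
  expect_equal(sum(v), sum(frags$end - frags$start) / nrow(frags))
})

test_that("region selection is strictly above threshold with <101 bp merging", {
  th <- 8.0e-7
  flat <- list(c1 = S4Vectors::Rle(th, 1000))
  expect_equal(nrow(select_signal_regions(flat, threshold = th)), 0)

  mk <- function(gap) {
    list(c1 = S4Vectors::Rle(
      c(0, 1, 0, 1, 0), c(100, 50, gap, 50, 100)
    ) * 1e-6)
  }
  merged <- select_signal_regions(mk(100), threshold = th)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$width, 200L)
  split <- select_signal_regions(mk(101), threshold = th)
  expect_equal(nrow(split), 2)
})

test_that("random step functions match a run-length-encoding oracle", {
  th <- 0.5
  withr::with_seed(72, {
    for (case in 1:100) {
      n_runs <- sample(3:12, 1)
      vals <- runif(n_runs)
      lens <- sample(20:300, n_runs, replace = TRUE)
      v <- rep(vals, lens)
      track <- list(c1 = S4Vectors::Rle(v))
      got <- select_signal_regions(track, threshold = th, merge_gap = 101)
      # oracle: scan the decoded vector, then merge gaps < 101
      above <- v > th
      r <- rle(above)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      runs <- data.frame(start = starts[r$values] - 1, end = ends[r$values])
      if (nrow(runs) > 1) {
        merged <- runs[1, ]
        for (i in 2:nrow(runs)) {
          if (runs$start[i] - merged$end[nrow(merged)] < 101) {
            merged$end[nrow(merged)] <- runs$end[i]
          } else merged <- rbind(merged, runs[i, ])
        }
        runs <- merged
      }
      expect_equal(nrow(got), nrow(runs))
      if (nrow(runs) > 0) {
        expect_equal(got$start, as.integer(runs$start))
        expect_equal(got$end, as.integer(runs$end))
        if (nrow(got) > 1) {
          expect_true(all(got$start[-1] - got$end[-nrow(got)] >= 101))
        }
      }
    }
  })
})

test_that("matched background preserves the length multiset and avoids queries", {
  genome <- generate_toy_genome(20, 50000, seed = 73)
  regions <- withr::with_seed(73, {
    idx <- sample.int(20, 100, replace = TRUE, prob = genome$length)
    L <- sample.int(2000L, 100, replace = TRUE)
    s <- floor(runif(100) * pmax(1, genome$length[idx] - L))
    tibble::tibble(contig = genome$contig[idx], start = as.integer(s),
                   end = as.integer(pmin(s + L, genome$length[idx])))
  })
  bg <- sample_matched_background(regions, genome, seed = 7)
  expect_equal(sort(bg$end - bg$start), sort(regions$end - regions$start))
  # zero query overlaps
  for (i in seq_len(nrow(bg))) {
    expect_equal(brute_overlap_count(regions, bg$contig[i],
                                     bg$start[i], bg$end[i]), 0)
  }
  # in bounds and deterministic
  joined <- merge(bg, genome, by = "contig")
  expect_true(all(joined$start >= 0 & joined$end <= joined$length))
  expect_identical(bg, sample_matched_background(regions, genome, seed = 7))

  too_long <- tibble::tibble(contig = "x", start = 0L, end = 10000000L)
  expect_error(sample_matched_background(too_long, genome, seed = 1),
               "exceeds the longest contig")
})

test_that("FASTA export writes exact region sequences with coordinate headers", {
  genome <- generate_toy_genome(3, 1000, seed = 74, with_sequences = TRUE)
  seqs <- attr(genome, "sequences")
  regions <- tibble::tibble(contig = genome$contig[1],
                            start = 0L, end = 5L)
  path <- withr::local_tempfile(fileext = ".fasta")
  dna <- export_region_fasta(regions, genome, path)
  expect_equal(as.character(dna[[1]]), substr(seqs[[1]], 1, 5))
  expect_equal(names(dna), sprintf("%s:0-5", genome$contig[1]))

  parsed <- Biostrings::readDNAStringSet(path)
  expect_equal(as.character(parsed[[1]]), substr(seqs[[1]], 1, 5))

  empty <- export_region_fasta(regions[0, ], genome,
                               withr::local_tempfile(fileext = ".fasta"))
  expect_equal(length(empty), 0)

  many <- withr::with_seed(74, {
    idx <- sample.int(3, 20, replace = TRUE)
    L <- sample.int(50L, 20, replace = TRUE)
    s <- floor(runif(20) * (genome$length[idx] - L))
    tibble::tibble(contig = genome$contig[idx], start = as.integer(s),
                   end = as.integer(s + L))
  })
  dna20 <- export_region_fasta(many, genome,
                               withr::local_tempfile(fileext = ".fasta"))
  expect_equal(unname(Biostrings::width(dna20)), many$end - many$start)

  oob <- tibble::tibble(contig = genome$contig[1], start = 0L,
                        end = genome$length[1] + 1L)
  expect_error(export_region_fasta(oob, genome,
                                   withr::local_tempfile(fileext = ".fasta")),
               "beyond sequence bounds")
})
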