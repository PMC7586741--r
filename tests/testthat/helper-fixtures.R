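# Small synthetic study built entirely in code; every test that needs a
# genome/annotation/fragments combination goes through here so sizes are
# consistent and cheap.

toy_study <- function(seed = 1, n_contigs = 10, mean_len = 30000,
                      n_genes = 40, gene_len = 2000, n_marked = 4,
                      enrichment_fold = 8, n_fragments = 5000,
                      frag_len_mean = 300, long_frac = 0,
                      n_samples = 1) {
  genome <- generate_toy_genome(n_contigs, mean_len, seed = seed)
  annotation <- generate_annotation(genome, n_genes, gene_len, seed = seed)
  gene_ids <- annotation$feature_id[annotation$type == "gene"]
  marked <- withr::with_seed(child_seed(seed, "test_truth"), {
    lapply(seq_len(n_samples), function(i) sample(gene_ids, n_marked))
  })
  names(marked) <- paste0("s", seq_len(n_samples))
  truth <- ground_truth(marked_genes = marked,
                        enrichment_fold = enrichment_fold)
  fragments <- generate_fragments(genome, annotation, truth,
                                  n_fragments = n_fragments,
                                  frag_len_mean = frag_len_mean,
                                  long_frac = long_frac, seed = seed)
  list(genome = genome, annotation = annotation, truth = truth,
       gene_ids = gene_ids, fragments = fragments)
}

# Brute-force interval overlap count: how many of the intervals in `ivs`
# (tibble with start/end, same contig) overlap [s, e) by >= 1 bp.
brute_overlap_count <- function(ivs, contig, s, e) {
  sum(ivs$contig == contig & ivs$start < e & ivs$end > s)
}

# Independent upper-tail binomial oracle: direct log-space term summation.
binom_upper_tail_oracle <- function(k, n, p0) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0)))
}

# Independent BH oracle: textbook step-up with cumulative minimum.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Independent upper-tail hypergeometric oracle by combinatorial enumeration.
hyper_upper_tail_oracle <- function(k, K, n_bg, n_smp) {
  j <- k:min(K, n_smp)
  sum(choose(K, j) * choose(n_bg - K, n_smp - j)) / choose(n_bg, n_smp)
}

# Mean per-gene fragment coverage (overlap counts) for a set of genes.
gene_overlap_counts <- function(fragments, annotation, genes) {
  vapply(genes, function(g) {
    row <- annotation[annotation$feature_id == g, ]
    brute_overlap_count(fragments, row$contig, row$start, row$end)
  }, numeric(1))
}
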