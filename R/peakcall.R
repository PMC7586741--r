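#' Tile a genome into fixed-width bins
#'
#' Each contig is split into consecutive `bin_size` bp bins; the terminal bin
#' is truncated at the contig end, so bin widths sum exactly to the contig
#' length.
#'
#' @param genome Genome tibble (`contig`, `length`).
#' @param bin_size Bin width in bp (default 500).
#' @return A tibble (`contig`, `start`, `end`, `width`), 0-based half-open.
#' @export
#' @examples
#' bin_genome(tibble::tibble(contig = "c1", length = 1250L), 500)
bin_genome <- function(genome, bin_size = 500) {
  stopifnot(bin_size >= 1, all(genome$length >= 1))
  bins <- lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    starts <- seq.int(0L, L - 1L, by = bin_size)
    tibble(contig = genome$contig[i], start = as.integer(starts),
           end = as.integer(pmin(starts + bin_size, L)))
  })
  out <- dplyr::bind_rows(bins)
  out$width <- out$end - out$start
  out
}

#' Count fragments overlapping each bin
#'
#' A fragment contributes to every bin it overlaps by at least one base, so
#' a fragment spanning a bin boundary is counted in both bins and per-bin
#' counts may sum to more than the number of fragments.
#'
#' @param fragments Fragment tibble.
#' @param bins Bin tibble from [bin_genome()].
#' @return `bins` with an added `count` column.
#' @export
count_per_bin <- function(fragments, bins) {
  assert_fragments(fragments)
  unknown <- setdiff(unique(fragments$contig), unique(bins$contig))
  if (length(unknown) > 0) {
    warning("skipping fragments on contig(s) absent from the bin grid: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    fragments <- fragments[!fragments$contig %in% unknown, , drop = FALSE]
  }
  bin_gr <- granges_from_0based(bins$contig, bins$start, bins$end)
  frag_gr <- granges_from_0based(fragments$contig, fragments$start, fragments$end)
  bins$count <- GenomicRanges::countOverlaps(bin_gr, frag_gr)
  bins
}

#' Exact binomial enrichment test per bin
#'
#' Under a uniform-placement null, the probability that one fragment overlaps
#' a given bin of width `w` is `p0 = w / effective_genome_length`; the number
#' of fragments in the bin is then binomial with size `n_total`.  The
#' reported p-value is the one-sided upper tail `P(X >= count)`, so only
#' enrichment (never depletion) can become significant.  Bins with zero
#' count get p = 1.
#'
#' @param bin_counts Bin tibble with a `count` column from [count_per_bin()].
#' @param n_total Total number of (filtered) fragments in the sample.
#' @param effective_genome_length Genome length used by the null; defaults to
#'   the summed bin widths (i.e. the full assembly length).
#' @return `bin_counts` with an added `p_value` column.
#' @export
binomial_test_bins <- function(bin_counts, n_total,
                               effective_genome_length = sum(bin_counts$width)) {
  stopifnot("count" %in% names(bin_counts),
            effective_genome_length >= max(bin_counts$width))
  if (n_total == 0) {
    warning("n_total is 0; all p-values set to 1", call. = FALSE)
    bin_counts$p_value <- 1
    return(bin_counts)
  }
  p0 <- bin_counts$width / effective_genome_length
  k <- bin_counts$count
  p <- stats::pbinom(k - 1, size = n_total, prob = p0, lower.tail = FALSE)
  p[k == 0] <- 1
  bin_counts$p_value <- p
  bin_counts
}

#' Benjamini-Hochberg adjustment of per-bin p-values
#'
#' Step-up false-discovery-rate control applied over the whole genome-wide
#' family of bins in one pass (zero-count bins included).  The output vector
#' matches the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values.
#' @export
adjust_bh <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Call peaks from significant bins
#'
#' Bins with `q_value <= fdr_threshold` become seed intervals; seed intervals
#' on the same contig separated by a gap strictly shorter than `merge_gap`
#' are merged transitively.  With contiguous 500 bp bins inter-seed gaps are
#' 0 or >= 500 bp, so the default 100 bp rule only ever joins adjacent bins,
#' but the merge is implemented generically over arbitrary seed intervals.
#'
#' @param bin_stats Bin tibble with `q_value` (and optionally `count`).
#' @param fdr_threshold Selection threshold on the q-value (default 1e-25).
#' @param merge_gap Gaps strictly smaller than this many bp are merged.
#' @return A tibble of peaks (`contig`, `start`, `end`, `width`, `n_bins`,
#'   `min_q`), disjoint per contig and separated by >= `merge_gap`.
#' @export
call_peaks <- function(bin_stats, fdr_threshold = 1e-25, merge_gap = 100) {
  stopifnot("q_value" %in% names(bin_stats), merge_gap >= 1)
  sig <- bin_stats[!is.na(bin_stats$q_value) &
                     bin_stats$q_value <= fdr_threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  width = integer(), n_bins = integer(), min_q = double()))
  }
  seed_gr <- granges_from_0based(sig$contig, sig$start, sig$end)
  peak_gr <- GenomicRanges::reduce(seed_gr, min.gapwidth = merge_gap)
  hits <- GenomicRanges::findOverlaps(seed_gr, peak_gr)
  min_q <- tapply(sig$q_value[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), min)
  n_bins <- tabulate(S4Vectors::subjectHits(hits), nbins = length(peak_gr))
  out <- tibble_from_granges(peak_gr)
  out$width <- out$end - out$start
  out$n_bins <- as.integer(n_bins)
  out$min_q <- as.numeric(min_q[as.character(seq_along(peak_gr))])
  dplyr::arrange(out, .data$contig, .data$start)
}

#' Run the complete binned peak-calling stage on one sample
#'
#' Convenience wrapper chaining [bin_genome()], [count_per_bin()],
#' [binomial_test_bins()], [adjust_bh()] and [call_peaks()] with the
#' pipeline's default parameters (500 bp bins, FDR <= 1e-25, < 100 bp merge).
#'
#' @inheritParams count_per_bin
#' @inheritParams binomial_test_bins
#' @inheritParams call_peaks
#' @param genome Genome tibble.
#' @param bin_size Bin width in bp.
#' @return A list with `bins` (per-bin table including `p_value`, `q_value`)
#'   and `peaks`.
#' @export
peakcall_sample <- function(fragments, genome, bin_size = 500,
                            fdr_threshold = 1e-25, merge_gap = 100,
                            effective_genome_length = sum(genome$length)) {
  bins <- bin_genome(genome, bin_size) |>
    count_per_bin(fragments = fragments) |>
    binomial_test_bins(n_total = nrow(fragments),
                       effective_genome_length = effective_genome_length)
  bins$q_value <- adjust_bh(bins$p_value)
  list(bins = bins, peaks = call_peaks(bins, fdr_threshold, merge_gap))
}
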