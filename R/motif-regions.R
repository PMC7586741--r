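#' Build a depth-normalized per-base coverage track
#'
#' Coverage at each base is the number of fragments overlapping it divided by
#' the total fragment count, i.e. reads per total reads per bp — the unit in
#' which the signal threshold for motif-region selection is expressed.
#'
#' @param fragments Fragment tibble.
#' @param genome Genome tibble (defines the track's extent).
#' @param n_total Total fragment count `N`; defaults to `nrow(fragments)`.
#' @return A `coverage_track` object wrapping one run-length-encoded vector
#'   per contig plus `n_total`.
#' @export
build_coverage <- function(fragments, genome, n_total = nrow(fragments)) {
  assert_fragments(fragments)
  if (n_total == 0) stop("cannot build coverage from an empty fragment set",
                         call. = FALSE)
  sl <- genome_seqlengths(genome)
  gr <- granges_from_0based(fragments$contig, fragments$start, fragments$end,
                            seqlengths = sl)
  cov <- GenomicRanges::coverage(gr) / n_total
  structure(list(coverage = cov, n_total = n_total), class = "coverage_track")
}

#' Select high-signal regions from a coverage track
#'
#' Maximal runs of bases with coverage strictly greater than `threshold`
#' become candidate regions; on each contig, regions separated by a gap
#' strictly shorter than `merge_gap` bp are merged transitively.  Bases with
#' coverage exactly equal to the threshold are not selected.
#'
#' @param track A `coverage_track` from [build_coverage()], or a named list /
#'   `RleList` of per-contig run-length-encoded coverage vectors.
#' @param threshold Signal threshold in reads per total reads (default
#'   8.0e-7).
#' @param merge_gap Gaps strictly smaller than this many bp are merged
#'   (default 101).
#' @return A tibble of disjoint regions (`contig`, `start`, `end`, `width`),
#'   0-based half-open, separated by >= `merge_gap` per contig.
#' @export
select_signal_regions <- function(track, threshold = 8.0e-7, merge_gap = 101) {
  stopifnot(threshold > 0, merge_gap >= 1)
  cov <- if (inherits(track, "coverage_track")) track$coverage else track
  recs <- lapply(names(cov), function(ctg) {
    v <- IRanges::slice(cov[[ctg]], lower = threshold, includeLower = FALSE)
    r <- IRanges::reduce(IRanges::ranges(v), min.gapwidth = merge_gap)
    if (length(r) == 0) return(NULL)
    tibble(contig = ctg, start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  out <- dplyr::bind_rows(recs)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  width = integer()))
  }
  out$width <- out$end - out$start
  dplyr::arrange(out, .data$contig, .data$start)
}

#' Sample length-matched background regions
#'
#' For every query region one background interval of identical length is
#' placed uniformly at random on the genome (contigs long enough to hold it,
#' weighted by the number of eligible start positions), so the background
#' length multiset exactly equals the query length multiset.  By default
#' background intervals must not overlap any query region; placement is
#' retried up to `max_tries` times before failing with the offending length.
#'
#' @param regions Query regions tibble (`contig`, `start`, `end`).
#' @param genome Genome tibble.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @param exclude_queries If `TRUE` (default), reject background placements
#'   overlapping any query region.
#' @param max_tries Retry budget per region.
#' @return A tibble of background regions (`contig`, `start`, `end`,
#'   `width`).
#' @export
sample_matched_background <- function(regions, genome, seed,
                                      exclude_queries = TRUE,
                                      max_tries = 1000) {
  if (nrow(regions) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  width = integer()))
  }
  lens <- regions$end - regions$start
  if (max(lens) > max(genome$length)) {
    stop("region length ", max(lens), " exceeds the longest contig",
         call. = FALSE)
  }
  sl <- genome_seqlengths(genome)
  query_gr <- granges_from_0based(regions$contig, regions$start, regions$end,
                                  seqlengths = sl)
  with_stream(seed, "matched_background", {
    placed <- lapply(lens, function(L) {
      eligible <- genome[genome$length >= L, , drop = FALSE]
      w <- eligible$length - L + 1
      for (i in seq_len(max_tries)) {
        idx <- sample.int(nrow(eligible), 1, prob = w)
        start <- sample.int(w[idx], 1) - 1L
        cand <- tibble(contig = eligible$contig[idx],
                       start = as.integer(start),
                       end = as.integer(start + L))
        if (!exclude_queries) return(cand)
        hit <- GenomicRanges::countOverlaps(
          granges_from_0based(cand$contig, cand$start, cand$end,
                              seqlengths = sl),
          query_gr)
        if (hit == 0) return(cand)
      }
      stop("could not place a background region of length ", L,
           " after ", max_tries, " tries", call. = FALSE)
    })
    out <- dplyr::bind_rows(placed)
    out$width <- out$end - out$start
    out
  })
}

#' Export region sequences as FASTA
#'
#' Writes one record per region with header `contig:start-end` (0-based
#' half-open coordinates) and the uppercase sequence, ready to serve as the
#' query (or background) input of an external motif-discovery run.
#'
#' @param regions Regions tibble (`contig`, `start`, `end`).
#' @param genome Genome tibble carrying sequences (see
#'   [generate_toy_genome()] with `with_sequences = TRUE`).
#' @param path Output FASTA path.
#' @return The `DNAStringSet` written, invisibly.
#' @export
export_region_fasta <- function(regions, genome, path) {
  seqs <- attr(genome, "sequences")
  if (is.null(seqs)) stop("genome carries no sequences", call. = FALSE)
  if (nrow(regions) == 0) {
    writeLines(character(), path)
    return(invisible(Biostrings::DNAStringSet()))
  }
  lens <- stats::setNames(nchar(seqs), names(seqs))
  bad <- regions$end > lens[regions$contig] | regions$start < 0
  if (any(bad)) stop("region(s) beyond sequence bounds", call. = FALSE)
  dna <- Biostrings::DNAStringSet(toupper(substr(
    seqs[regions$contig], regions$start + 1L, regions$end
  )))
  names(dna) <- sprintf("%s:%d-%d", regions$contig, regions$start, regions$end)
  Biostrings::writeXStringSet(dna, path)
  invisible(dna)
}
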