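#' Merge mapped read pairs into fragments
#'
#' Mates mapped to the same contig are merged into one fragment spanning from
#' the leftmost to the rightmost mapped base; pairs whose mates map to
#' different contigs (or have a missing mate) are discarded.  Records with a
#' malformed mate interval (`start >= end`) are dropped with a warning.
#' Strand is ignored throughout the pipeline.
#'
#' @param read_pairs A data frame with columns `pair_id`, `contig1`,
#'   `start1`, `end1`, `contig2`, `start2`, `end2` (0-based half-open), e.g.
#'   from [read_bedpe()].
#' @return A tibble of fragments (`contig`, `start`, `end`, `length`) with a
#'   `"merge_summary"` attribute recording input, merged, cross-contig and
#'   malformed pair counts.
#' @export
#' @examples
#' pairs <- tibble::tibble(pair_id = "p1", contig1 = "c1", start1 = 100,
#'                         end1 = 225, contig2 = "c1", start2 = 400, end2 = 525)
#' merge_read_pairs(pairs)
merge_read_pairs <- function(read_pairs) {
  stopifnot(all(c("contig1", "start1", "end1", "contig2", "start2", "end2")
                %in% names(read_pairs)))
  n_in <- nrow(read_pairs)
  malformed <- with(read_pairs,
                    (!is.na(start1) & !is.na(end1) & start1 >= end1) |
                    (!is.na(start2) & !is.na(end2) & start2 >= end2))
  if (any(malformed)) {
    warning(sum(malformed), " read pair(s) with malformed mate intervals dropped",
            call. = FALSE)
    read_pairs <- read_pairs[!malformed, , drop = FALSE]
  }
  unpaired <- is.na(read_pairs$contig1) | is.na(read_pairs$contig2)
  cross <- !unpaired & read_pairs$contig1 != read_pairs$contig2
  keep <- read_pairs[!unpaired & !cross, , drop = FALSE]
  fragments <- tibble(
    contig = keep$contig1,
    start  = as.integer(pmin(keep$start1, keep$start2)),
    end    = as.integer(pmax(keep$end1, keep$end2))
  )
  fragments$length <- fragments$end - fragments$start
  structure(fragments, merge_summary = list(
    n_pairs = n_in,
    n_merged = nrow(fragments),
    n_cross_contig = sum(cross),
    n_unpaired = sum(unpaired),
    n_malformed = sum(malformed)
  ))
}

#' Discard fragments longer than a size cutoff
#'
#' CUT&RUN releases nucleosome-sized fragments; long fragments are dominated
#' by background cleavage, so fragments *longer than* `max_len` (default
#' 700 bp) are discarded.  The boundary is strict: a fragment of exactly
#' `max_len` bp is retained.  The operation is idempotent.
#'
#' @param fragments Fragment tibble (`contig`, `start`, `end`).
#' @param max_len Maximum retained fragment length in bp.
#' @return The filtered tibble, with attribute `"n_removed"`.
#' @export
filter_by_length <- function(fragments, max_len = 700) {
  stopifnot(max_len > 0)
  assert_fragments(fragments)
  len <- fragments$end - fragments$start
  keep <- len <= max_len
  out <- fragments[keep, , drop = FALSE]
  if (!"length" %in% names(out)) out$length <- out$end - out$start
  structure(as_tibble(out), n_removed = sum(!keep))
}

#' Spike-in quality control: correlation of spike-in vs total read counts
#'
#' A fixed amount of exogenous spike-in DNA is added to every sample, so
#' spike-in read counts should scale linearly with total sequencing depth;
#' a strong positive Pearson correlation indicates comparable recovery
#' efficiency across samples.
#'
#' @param samples Data frame with columns `sample_id`, `spikein_reads`,
#'   `total_reads`; at least 3 samples.
#' @param threshold QC-pass threshold on the correlation coefficient.
#' @return A one-row tibble: `r`, `n`, `qc_pass`, `note`.  When either
#'   vector has zero variance the correlation is undefined (`r = NA`,
#'   `qc_pass = FALSE`).
#' @export
spikein_correlation <- function(samples, threshold = 0.8) {
  stopifnot(all(c("spikein_reads", "total_reads") %in% names(samples)))
  if (nrow(samples) < 3) stop("need at least 3 samples", call. = FALSE)
  x <- samples$spikein_reads
  y <- samples$total_reads
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble(r = NA_real_, n = nrow(samples), qc_pass = FALSE,
                  note = "correlation undefined: zero variance"))
  }
  r <- stats::cor(x, y, method = "pearson")
  tibble(r = r, n = nrow(samples), qc_pass = r >= threshold, note = NA_character_)
}
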