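#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
#' @importFrom ggplot2 autoplot
NULL

# Internal coordinate convention: 0-based half-open [start, end).
# IRanges/GRanges are 1-based closed, so conversion happens exactly here.
ranges_from_0based <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

granges_from_0based <- function(contig, start, end, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(contig),
    ranges   = ranges_from_0based(start, end)
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

tibble_from_granges <- function(gr) {
  tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,
    end    = GenomicRanges::end(gr)
  )
}

genome_seqlengths <- function(genome) {
  stats::setNames(as.integer(genome$length), genome$contig)
}

#' Derive a reproducible child seed for a named random stream
#'
#' All randomness in the package flows from one user-supplied seed; each
#' generated artifact (genome, annotation, each sample's fragments, ...)
#' draws from its own stream so that regenerating one file never perturbs
#' another.  The child seed is a deterministic hash of the parent seed and
#' the stream name, kept below 2^31 - 1.
#'
#' @param seed Integer parent seed.
#' @param stream Character scalar naming the stream.
#' @return An integer seed.
#' @export
#' @examples
#' child_seed(1L, "genome")
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(seed) %% 2147483629 + h * 7919) %% 2147483629)
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(child_seed(seed, stream), code)
}

assert_fragments <- function(fragments) {
  stopifnot(is.data.frame(fragments),
            all(c("contig", "start", "end") %in% names(fragments)))
  if (nrow(fragments) > 0 && any(fragments$end <= fragments$start)) {
    stop("malformed fragment intervals: end must exceed start", call. = FALSE)
  }
  invisible(fragments)
}
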