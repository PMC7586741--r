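#' Read and write the pipeline's on-disk formats
#'
#' All interval files follow the field conventions: BED/BEDPE are 0-based
#' half-open, GFF3 is 1-based closed (conversion happens inside the GFF3
#' functions only), contig lengths and expression matrices are plain TSV.
#'
#' @param path File path.
#' @name crunmark-io
NULL

#' @rdname crunmark-io
#' @param genome Genome tibble (`contig`, `length`).
#' @export
write_contig_lengths <- function(genome, path) {
  readr::write_tsv(genome[, c("contig", "length")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname crunmark-io
#' @export
read_contig_lengths <- function(path) {
  readr::read_tsv(path, col_names = c("contig", "length"),
                  col_types = readr::cols(
                    contig = readr::col_character(),
                    length = readr::col_integer()
                  ))
}

#' @rdname crunmark-io
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- attr(genome, "sequences")
  if (is.null(seqs)) stop("genome carries no sequences; regenerate with ",
                          "`with_sequences = TRUE`", call. = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname crunmark-io
#' @param fragments Fragment tibble (`contig`, `start`, `end`).
#' @export
write_fragments_bed <- function(fragments, path) {
  readr::write_tsv(fragments[, c("contig", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname crunmark-io
#' @export
read_fragments_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("contig", "start", "end"),
                       col_types = readr::cols(
                         contig = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer()
                       ))
  dplyr::mutate(x, length = .data$end - .data$start)
}

#' @rdname crunmark-io
#' @export
read_bedpe <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("contig1", "start1", "end1", "contig2", "start2", "end2",
                  "pair_id"),
    col_types = readr::cols(
      contig1 = readr::col_character(), start1 = readr::col_integer(),
      end1 = readr::col_integer(), contig2 = readr::col_character(),
      start2 = readr::col_integer(), end2 = readr::col_integer(),
      pair_id = readr::col_character()
    )
  )
}

#' @rdname crunmark-io
#' @param annotation Annotation tibble from [generate_annotation()].
#' @param genome Genome tibble, used for GFF3 sequence-region headers.
#' @export
write_annotation_gff3 <- function(annotation, path, genome = NULL) {
  if (nrow(annotation) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- granges_from_0based(
    annotation$contig, annotation$start, annotation$end,
    seqlengths = if (!is.null(genome)) genome_seqlengths(genome)
  )
  S4Vectors::mcols(gr)$ID <- annotation$feature_id
  S4Vectors::mcols(gr)$type <- annotation$type
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' @rdname crunmark-io
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  out <- tibble_from_granges(gr)
  out$feature_id <- as.character(S4Vectors::mcols(gr)$ID)
  out$type <- as.character(S4Vectors::mcols(gr)$type)
  out[, c("feature_id", "contig", "start", "end", "type")]
}

#' @rdname crunmark-io
#' @param expression Expression tibble (`gene_id` + one column per tissue).
#' @export
write_expression_tsv <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}

#' @rdname crunmark-io
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
}

#' @rdname crunmark-io
#' @param maps Functional maps list from [generate_functional_maps()].
#' @param go_path,homology_path Output paths for the two map tables.
#' @export
write_functional_maps <- function(maps, go_path, homology_path) {
  readr::write_tsv(maps$go, go_path)
  readr::write_tsv(maps$homology, homology_path)
  invisible(c(go_path, homology_path))
}

#' @rdname crunmark-io
#' @export
read_functional_maps <- function(go_path, homology_path) {
  list(
    go = readr::read_tsv(go_path, col_types = readr::cols(
      ref_gene_id = readr::col_character(), go_id = readr::col_character()
    )),
    homology = readr::read_tsv(homology_path, col_types = readr::cols(
      gene_id = readr::col_character(), ref_gene_id = readr::col_character(),
      ref_marked = readr::col_integer()
    ))
  )
}

#' @rdname crunmark-io
#' @param peaks Peak tibble from [call_peaks()].
#' @export
write_peaks_bed <- function(peaks, path) {
  score <- pmin(1000, round(-log10(pmax(peaks$min_q, 1e-300))))
  out <- tibble(
    contig = peaks$contig, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%04d", seq_len(nrow(peaks))), score = score
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname crunmark-io
#' @param track A coverage track from [build_coverage()].
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  recs <- lapply(names(track$coverage), function(ctg) {
    r <- track$coverage[[ctg]]
    tibble(
      contig = ctg,
      start  = cumsum(c(0L, S4Vectors::runLength(r)))[seq_along(S4Vectors::runLength(r))],
      end    = cumsum(S4Vectors::runLength(r)),
      value  = S4Vectors::runValue(r)
    )
  })
  out <- dplyr::filter(dplyr::bind_rows(recs), .data$value > 0)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
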