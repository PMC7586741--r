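#' Extend gene bodies into quantification regions
#'
#' The marking call and the FPKB intensity are both computed over the gene
#' body extended by `extension` bp upstream and downstream, clipped to contig
#' bounds.
#'
#' @param annotation Annotation tibble; only `type == "gene"` rows are used.
#' @param genome Genome tibble supplying contig lengths for clipping.
#' @param extension Extension in bp on each side (default 500).
#' @return A tibble (`gene_id`, `contig`, `start`, `end`, `length_ext`),
#'   0-based half-open.
#' @export
gene_regions <- function(annotation, genome, extension = 500) {
  stopifnot(extension >= 0)
  genes <- dplyr::filter(annotation, .data$type == "gene")
  g <- dplyr::left_join(genes, genome[, c("contig", "length")], by = "contig")
  if (any(is.na(g$length))) {
    stop("gene(s) on contigs absent from the genome", call. = FALSE)
  }
  tibble(
    gene_id = g$feature_id,
    contig  = g$contig,
    start   = pmax(0L, as.integer(g$start - extension)),
    end     = pmin(as.integer(g$length), as.integer(g$end + extension))
  ) |>
    dplyr::mutate(length_ext = .data$end - .data$start)
}

#' Call marked genes by peak overlap
#'
#' A gene is called mark-enriched when at least one called peak overlaps its
#' extended region by one or more bases (intervals are half-open, so an
#' abutting peak does not count).
#'
#' @param regions Gene regions from [gene_regions()].
#' @param peaks Peak tibble from [call_peaks()].
#' @return `regions` with a logical `enriched` column.
#' @export
assign_enriched_genes <- function(regions, peaks) {
  region_gr <- granges_from_0based(regions$contig, regions$start, regions$end)
  out <- regions
  if (nrow(peaks) == 0) {
    out$enriched <- FALSE
    return(out)
  }
  peak_gr <- granges_from_0based(peaks$contig, peaks$start, peaks$end)
  out$enriched <- GenomicRanges::countOverlaps(region_gr, peak_gr) > 0
  out
}

#' Quantify per-gene signal intensity in FPKB
#'
#' FPKB is fragments per kilobase of (extended) gene region per billion
#' mapped fragments: `fpkb = k / (length_ext/1000) / (N/1e9)` where `k` is
#' the number of fragments overlapping the region and `N` the total filtered
#' fragment count of the sample.  A fragment overlapping several gene regions
#' counts toward each of them.
#'
#' @param fragments Fragment tibble (post size filter).
#' @param regions Gene regions from [gene_regions()].
#' @param n_total Total filtered fragments `N`; defaults to `nrow(fragments)`.
#' @return `regions` with added `count` and `fpkb` columns.
#' @export
#' @examples
#' # 30 fragments on a 3 kb region out of 10^7 mapped: 30 / 3 / 0.01 = 1000
quantify_fpkb <- function(fragments, regions, n_total = nrow(fragments)) {
  assert_fragments(fragments)
  out <- regions
  region_gr <- granges_from_0based(regions$contig, regions$start, regions$end)
  frag_gr <- granges_from_0based(fragments$contig, fragments$start, fragments$end)
  out$count <- GenomicRanges::countOverlaps(region_gr, frag_gr)
  if (n_total == 0) {
    warning("n_total is 0; all FPKB values set to 0", call. = FALSE)
    out$fpkb <- 0
    return(out)
  }
  out$fpkb <- out$count / (out$length_ext / 1000) / (n_total / 1e9)
  out
}

#' The FPKB of a single fragment on a 1 kb region
#'
#' Used as the default pseudocount in fold-change comparisons: adding it to
#' both samples keeps ratios finite and unit-consistent.
#'
#' @param n_total Total mapped fragments of the sample.
#' @return `1e9 / n_total`.
#' @export
fpkb_pseudocount <- function(n_total) {
  stopifnot(n_total > 0)
  1e9 / n_total
}

#' Pairwise fold-change comparison of per-gene signal
#'
#' Flags genes whose signal differs between two samples by `fold` times or
#' more ("twice or more" by default): `gained` genes satisfy
#' `(fpkb_b + pseudo) / (fpkb_a + pseudo) >= fold`, `lost` genes the
#' symmetric condition.  The threshold is inclusive and the two sets are
#' disjoint for `fold > 1`.
#'
#' @param sig_a,sig_b Per-gene signal tibbles with `gene_id` and `fpkb`
#'   (e.g. from [quantify_fpkb()]), over the same gene universe.
#' @param fold Fold threshold (> 1).
#' @param pseudo Pseudocount added to both intensities; see
#'   [fpkb_pseudocount()] for the recommended sample-specific value.
#' @return A `fold_comparison` object: list with `gained`, `lost` (character
#'   vectors) and `table` (per-gene tibble with the ratio and a `status`
#'   column).
#' @export
pairwise_fold_calls <- function(sig_a, sig_b, fold = 2, pseudo = 1) {
  stopifnot(fold > 1, pseudo > 0)
  tab <- dplyr::inner_join(
    dplyr::select(sig_a, "gene_id", fpkb_a = "fpkb"),
    dplyr::select(sig_b, "gene_id", fpkb_b = "fpkb"),
    by = "gene_id"
  )
  if (nrow(tab) != nrow(sig_a) || nrow(tab) != nrow(sig_b)) {
    stop("sig_a and sig_b must cover the same gene universe", call. = FALSE)
  }
  tab$ratio <- (tab$fpkb_b + pseudo) / (tab$fpkb_a + pseudo)
  tab$status <- dplyr::case_when(
    tab$ratio >= fold ~ "gained",
    tab$ratio <= 1 / fold ~ "lost",
    TRUE ~ "unchanged"
  )
  structure(
    list(
      gained = tab$gene_id[tab$status == "gained"],
      lost   = tab$gene_id[tab$status == "lost"],
      table  = tab,
      fold   = fold,
      pseudo = pseudo
    ),
    class = "fold_comparison"
  )
}

#' Set difference of marked-gene sets between two samples
#'
#' @param set_a,set_b Character vectors of marked gene ids.
#' @return A list with `a_only`, `b_only` and `both`.
#' @export
set_difference_marked <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  list(
    a_only = setdiff(set_a, set_b),
    b_only = setdiff(set_b, set_a),
    both   = intersect(set_a, set_b)
  )
}

#' Exclusive intersection counts of multiple marked-gene sets
#'
#' Assigns every gene in the union to exactly one exclusive membership cell
#' (the combination of sets that contain it), as drawn in an UpSet plot, so
#' cell counts sum to the union size.
#'
#' @param sets A named list of two or more character vectors.
#' @return A tibble (`combination`, `degree`, `n`) sorted by decreasing `n`,
#'   with attributes `"set_totals"` (named per-set sizes), `"union_size"`
#'   and `"core_size"` (genes present in every set).
#' @export
intersection_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets))
  if (length(universe) == 0) {
    return(structure(
      tibble(combination = character(), degree = integer(), n = integer()),
      set_totals = vapply(sets, length, integer(1)),
      union_size = 0L, core_size = 0L
    ))
  }
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  counts <- table(key)
  out <- tibble(
    combination = names(counts),
    degree = vapply(strsplit(names(counts), "&", fixed = TRUE), length, integer(1)),
    n = as.integer(counts)
  ) |> dplyr::arrange(dplyr::desc(.data$n))
  structure(out,
            set_totals = vapply(sets, length, integer(1)),
            union_size = length(universe),
            core_size = sum(rowSums(member) == length(sets)))
}

#' Paired t-test of signal intensities between two samples
#'
#' Classical paired Student's t-test on per-gene intensity differences over a
#' common gene set, with explicit conventions for degenerate inputs: if all
#' differences are exactly zero, `t = 0, p = 1`; if the differences are a
#' nonzero constant (zero variance), the t statistic diverges and `p = 0` is
#' reported with a degeneracy flag.
#'
#' @param a,b Numeric vectors of paired intensities (length >= 2).
#' @return A `paired_signal_test` object with elements `t`, `p`, `df`,
#'   `mean_diff`, `n`, `degenerate`.
#' @export
paired_t_signal <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  n <- length(a)
  if (n < 2) stop("need at least 2 paired observations", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sd_d <- stats::sd(d)
  degenerate <- FALSE
  if (sd_d == 0) {
    if (md == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(md) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t_stat <- md / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(
    list(t = t_stat, p = p, df = n - 1, mean_diff = md, n = n,
         degenerate = degenerate),
    class = "paired_signal_test"
  )
}
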