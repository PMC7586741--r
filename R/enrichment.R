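#' Map genes to GO terms via their reference-species homologue
#'
#' Each gene inherits the GO terms of its (best-hit) homologue; when a gene
#' appears more than once in the homology table, the first listed hit is
#' used.  Genes without a homologue ("orphan genes") map to nothing.
#'
#' @param genes Character vector of gene ids.
#' @param maps List with tibbles `homology` (`gene_id`, `ref_gene_id`) and
#'   `go` (`ref_gene_id`, `go_id`), as from [generate_functional_maps()] or
#'   [read_functional_maps()].
#' @return A tibble (`gene_id`, `go_id`); one row per assignment.
#' @export
map_genes_to_go <- function(genes, maps) {
  hom <- dplyr::distinct(maps$homology, .data$gene_id, .keep_all = TRUE)
  hom <- hom[hom$gene_id %in% genes, c("gene_id", "ref_gene_id")]
  dplyr::inner_join(hom, maps$go, by = "ref_gene_id")[, c("gene_id", "go_id")]
}

#' Hypergeometric GO-term enrichment through homology
#'
#' Both the sample and the background are first restricted to genes with a
#' reference-species homologue; for each term with `K` annotated genes in the
#' background and `k` in the sample the upper-tail hypergeometric probability
#' `P(X >= k)` of drawing that many annotated genes in a sample of size
#' `n_sample` from `n_background` genes is reported, together with the
#' enrichment ratio `(k / n_sample) / (K / n_background)`.  Terms absent from
#' the background are skipped.  Rows are sorted by decreasing enrichment,
#' then increasing p.
#'
#' @param sample_genes Character vector; must be a subset of
#'   `background_genes`.
#' @param background_genes Character vector of the gene universe.
#' @param maps Functional maps list (see [map_genes_to_go()]); an optional
#'   `terms` tibble (`go_id`, `label`) supplies labels.
#' @param adjust If `TRUE`, append a BH-adjusted `q_value` column.
#' @return A tibble (`go_id`, `label`, `freq_sample`, `freq_background`,
#'   `enrichment`, `p_value`[, `q_value`]).
#' @export
hypergeom_go <- function(sample_genes, background_genes, maps, adjust = FALSE) {
  sample_genes <- unique(as.character(sample_genes))
  background_genes <- unique(as.character(background_genes))
  if (!all(sample_genes %in% background_genes)) {
    stop("sample_genes must be a subset of background_genes", call. = FALSE)
  }
  with_hom <- unique(dplyr::distinct(maps$homology, .data$gene_id,
                                     .keep_all = TRUE)$gene_id)
  bg <- intersect(background_genes, with_hom)
  smp <- intersect(sample_genes, with_hom)
  n_bg <- length(bg)
  n_smp <- length(smp)
  ann_bg <- map_genes_to_go(bg, maps)
  ann_smp <- ann_bg[ann_bg$gene_id %in% smp, , drop = FALSE]
  K <- table(ann_bg$go_id)
  k <- table(factor(ann_smp$go_id, levels = names(K)))
  out <- tibble(
    go_id = names(K),
    freq_sample = as.integer(k),
    freq_background = as.integer(K)
  )
  out$enrichment <- (out$freq_sample / n_smp) / (out$freq_background / n_bg)
  out$p_value <- stats::phyper(out$freq_sample - 1, out$freq_background,
                               n_bg - out$freq_background, n_smp,
                               lower.tail = FALSE)
  if (!is.null(maps$terms)) {
    out <- dplyr::left_join(out, maps$terms, by = "go_id")
  } else {
    out$label <- NA_character_
  }
  out <- out[, c("go_id", "label", "freq_sample", "freq_background",
                 "enrichment", "p_value")]
  if (adjust) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, dplyr::desc(.data$enrichment), .data$p_value)
}

#' Cross-species conservation of mark targets
#'
#' Splits genes by the marking status of their reference-species homologue
#' (marked homologue / unmarked homologue / no homologue, i.e. orphan) and
#' reports the fraction of genes marked in the study species within each
#' category, plus an upper-tail hypergeometric p-value for over-representation
#' of study-species marked genes among homologues of reference-marked genes.
#'
#' @param spruce_marked Character vector of genes marked in the study species.
#' @param maps Functional maps list with `homology` carrying `ref_marked`.
#' @param all_genes Character vector of the full gene universe (needed to
#'   identify orphans).
#' @return A `conservation_contrast` object: per-category tibble
#'   (`category`, `n`, `n_marked`, `fraction`) plus the test's `p`.
#' @export
conservation_contrast <- function(spruce_marked, maps, all_genes) {
  hom <- dplyr::distinct(maps$homology, .data$gene_id, .keep_all = TRUE)
  all_genes <- unique(as.character(all_genes))
  spruce_marked <- intersect(unique(as.character(spruce_marked)), all_genes)
  category <- dplyr::case_when(
    !(all_genes %in% hom$gene_id) ~ "orphan",
    all_genes %in% hom$gene_id[hom$ref_marked == 1] ~ "ref_marked",
    TRUE ~ "ref_unmarked"
  )
  marked <- all_genes %in% spruce_marked
  tab <- tibble(category = category, marked = marked) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(), n_marked = sum(.data$marked),
                     .groups = "drop") |>
    dplyr::mutate(fraction = ifelse(.data$n > 0, .data$n_marked / .data$n,
                                    NA_real_))
  # hypergeometric: among genes with a homologue, are study-species marked
  # genes over-represented in the ref_marked category?
  in_hom <- category != "orphan"
  n_universe <- sum(in_hom)
  K <- sum(category == "ref_marked")
  n_draw <- sum(marked & in_hom)
  k <- sum(marked & category == "ref_marked")
  p <- if (n_universe == 0 || K == 0 || n_draw == 0) {
    NA_real_
  } else {
    stats::phyper(k - 1, K, n_universe - K, n_draw, lower.tail = FALSE)
  }
  structure(
    list(fractions = tab, p = p,
         counts = list(universe = n_universe, ref_marked = K,
                       spruce_marked = n_draw, joint = k)),
    class = "conservation_contrast"
  )
}
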