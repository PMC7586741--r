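#' Declare the ground truth planted into a synthetic dataset
#'
#' Downstream recovery tests need to know which genes were designed to carry
#' the histone mark, how strong the enrichment is, which genes are expressed
#' tissue-specifically, and which GO terms were planted as enriched.  This
#' constructor collects those design choices in one validated object that the
#' `generate_*()` functions consume.
#'
#' @param marked_genes Character vector of marked gene ids, or a named list of
#'   such vectors (one element per sample).  A bare vector is treated as a
#'   single sample called `"sample_1"`.
#' @param enrichment_fold Fold enrichment of fragment density over marked
#'   gene regions relative to uniform background; >= 1, where 1 means no
#'   enrichment (a null design for calibration checks).
#' @param background_rate Optional background fragment density
#'   (fragments per bp).  When `NULL` the density is derived from the
#'   `n_fragments` argument of [generate_fragments()].
#' @param specific_genes,broad_genes Character vectors of gene ids designed to
#'   be expressed in a single tissue vs uniformly across tissues.
#' @param planted_go_terms Character vector of GO term ids to over-represent
#'   among a designated gene set.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(marked_genes = character(),
                         enrichment_fold = 8,
                         background_rate = NULL,
                         specific_genes = character(),
                         broad_genes = character(),
                         planted_go_terms = character()) {
  if (!is.list(marked_genes)) marked_genes <- list(sample_1 = marked_genes)
  if (is.null(names(marked_genes)) || any(names(marked_genes) == "")) {
    names(marked_genes) <- paste0("sample_", seq_along(marked_genes))
  }
  stopifnot(enrichment_fold >= 1)
  structure(
    list(
      marked_genes     = lapply(marked_genes, as.character),
      enrichment_fold  = enrichment_fold,
      background_rate  = background_rate,
      specific_genes   = as.character(specific_genes),
      broad_genes      = as.character(broad_genes),
      planted_go_terms = as.character(planted_go_terms)
    ),
    class = "ground_truth"
  )
}

#' Generate a toy genome of many short contigs
#'
#' Emulates a large conifer-style assembly that is split across many short
#' scaffolds: contig lengths are drawn from a right-skewed lognormal
#' distribution with mean `mean_len` (sdlog 0.4) and a floor of 500 bp, so
#' contigs vary several-fold in length as in real fragmented assemblies
#' while the total assembly size stays close to `n_contigs * mean_len`.
#'
#' @param n_contigs Number of contigs (>= 1).
#' @param mean_len Mean contig length in bp (>= 500).
#' @param seed Integer seed; the same seed always yields the same genome.
#' @param with_sequences If `TRUE`, attach random A/C/G/T sequences (needed
#'   only for FASTA export of motif regions).
#' @return A tibble with columns `contig` and `length`; when sequences are
#'   generated they are stored in the `"sequences"` attribute as a named
#'   character vector.
#' @export
#' @examples
#' g <- generate_toy_genome(5, 2000, seed = 1)
#' sum(g$length)
generate_toy_genome <- function(n_contigs, mean_len, seed, with_sequences = FALSE) {
  stopifnot(n_contigs >= 1, mean_len >= 500)
  lens <- with_stream(seed, "genome", {
    sdlog <- 0.4
    pmax(500, round(stats::rlnorm(n_contigs,
                                  meanlog = log(mean_len) - sdlog^2 / 2,
                                  sdlog = sdlog)))
  })
  genome <- tibble(
    contig = sprintf("ctg%04d", seq_len(n_contigs)),
    length = as.integer(lens)
  )
  if (with_sequences) {
    seqs <- with_stream(seed, "sequences", {
      vapply(genome$length, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }, character(1))
    })
    attr(genome, "sequences") <- stats::setNames(seqs, genome$contig)
  }
  genome
}

#' Generate a gene and transposable-element annotation on a toy genome
#'
#' Genes are placed in disjoint random slots (guaranteeing non-overlap);
#' transposable elements are tiled over approximately `te_fraction` of the
#' remaining intergenic sequence.
#'
#' @param genome A genome tibble from [generate_toy_genome()].
#' @param n_genes Number of genes to place.
#' @param gene_len Gene length in bp.
#' @param te_fraction Fraction of intergenic sequence to cover with
#'   transposable elements, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A tibble with columns `feature_id`, `contig`, `start`, `end`
#'   (0-based half-open) and `type` (`"gene"` or `"transposable_element"`).
#' @export
generate_annotation <- function(genome, n_genes, gene_len = 2000,
                                te_fraction = 0, seed = 1) {
  stopifnot(n_genes >= 0, gene_len >= 1, te_fraction >= 0, te_fraction < 1)
  slot <- 2L * gene_len
  slots <- dplyr::bind_rows(lapply(seq_len(nrow(genome)), function(i) {
    k <- genome$length[i] %/% slot
    if (k == 0) return(NULL)
    tibble(contig = genome$contig[i], slot_start = (seq_len(k) - 1L) * slot)
  }))
  if (n_genes > 0 && (is.null(slots) || nrow(slots) < n_genes)) {
    stop("cannot pack ", n_genes, " genes of ", gene_len,
         " bp on this genome without overlap", call. = FALSE)
  }
  genes <- if (n_genes == 0) {
    tibble(feature_id = character(), contig = character(),
           start = integer(), end = integer(), type = character())
  } else {
    with_stream(seed, "annotation", {
      picked <- slots[sample.int(nrow(slots), n_genes), , drop = FALSE]
      jitter <- sample.int(slot - gene_len, n_genes, replace = TRUE) - 1L
      tibble(
        feature_id = sprintf("g%04d", seq_len(n_genes)),
        contig = picked$contig,
        start  = as.integer(picked$slot_start + jitter),
        end    = as.integer(picked$slot_start + jitter + gene_len),
        type   = "gene"
      ) |> dplyr::arrange(.data$contig, .data$start)
    })
  }
  tes <- if (te_fraction == 0) {
    genes[0, ]
  } else {
    te_len <- 500L
    gaps <- intergenic_gaps(genome, genes)
    with_stream(seed, "te", {
      recs <- lapply(seq_len(nrow(gaps)), function(i) {
        gap_len <- gaps$end[i] - gaps$start[i]
        k <- round(te_fraction * gap_len / te_len)
        if (k < 1) return(NULL)
        stride <- gap_len %/% k
        off <- if (stride > te_len) {
          sample.int(stride - te_len, k, replace = TRUE) - 1L
        } else rep(0L, k)
        s <- gaps$start[i] + (seq_len(k) - 1L) * stride + off
        tibble(contig = gaps$contig[i], start = as.integer(s),
               end = as.integer(pmin(s + te_len, gaps$end[i])))
      })
      out <- dplyr::bind_rows(recs)
      if (nrow(out) == 0) genes[0, ] else {
        out$feature_id <- sprintf("te%05d", seq_len(nrow(out)))
        out$type <- "transposable_element"
        out[, c("feature_id", "contig", "start", "end", "type")]
      }
    })
  }
  dplyr::bind_rows(genes, tes)
}

intergenic_gaps <- function(genome, genes) {
  sl <- genome_seqlengths(genome)
  full <- granges_from_0based(genome$contig, 0L, genome$length, seqlengths = sl)
  if (nrow(genes) == 0) return(tibble_from_granges(full))
  gr <- granges_from_0based(genes$contig, genes$start, genes$end, seqlengths = sl)
  tibble_from_granges(GenomicRanges::setdiff(full, gr))
}

#' Generate per-sample fragment tables with planted enrichment
#'
#' Background fragments are placed uniformly over the genome; each marked
#' gene additionally receives fragments over its body +/- `extension` so that
#' fragment density there is `enrichment_fold` times the background density.
#' Fragment lengths follow a truncated normal (floor 50 bp) and a fraction
#' `long_frac` are given contaminant lengths in (700, 2000] bp to exercise
#' the size filter.
#'
#' @param genome,annotation Outputs of [generate_toy_genome()] and
#'   [generate_annotation()].
#' @param truth A [ground_truth()] object; its `marked_genes` element defines
#'   the samples to simulate.
#' @param n_fragments Background fragments per sample.  When
#'   `truth$background_rate` is set it takes precedence and
#'   `n_fragments = background_rate * genome length`.
#' @param frag_len_mean,frag_len_sd Fragment-length distribution (bp).
#' @param long_frac Fraction of fragments given lengths > 700 bp.
#' @param seed Integer seed.
#' @return A named list of tibbles (one per sample) with columns
#'   `contig`, `start`, `end`, `length`.
#' @export
generate_fragments <- function(genome, annotation, truth,
                               n_fragments = 10000,
                               frag_len_mean = 300,
                               frag_len_sd = frag_len_mean / 4,
                               long_frac = 0, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"),
            n_fragments >= 0, long_frac >= 0, long_frac < 1)
  genes <- dplyr::filter(annotation, .data$type == "gene")
  genome_len <- sum(genome$length)
  if (!is.null(truth$background_rate)) {
    n_fragments <- round(truth$background_rate * genome_len)
  }
  bg_rate <- n_fragments / genome_len
  samples <- names(truth$marked_genes)
  out <- lapply(samples, function(sample_name) {
    marked <- truth$marked_genes[[sample_name]]
    missing <- setdiff(marked, genes$feature_id)
    if (length(missing) > 0) {
      stop("marked gene(s) not in annotation: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    with_stream(seed, paste0("fragments_", sample_name), {
      bg <- place_uniform_fragments(genome, n_fragments,
                                    frag_len_mean, frag_len_sd, long_frac)
      regions <- enriched_regions(genes, genome, marked)
      extra <- if (nrow(regions) == 0) bg[0, ] else {
        n_extra <- stats::rpois(
          nrow(regions),
          (truth$enrichment_fold - 1) * bg_rate * (regions$end - regions$start)
        )
        place_region_fragments(regions, genome, n_extra,
                               frag_len_mean, frag_len_sd, long_frac)
      }
      dplyr::arrange(dplyr::bind_rows(bg, extra), .data$contig, .data$start)
    })
  })
  stats::setNames(out, samples)
}

enriched_regions <- function(genes, genome, marked, extension = 500L) {
  g <- dplyr::filter(genes, .data$feature_id %in% marked)
  g <- dplyr::left_join(g, genome, by = "contig")
  tibble(
    contig = g$contig,
    start  = pmax(0L, g$start - extension),
    end    = pmin(g$length, g$end + extension)
  )
}

draw_fragment_lengths <- function(n, mean_len, sd_len, long_frac) {
  if (n == 0) return(integer())
  len <- pmax(50, round(stats::rnorm(n, mean_len, sd_len)))
  long <- stats::runif(n) < long_frac
  len[long] <- round(stats::runif(sum(long), 701, 2000))
  as.integer(len)
}

place_uniform_fragments <- function(genome, n, mean_len, sd_len, long_frac) {
  if (n == 0) {
    return(tibble(contig = character(), start = integer(),
                  end = integer(), length = integer()))
  }
  idx <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  L <- genome$length[idx]
  start <- floor(stats::runif(n) * L)
  len <- draw_fragment_lengths(n, mean_len, sd_len, long_frac)
  end <- pmin(start + len, L)
  tibble(contig = genome$contig[idx], start = as.integer(start),
         end = as.integer(end), length = as.integer(end - start))
}

place_region_fragments <- function(regions, genome, n_per_region,
                                   mean_len, sd_len, long_frac) {
  sl <- genome_seqlengths(genome)
  recs <- lapply(seq_len(nrow(regions)), function(i) {
    n <- n_per_region[i]
    if (n == 0) return(NULL)
    w <- regions$end[i] - regions$start[i]
    start <- regions$start[i] + floor(stats::runif(n) * w)
    len <- draw_fragment_lengths(n, mean_len, sd_len, long_frac)
    end <- pmin(start + len, sl[[regions$contig[i]]])
    tibble(contig = regions$contig[i], start = as.integer(start),
           end = as.integer(end), length = as.integer(end - start))
  })
  out <- dplyr::bind_rows(recs)
  if (is.null(out) || nrow(out) == 0) {
    tibble(contig = character(), start = integer(),
           end = integer(), length = integer())
  } else out
}

#' Generate a multi-tissue expression matrix with designed specificity
#'
#' Genes listed in `truth$specific_genes` are expressed predominantly in one
#' tissue (assigned round-robin), with a `leakage` fraction of the level in
#' all other tissues; genes in `truth$broad_genes` (and all remaining genes)
#' are expressed near-uniformly.  Noise is multiplicative log-normal.
#'
#' @param annotation Annotation tibble; only `type == "gene"` rows are used.
#' @param n_tissues Number of tissues (>= 2).
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed.
#' @param base_level Expression level of the dominant tissue.
#' @param leakage Fraction of `base_level` that specific genes express in
#'   their non-dominant tissues.
#' @param noise_sd Standard deviation of log-normal multiplicative noise
#'   (0 for noise-free designs).
#' @return A tibble with `gene_id` and one non-negative column per tissue.
#' @export
generate_expression <- function(annotation, n_tissues, truth, seed = 1,
                                base_level = 100, leakage = 0.02,
                                noise_sd = 0.1) {
  stopifnot(n_tissues >= 2)
  genes <- dplyr::filter(annotation, .data$type == "gene")$feature_id
  specific <- intersect(truth$specific_genes, genes)
  mat <- matrix(base_level, nrow = length(genes), ncol = n_tissues,
                dimnames = list(genes, sprintf("tissue_%02d", seq_len(n_tissues))))
  if (length(specific) > 0) {
    dominant <- ((seq_along(specific) - 1L) %% n_tissues) + 1L
    mat[specific, ] <- base_level * leakage
    mat[cbind(match(specific, genes), dominant)] <- base_level
  }
  if (noise_sd > 0) {
    mat <- with_stream(seed, "expression", {
      mat * exp(matrix(stats::rnorm(length(mat), 0, noise_sd), nrow = nrow(mat)))
    })
  }
  dplyr::bind_cols(tibble(gene_id = genes), as_tibble(mat))
}

#' Generate homology and GO maps with planted term enrichment
#'
#' A configurable fraction of genes are left without a reference-species
#' homologue ("orphan genes"); the rest map one-to-one onto reference gene
#' ids carrying a marked/unmarked flag.  GO terms are assigned to reference
#' genes at a baseline probability; each planted term is assigned to the
#' homologues of `target_genes` at `odds_ratio` times the baseline odds, and
#' the reference marked flag can likewise be made to co-vary with the target
#' set via `conservation_odds`.
#'
#' @param annotation Annotation tibble.
#' @param n_terms Number of GO terms in the vocabulary (>= 1).
#' @param truth A [ground_truth()] object; `truth$planted_go_terms` must be a
#'   subset of the generated vocabulary `GO:0000001 ... GO:<n_terms>`.
#' @param seed Integer seed.
#' @param orphan_fraction Fraction of genes without a homologue.
#' @param odds_ratio Odds ratio of planted-term assignment for target genes
#'   relative to the baseline `base_term_prob`.
#' @param target_genes Gene set carrying the planted enrichment; defaults to
#'   the first sample's marked genes.
#' @param base_term_prob Baseline probability that a term is assigned to a
#'   gene's homologue.
#' @param ref_marked_prob Baseline probability a reference gene is marked.
#' @param conservation_odds Odds ratio tying the reference marked flag to
#'   membership in `target_genes` (1 = independent).
#' @return A list with tibbles `homology` (`gene_id`, `ref_gene_id`,
#'   `ref_marked`), `go` (`ref_gene_id`, `go_id`) and `terms`
#'   (`go_id`, `label`).
#' @export
generate_functional_maps <- function(annotation, n_terms, truth, seed = 1,
                                     orphan_fraction = 0.2, odds_ratio = 1,
                                     target_genes = NULL,
                                     base_term_prob = 0.1,
                                     ref_marked_prob = 0.3,
                                     conservation_odds = 1) {
  stopifnot(n_terms >= 1, orphan_fraction >= 0, orphan_fraction <= 1)
  genes <- dplyr::filter(annotation, .data$type == "gene")$feature_id
  if (is.null(target_genes)) target_genes <- truth$marked_genes[[1]]
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  planted <- intersect(truth$planted_go_terms, terms)
  with_stream(seed, "functional_maps", {
    n_hom <- round((1 - orphan_fraction) * length(genes))
    hom_genes <- sort(sample(genes, n_hom))
    is_target <- hom_genes %in% target_genes
    p_marked <- odds_boost(ref_marked_prob, ifelse(is_target, conservation_odds, 1))
    homology <- tibble(
      gene_id = hom_genes,
      ref_gene_id = sprintf("AT%05dg", seq_len(n_hom)),
      ref_marked = as.integer(stats::runif(n_hom) < p_marked)
    )
    assignments <- lapply(seq_along(terms), function(j) {
      p <- odds_boost(
        base_term_prob,
        ifelse(is_target & terms[j] %in% planted, odds_ratio, 1)
      )
      hit <- stats::runif(n_hom) < p
      if (!any(hit)) return(NULL)
      tibble(ref_gene_id = homology$ref_gene_id[hit], go_id = terms[j])
    })
    list(
      homology = homology,
      go = dplyr::bind_rows(assignments),
      terms = tibble(go_id = terms, label = paste("synthetic process", seq_len(n_terms)))
    )
  })
}

# shift a probability by an odds ratio: p' has odds OR * p/(1-p)
odds_boost <- function(p, or) {
  o <- or * p / (1 - p)
  o / (1 + o)
}
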