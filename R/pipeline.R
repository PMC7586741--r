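#' Assemble a validated pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with defaults matching
#' the method's published values: 500 bp bins, 700 bp maximum fragment
#' length, FDR threshold 1e-25, < 100 bp peak merging, 500 bp gene-region
#' extensions, 2-fold differential calls, 8.0e-7 reads/total-reads motif
#' threshold with < 101 bp merging, and natural-log entropy.
#'
#' @param bin_size Bin width in bp.
#' @param max_fragment Maximum retained fragment length in bp.
#' @param fdr FDR threshold for significant bins.
#' @param merge_gap Peak-merge gap in bp (strictly smaller gaps merge).
#' @param extension Gene-region extension in bp.
#' @param fold Fold threshold for differential calls.
#' @param motif_threshold Coverage threshold for motif-region selection.
#' @param motif_merge Motif-region merge gap in bp.
#' @param entropy_base Entropy logarithm base.
#' @param seed Integer seed driving all randomness.
#' @param simulate Named list of synthetic-data parameters (see
#'   [run_pipeline()]); `NULL` disables simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bin_size = 500, max_fragment = 700, fdr = 1e-25,
                            merge_gap = 100, extension = 500, fold = 2,
                            motif_threshold = 8.0e-7, motif_merge = 101,
                            entropy_base = exp(1), seed = 1,
                            simulate = list()) {
  cfg <- list(bin_size = bin_size, max_fragment = max_fragment, fdr = fdr,
              merge_gap = merge_gap, extension = extension, fold = fold,
              motif_threshold = motif_threshold, motif_merge = motif_merge,
              entropy_base = entropy_base, seed = seed, simulate = simulate)
  num <- cfg[c("bin_size", "max_fragment", "merge_gap", "extension", "fold",
               "motif_threshold", "motif_merge", "entropy_base")]
  if (any(unlist(num) <= 0) || fdr < 0) {
    stop("all pipeline parameters must be positive (fdr may be 0)",
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; unknown keys are rejected, missing keys take the
#' defaults of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full synthetic-data pipeline end to end
#'
#' Generates a toy genome, annotation, per-sample fragment sets, expression
#' panel and functional maps from `config$simulate` (all with known ground
#' truth), then runs every analysis stage: fragment size filtering, binned
#' binomial peak calling with BH adjustment, gene-level marking calls and
#' FPKB intensities, pairwise fold comparisons and set intersections, the
#' entropy specificity contrast, hypergeometric GO enrichment, the
#' conservation contrast, and motif-region extraction with length-matched
#' background.  Every output is written under `outdir` as TSV/BED/FASTA/JSON
#' together with a run manifest recording parameters, seed, package version
#' and output checksums.  Re-running with the same configuration and seed
#' reproduces every file byte for byte.
#'
#' @param config A `pipeline_config` object.  `config$simulate` may override
#'   the simulation defaults: `n_contigs`, `mean_len`, `n_genes`, `gene_len`,
#'   `n_marked`, `enrichment_fold`, `n_fragments`, `frag_len_mean`,
#'   `long_frac`, `n_tissues`, `n_specific`, `n_broad`, `n_terms`,
#'   `n_samples`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- utils::modifyList(list(
    n_contigs = 50, mean_len = 30000, n_genes = 200, gene_len = 2000,
    n_marked = 20, enrichment_fold = 8, n_fragments = 25000,
    frag_len_mean = 300, long_frac = 0.05, n_tissues = 8,
    n_specific = 50, n_broad = 50, n_terms = 25, n_samples = 2
  ), config$simulate)
  seed <- config$seed

  genome <- generate_toy_genome(sim$n_contigs, sim$mean_len, seed = seed,
                                with_sequences = TRUE)
  annotation <- generate_annotation(genome, sim$n_genes, sim$gene_len,
                                    seed = seed)
  gene_ids <- dplyr::filter(annotation, .data$type == "gene")$feature_id
  marked <- with_stream(seed, "truth", {
    lapply(seq_len(sim$n_samples), function(i) sample(gene_ids, sim$n_marked))
  })
  names(marked) <- paste0("sample_", seq_len(sim$n_samples))
  # marked genes are designed to be expressed tissue-specifically, mirroring
  # the biology the pipeline is meant to recover
  specific <- with_stream(seed, "truth_specific", {
    extra <- setdiff(gene_ids, marked[[1]])
    unique(c(marked[[1]],
             sample(extra, max(0, sim$n_specific - length(marked[[1]])))))
  })
  broad <- with_stream(seed, "truth_broad",
                       sample(setdiff(gene_ids, specific),
                              min(sim$n_broad,
                                  length(setdiff(gene_ids, specific)))))
  truth <- ground_truth(
    marked_genes = marked,
    enrichment_fold = sim$enrichment_fold,
    specific_genes = specific,
    broad_genes = broad,
    planted_go_terms = "GO:0000001"
  )
  frag_sets <- generate_fragments(genome, annotation, truth,
                                  n_fragments = sim$n_fragments,
                                  frag_len_mean = sim$frag_len_mean,
                                  long_frac = sim$long_frac, seed = seed)
  expression <- generate_expression(annotation, sim$n_tissues, truth,
                                    seed = seed)
  maps <- generate_functional_maps(annotation, sim$n_terms, truth,
                                   seed = seed, odds_ratio = 10,
                                   conservation_odds = 6)

  write_contig_lengths(genome, file.path(outdir, "contig_lengths.tsv"))
  write_annotation_gff3(annotation, file.path(outdir, "annotation.gff3"),
                        genome = genome)
  write_expression_tsv(expression, file.path(outdir, "expression.tsv"))
  write_functional_maps(maps, file.path(outdir, "go_map.tsv"),
                        file.path(outdir, "homology_map.tsv"))
  jsonlite::write_json(
    list(marked_genes = truth$marked_genes,
         enrichment_fold = truth$enrichment_fold,
         specific_genes = truth$specific_genes,
         broad_genes = truth$broad_genes,
         planted_go_terms = truth$planted_go_terms),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, pretty = TRUE
  )

  regions <- gene_regions(annotation, genome, extension = config$extension)
  per_sample <- lapply(names(frag_sets), function(s) {
    frags <- filter_by_length(frag_sets[[s]], max_len = config$max_fragment)
    write_fragments_bed(frags, file.path(outdir, paste0("fragments_", s, ".bed")))
    pk <- peakcall_sample(frags, genome, bin_size = config$bin_size,
                          fdr_threshold = config$fdr,
                          merge_gap = config$merge_gap)
    readr::write_tsv(pk$bins, file.path(outdir, paste0("bins_", s, ".tsv")))
    write_peaks_bed(pk$peaks, file.path(outdir, paste0("peaks_", s, ".bed")))
    sig <- assign_enriched_genes(regions, pk$peaks) |>
      quantify_fpkb(fragments = frags, n_total = nrow(frags))
    readr::write_tsv(
      dplyr::select(sig, "gene_id", "enriched", "count", "fpkb"),
      file.path(outdir, paste0("gene_signal_", s, ".tsv"))
    )
    list(sample = s, fragments = frags, peaks = pk$peaks, bins = pk$bins,
         signal = sig)
  })
  names(per_sample) <- names(frag_sets)

  enriched_sets <- lapply(per_sample, function(x) {
    x$signal$gene_id[x$signal$enriched]
  })
  results <- list(genome = genome, annotation = annotation, truth = truth,
                  samples = per_sample, enriched_sets = enriched_sets)

  if (length(per_sample) >= 2) {
    a <- per_sample[[1]]; b <- per_sample[[2]]
    fc <- pairwise_fold_calls(
      a$signal, b$signal, fold = config$fold,
      pseudo = fpkb_pseudocount(nrow(a$fragments))
    )
    readr::write_tsv(fc$table, file.path(outdir, "fold_comparison.tsv"))
    ic <- intersection_counts(enriched_sets)
    readr::write_tsv(as_tibble(ic), file.path(outdir, "intersection_cells.tsv"))
    sd <- set_difference_marked(enriched_sets[[1]], enriched_sets[[2]])
    common <- a$signal$gene_id[a$signal$enriched | b$signal$enriched]
    tt <- if (length(common) >= 2) {
      paired_t_signal(a$signal$fpkb[a$signal$gene_id %in% common],
                      b$signal$fpkb[b$signal$gene_id %in% common])
    } else NULL
    results$fold_comparison <- fc
    results$intersections <- ic
    results$set_difference <- sd
    results$paired_test <- tt
    jsonlite::write_json(
      list(set_totals = as.list(attr(ic, "set_totals")),
           union_size = attr(ic, "union_size"),
           core_size = attr(ic, "core_size"),
           a_only = length(sd$a_only), b_only = length(sd$b_only),
           both = length(sd$both),
           gained = length(fc$gained), lost = length(fc$lost),
           paired_t = if (is.null(tt)) NA else tt$t,
           paired_p = if (is.null(tt)) NA else tt$p),
      file.path(outdir, "comparison_summary.json"), auto_unbox = TRUE,
      pretty = TRUE
    )
  }

  targets <- enriched_sets[[1]]
  if (length(targets) > 0 && length(targets) < length(gene_ids)) {
    ec <- entropy_contrast(expression, targets = targets,
                           base = config$entropy_base)
    readr::write_tsv(ec$entropies, file.path(outdir, "gene_entropy.tsv"))
    jsonlite::write_json(glance(ec),
                         file.path(outdir, "entropy_contrast.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    results$entropy <- ec
    go <- hypergeom_go(targets, gene_ids, maps)
    results$go <- go
    cc <- conservation_contrast(targets, maps, gene_ids)
    results$conservation <- cc
  } else {
    ent <- expression_entropy(expression, base = config$entropy_base)
    readr::write_tsv(ent, file.path(outdir, "gene_entropy.tsv"))
    go <- hypergeom_go(character(), gene_ids, maps)[0, ]
    cc <- NULL
  }
  readr::write_tsv(go, file.path(outdir, "go_enrichment.tsv"))
  readr::write_tsv(
    if (is.null(cc)) tibble(category = character(), n = integer(),
                            n_marked = integer(), fraction = double())
    else cc$fractions,
    file.path(outdir, "conservation.tsv")
  )

  frags1 <- per_sample[[1]]$fragments
  track <- build_coverage(frags1, genome)
  write_bedgraph(track, file.path(outdir, "coverage.bedgraph"))
  motif <- select_signal_regions(track, threshold = config$motif_threshold,
                                 merge_gap = config$motif_merge)
  readr::write_tsv(motif[, c("contig", "start", "end")],
                   file.path(outdir, "motif_regions.bed"), col_names = FALSE)
  if (nrow(motif) > 0) {
    bg <- tryCatch(
      sample_matched_background(motif, genome,
                                seed = child_seed(seed, "motif_bg")),
      error = function(e) {
        warning("matched background skipped: ", conditionMessage(e),
                "\n(the signal threshold is per-bp coverage normalized by ",
                "total reads; on a small dense toy genome it must be raised ",
                "well above the genome-wide mean)", call. = FALSE)
        NULL
      }
    )
    export_region_fasta(motif, genome, file.path(outdir, "motif_query.fasta"))
    if (!is.null(bg)) {
      readr::write_tsv(bg[, c("contig", "start", "end")],
                       file.path(outdir, "motif_background.bed"),
                       col_names = FALSE)
      export_region_fasta(bg, genome,
                          file.path(outdir, "motif_background.fasta"))
    }
    results$motif <- list(regions = motif, background = bg)
  }

  outputs <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "crunmark",
    version = as.character(utils::packageVersion("crunmark")),
    seed = seed,
    parameters = config[setdiff(names(config), "simulate")],
    simulate = sim,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, outputs))), outputs
    ))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
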