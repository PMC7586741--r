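# crunmark

Gene-level profiling of repressive histone marks (H3K27me3 and similar) from
CUT&RUN fragment data mapped to **large, highly fragmented genome
assemblies** — the situation typical of conifers and other organisms whose
assemblies consist of tens of thousands of short contigs with no chromosome
scale. Standard peak callers assume deep local coverage and contiguous
chromosomes; `crunmark` instead implements a simple, transparent pipeline
built for sparse fragment pileups scattered over many contigs:

1. **Fragments** — mapped read pairs are merged into fragments
   (same-contig mates only), and fragments longer than 700 bp are discarded
   as background cleavage. Spike-in QC checks that spike-in read counts
   scale with sequencing depth (Pearson r).
2. **Peak calling** — every contig is tiled into 500 bp bins; the number of
   fragments overlapping each bin is tested against a uniform-placement
   binomial null. For a bin of width *w* on an effective genome of length
   *G*, with *N* mapped fragments of which *k* overlap the bin:

   p₀ = *w* / *G*,  p-value = P(X ≥ *k*),  X ~ Binomial(*N*, p₀)

   P-values are Benjamini–Hochberg adjusted genome-wide; bins with
   FDR ≤ 10⁻²⁵ are selected and merged into peaks when separated by less
   than 100 bp.
3. **Gene signal** — a gene is *marked* when a peak overlaps its body
   ±500 bp; its signal intensity is FPKB, fragments per kilobase of
   (extended) gene region per billion mapped fragments:
   fpkb = *k* / (len/1000) / (*N*/10⁹). Samples are compared by paired
   t-tests on intensities, ≥2-fold gained/lost calls, set differences and
   UpSet-style exclusive intersections.
4. **Specificity** — Shannon entropy H = −Σ pᵢ ln pᵢ of each gene's
   expression across a tissue/condition panel; marked vs unmarked gene sets
   are contrasted with a Wilcoxon rank-sum test (condition-specific genes
   have low entropy).
5. **Enrichment** — GO terms are inherited through best-hit homologues of a
   reference species and tested by the upper-tail hypergeometric
   distribution over the homologue-bearing gene universe; a conservation
   contrast asks whether genes marked in the study species are
   over-represented among homologues of reference-marked genes.
6. **Motif regions** — per-bp coverage normalized by total reads; runs
   strictly above a threshold (default 8.0×10⁻⁷ reads/total reads) merged
   below 101 bp become query regions, and length-matched background
   intervals are sampled for external motif discovery (FASTA export).

A first-class **synthetic-data module** generates toy genomes, annotations,
fragment sets with planted enrichment, designed expression panels and
GO/homology maps with known ground truth, so the entire pipeline is testable
end to end with no external data.

## Worked example

```r
library(crunmark)

genome     <- generate_toy_genome(n_contigs = 50, mean_len = 20000, seed = 7)
annotation <- generate_annotation(genome, n_genes = 100, gene_len = 2000, seed = 7)
truth      <- ground_truth(marked_genes = list(EC = annotation$feature_id[1:10]),
                           enrichment_fold = 10)
frags <- generate_fragments(genome, annotation, truth,
                            n_fragments = 20000, long_frac = 0.05, seed = 7)$EC
frags <- filter_by_length(frags, max_len = 700)   # 24482 kept, 1228 removed

pk <- peakcall_sample(frags, genome, bin_size = 500,
                      fdr_threshold = 1e-25, merge_gap = 100)
nrow(pk$peaks)
#> [1] 10

sig <- gene_regions(annotation, genome, extension = 500) |>
  assign_enriched_genes(peaks = pk$peaks) |>
  quantify_fpkb(fragments = frags, n_total = nrow(frags))
sum(sig$enriched)
#> [1] 11
head(dplyr::arrange(sig, dplyr::desc(fpkb)), 3)[, c("gene_id", "enriched", "count", "fpkb")]
#> # A tibble: 3 × 4
#>   gene_id enriched count     fpkb
#>   <chr>   <lgl>    <int>    <dbl>
#> 1 g0053   TRUE       633 8618577.
#> 2 g0004   TRUE       628 8550500.
#> 3 g0083   TRUE       628 8550500.
```

Ten planted loci yield ten peaks; eleven genes are called marked (the ten
planted genes plus one neighbour whose ±500 bp extension touches a peak —
exactly the behaviour the extended-region overlap rule implies). FPKB values
around 8.6×10⁶ correspond to ~630 fragments on a 3 kb extended region in a
24,482-fragment library.

`run_pipeline(pipeline_config(seed = 1), outdir = "out")` runs every stage on
a freshly simulated two-sample study and writes TSV/BED/FASTA/JSON outputs
plus a manifest; re-running with the same seed reproduces every file byte for
byte. `tidy()`/`glance()` methods and `plot_*()`/`autoplot()` functions
summarize and display the result objects.

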