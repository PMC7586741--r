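---
title: "Methods: binned binomial peak calling and gene-level mark analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned binomial peak calling and gene-level mark analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crunmark)
```

## The problem

CUT&RUN releases nucleosome-sized DNA fragments at antibody-bound loci, with
much lower background than conventional ChIP. Profiling a repressive mark
such as H3K27me3 in a conifer-scale genome poses two difficulties that
standard peak callers handle poorly: the assembly is split across a huge
number of short contigs, and genome-wide coverage is extremely sparse, so
local-background ("lambda") models have little data to estimate from. The
pipeline implemented here takes the opposite approach: a single global null,
fixed-width bins, and an extremely stringent FDR cutoff, followed by
gene-level summaries that are robust to assembly fragmentation.

## The statistical core

**Fragments.** Read pairs mapped to the same contig are merged into one
fragment spanning both mates; cross-contig and unpaired mates are discarded
and counted. Fragments longer than 700 bp are removed (strictly longer:
a 700 bp fragment is kept) — long fragments are dominated by nonspecific
cleavage. No deduplication and no MAPQ filtering are applied; the mapped
intervals are taken as given. Strand is ignored throughout.

**Binomial bin test.** Each contig is tiled into 500 bp bins (terminal bin
truncated). A fragment counts toward every bin it overlaps by at least 1 bp,
so fragments spanning a bin boundary are counted twice — this follows the
overlap-counting definition literally and slightly couples neighbouring
bins, which is harmless at the FDR threshold used. Under the null that each
of the $N$ filtered fragments is placed uniformly on the genome, the count
$k$ in a bin of width $w$ is $\mathrm{Binomial}(N, w/G)$ with $G$ the
effective genome length (default: the summed contig lengths, overridable —
a mappability-corrected length can be supplied instead). The reported
p-value is the one-sided upper tail $P(X \ge k)$: only enrichment is called,
never depletion. Zero-count bins get $p = 1$.

The null deserves emphasis: uniform placement is the *simplest* model
consistent with a binomial per-bin test, and it is intentionally
conservative about nothing — real coverage is overdispersed, which is why
the selection threshold is so stringent (below). The choice of whether $N$
counts fragments or read ends, and whether $G$ is mappability-corrected,
are left as configuration; defaults are fragments and raw assembly length.

**FDR and peaks.** P-values are Benjamini–Hochberg adjusted in one
genome-wide family including zero-count bins (no exclusion rule is applied
before adjustment). Bins with $q \le 10^{-25}$ become peak seeds; seeds on
one contig separated by a gap strictly shorter than 100 bp are merged
transitively. With contiguous 500 bp bins, inter-seed gaps are either 0 or
$\ge 500$ bp, so the default merge only ever joins adjacent bins — the merge
is nevertheless implemented generically so that arbitrary seed intervals
(e.g. re-merging called peaks) behave sensibly; peak calling is idempotent
under re-merging.

**Gene-level calls and FPKB.** A gene is marked when any peak overlaps its
body extended by 500 bp on each side (half-open intervals; an abutting peak
does not count). The same extended region is used for intensity:
$\mathrm{fpkb} = k / (L/1000) / (N/10^9)$ with $L$ the extended length.
Using one window for both call and intensity keeps the two summaries
consistent; a body-only window can be obtained by setting the extension
to 0. Pairwise comparisons flag genes whose pseudocounted intensity ratio
is $\ge 2$ ("twice or more", inclusive). The default pseudocount is the
FPKB a single fragment would produce on a 1 kb region ($10^9/N$), which
keeps ratios finite and unit-consistent; a pseudocount of this form, rather
than a fixed constant, makes the 2-fold rule depth-independent. The paired
t-test on intensities is computed from the closed form so that degenerate
inputs have defined behaviour: all-zero differences give $t = 0, p = 1$;
constant nonzero differences give a diverging statistic, reported as
$p = 0$ with an explicit degeneracy flag.

**Expression specificity.** For each gene, expression across a panel of
$T$ tissues or conditions is normalized to proportions and summarized by
Shannon entropy $H = -\sum p_i \ln p_i \in [0, \ln T]$ (natural log by
default, configurable base; the value is invariant to rescaling a profile).
Genes with zero total expression are excluded and counted — entropy is
undefined for them and any imputation would be arbitrary. Marked and
unmarked gene sets are compared with a two-sided Wilcoxon rank-sum test.
The choice of rank-sum is a package decision (the comparison is between two
skewed bounded distributions; no normality is assumed) and is recorded in
the output object.

**GO enrichment through homology.** Genes inherit GO terms from their
best-hit homologue in a reference species (first listed hit when several
are given); genes without a homologue ("orphans") are removed from both
sample and background *before* testing, so the universe is the
homologue-bearing gene set. Per term, the upper-tail hypergeometric
p-value and the enrichment ratio
$(k/n_{\mathrm{sample}})/(K/n_{\mathrm{background}})$ are reported; raw
p-values are primary (matching the flat-table convention of such analyses)
with BH adjustment available as an optional column. No GO-graph
propagation is performed. The conservation contrast splits genes into
homologue-of-marked / homologue-of-unmarked / orphan and tests
over-representation of study-species marked genes in the first category
with the same hypergeometric tail.

**Motif regions.** Coverage is fragments-per-bp divided by total fragments
(reads per total reads per bp). Runs strictly above the threshold are
selected (values exactly at the threshold never seed a region), merged when
gaps are shorter than 101 bp, and exported as FASTA together with
length-matched background: one background interval per query, identical
length, placed uniformly over contigs long enough to hold it and rejected
if it overlaps any query region (a deliberate tightening over plain random
sampling, to keep the control set uncontaminated; it can be switched off).
The raw per-bp track is thresholded — no smoothing is applied.

## The synthetic-data generator

The generator is the package's test bed and defines what the validation
results mean. It emulates:

* a fragmented assembly — contig lengths lognormal (sdlog 0.4, floor
  500 bp) around a configurable mean, so contigs vary several-fold while
  total assembly size is predictable;
* sparse fragment pileups — `n_fragments` background fragments placed
  uniformly (contig chosen proportional to length), plus Poisson extras
  over each marked gene ±500 bp raising density there to
  `enrichment_fold` × background; fragment starts are uniform within their
  region and lengths are truncated normal (mean 300 bp, sd mean/4, floor
  50 bp), with a configurable fraction of contaminants uniform in
  (700, 2000] bp to exercise the size-filter boundary;
* designed expression — specific genes expressed in one tissue
  (round-robin assignment) with a small leakage elsewhere, broad genes
  near-uniform, multiplicative log-normal noise;
* functional maps — a configurable orphan fraction, one-to-one homology,
  and planted GO terms whose assignment odds among a target gene set are
  boosted by a chosen odds ratio.

All randomness flows from one seed through named child streams
(`child_seed()`), so regenerating one artifact never perturbs another and
fixed seeds give byte-identical files.

What the generator does **not** emulate: mapping error, duplicate reads,
GC/mappability bias, overdispersed (clumped) background, copy-number
variation, or spike-in sequence content. Passing recovery tests therefore
demonstrate that the implementation is faithful to its definitions and that
the statistics behave as designed under their own null — not that the
pipeline is robust to every artefact of real libraries.

## Study conditions used in validation

Recovery checks run at "desk scale": toy assemblies of ~1–1.5 Mbp over
50 contigs, 30–200 genes of 2 kb, and 20,000–37,500 fragments per sample.
These sizes keep the whole suite fast while leaving every statistic in a
regime where recovery is decisively expected: with 8–10-fold enrichment the
design places an expectation of roughly 100 fragments on each marked 500 bp
bin against a null expectation near 10, for which the upper binomial tail
lies far below the $10^{-25}$ FDR cutoff. At the lower floor of ~40
expected fragments per marked bin the tail probability sits near the
cutoff itself and recovery becomes marginal — the deep-coverage design was
chosen a priori for that reason. The planted-locus experiment places its
three marked genes on distinct contigs so that "three loci" cannot collapse
into fewer peaks by adjacency; neighbouring genes within ~1 kb of a marked
gene are legitimately called marked by the extended-overlap rule and are
accounted as false positives only in the gene-level recovery check, whose
tolerance (FPR ≤ 5%) they do not threaten.

One default does not transfer to toy scale: the motif-region threshold
(8.0×10⁻⁷ reads/total reads) is an absolute normalized-coverage value
calibrated to a multi-Gbp genome. Mean background normalized coverage
equals mean fragment length divided by genome length, i.e. ~1.5×10⁻⁸ at
20 Gbp but ~3×10⁻⁴ at 1 Mbp — on a toy genome the default would select
essentially everything. The demonstration pipeline therefore passes a
toy-scale threshold (around 10⁻³–10⁻²) chosen between the background and
enriched coverage levels; the packaged default remains the published value,
and `run_pipeline()` degrades gracefully (background sampling skipped with
a warning) if an ill-matched threshold makes matched-background placement
infeasible.

## Numerical and design notes

* Coordinates are 0-based half-open everywhere internally and in BED
  output; GFF3 conversion (1-based closed) happens only at the I/O
  boundary, in both directions.
* `adjust_bh()` delegates to `p.adjust(method = "BH")`; the test suite
  verifies it against an independent hand-written step-up implementation,
  and the binomial/hypergeometric tails against direct log-space summation
  and combinatorial enumeration.
* Ties in the fold-change rule are inclusive (`>=`), matching "twice or
  more"; `gained` and `lost` are provably disjoint for any fold > 1.
* `intersection_counts()` assigns every gene in the union to exactly one
  exclusive cell, so cell counts always sum to the union size.
* Degenerate inputs are defined, not accidental: zero mapped fragments
  give all-1 p-values / zero FPKB with warnings; an FDR threshold of 0
  yields zero peaks and empty-but-valid downstream outputs; empty region
  sets export empty FASTA.

## Limitations

The uniform binomial null ignores local biases; there is no control-sample
(IgG/input) normalization, no summit estimation, and no local-background
model — all are out of scope by design. GO enrichment does not propagate
terms up the ontology graph, and the homology mapping is best-hit
one-to-one. The expression unit fed to the entropy computation is taken as
given (any non-negative unit works; entropy is scale-invariant per gene,
but not invariant to changing units across conditions).
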