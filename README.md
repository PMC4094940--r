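# retrosite

Genome-wide profiling of retroviral vector integration sites.

Integrating gene-therapy vectors (gamma-retroviral, lentiviral,
alpharetroviral) insert their payload at a single genomic base recovered by
LM-PCR amplification of the vector–genome junction. Where a vector
integrates — near transcription start sites, inside transcribed genes, in
repeats, in epigenetically active chromatin, or clustered into hot spots —
determines its genotoxic risk. `retrosite` implements the standard
integration-site analysis for anyone comparing vector platforms or
characterising an insertion-site dataset against an in-silico random
control:

- **Junction-read processing** — filter short alignments, resolve
  multi-mapping reads by a percent-identity delta, collapse redundant reads
  sharing a junction coordinate `(chrom, pos, strand)` into unique sites,
  and rescue ambiguous reads univocally attributable to one repeat family.
- **Annotation** — classify each site as TSS-proximal (within ±2.5 kb of
  any TSS), intragenic, or intergenic; annotate feature tracks (CpG
  islands, conserved non-coding sequences, TFBSs, DNase I HS) overlapping a
  ±1 kb site window by ≥1 bp; assign the repeat family directly containing
  the site base; list target genes with a TSS within ±50 kb.
- **Profiles** — TSS-distance histograms at coarse (2.5 kb) and fine
  (50 bp) resolution; mean ChIP-seq fragment density in a 5-kb window
  around sites; chromatin-state assignment (Promoter / Enhancer /
  Transcribed / Heterochromatin) from histone-mark combinations
  (H3K4me3, H3K4me1, H3K36me3, H3K27me3), accepting only sites
  unambiguously matching exactly one state rule.
- **Cluster (hot-spot) calling** — a numerosity-adjusted scan statistic:
  modelling `n` sites on an effective genome of length `L` as a homogeneous
  Poisson process, the cluster window `w` is the largest value with
  `P(Poisson(n·w/L) ≥ k−1) ≤ α` (defaults `k = 3`, `α = 0.01`), so larger
  datasets get proportionally tighter windows; any ≥ `k` sites spanning
  ≤ `w` seed a cluster and chained windows merge maximally.
- **Dataset comparison** — two-sided Fisher's exact tests on every
  (dataset pair × category) 2×2 table, starred at `p < 0.01`.
- **Synthetic data** — a miniature genome plus site generators mixing
  TSS-Gaussian, gene-body and uniform placement, so the entire pipeline is
  testable without sequencing data.

All user-facing functions take a tibble first and return tibbles, so
stages chain with the pipe; coordinates are 0-based half-open throughout.

## Worked example

```r
library(retrosite)

genome <- make_genome(n_chroms = 2, chrom_len = 1e7, n_genes = 200, seed = 1)
sites  <- generate_sites(genome,
  site_config(8250, c(0.05, 0.15, 0.80), seed = 2, dataset = "vectorA"))

ann <- annotate_sites(sites, genome$genes,
  features = genome$features, repeats = genome$repeats)
summarize_annotation(ann)
#>    dataset category     count total percent
#>  4 vectorA INTERGENIC    4795  8250   58.1
#>  5 vectorA INTRAGENIC    2503  8250   30.3
#> 13 vectorA TSS_PROXIMAL   952  8250   11.5
#>  9 vectorA Repeat        1977  8250   24.0     (plus per-family rows ...)
```

The three region classes partition the dataset (58.1 + 30.3 + 11.5 = 100).
With a mixture that is 80% uniform, this vector is only mildly TSS-biased;
comparing against a 40,000-site uniform control still flags the bias,
because at these sample sizes even modest enrichments are significant:

```r
ctrl <- generate_sites(genome, site_config(40000, c(0, 0, 1), seed = 3,
  dataset = "control"))
summ <- summarize_annotation(
  classify_region(dplyr::bind_rows(sites, ctrl), genome$genes))
compare_categories(summ, categories = c("TSS_PROXIMAL", "INTRAGENIC", "INTERGENIC"))
#>   dataset_1 dataset_2 category         a     b    c    d odds_ratio         p
#> 1 control   vectorA   INTERGENIC   29637 10363 4795 3455      2.06  2.24e-177
#> 2 control   vectorA   INTRAGENIC    8431 31569 2503 5747      0.613 7.10e- 71
#> 3 control   vectorA   TSS_PROXIMAL  1932 38068  952 7298      0.389 1.66e-102
```

(the odds ratios are control-vs-vectorA here: the vector is ~2.6× enriched
at TSSs and depleted intergenically). Cluster calling adjusts its window to
the dataset size and genome length:

```r
def <- derive_threshold(n = nrow(sites), L = effective_genome_length(genome$chrom_sizes))
def
#> Cluster definition: >= 3 sites within 360 bp (alpha = 0.01, n = 8,250, L = 2e+07 bp)
cluster_summary(call_clusters(sites, def), nrow(sites))
#>   n_clusters clustered_sites pct_sites_in_clusters mean_cluster_dimension
#> 1        151             498                  6.04                   3.30
```

On a real 2.9-Gb genome the same `n = 8250` gives `w = 52,219` bp — tens of
kilobases, not hundreds of bases — which is why the window must be derived
per dataset rather than fixed. `autoplot()` methods render TSS profiles and
ChIP density curves; `tidy()`/`glance()` return model objects as tibbles.

`simulate_study()` and `run_integration_analysis()` run the whole pipeline
end-to-end, writing TSV/BED outputs and a run manifest;
`inst/scripts/run-analysis.R` wraps both for shell use.

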