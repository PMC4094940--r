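---
title: "Profiling retroviral integration sites: models, windows and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling retroviral integration sites: models, windows and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`retrosite` analyses where integrating retroviral vectors land in a genome.
This vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the decisions taken where the design was genuinely open.

## From junction reads to sites

An integration site is represented by a single base: the 0-based position
of the first genomic nucleotide flanking the vector's 3'-LTR. For a
plus-strand alignment this is the hit start; for a minus-strand alignment
it is `end − 1`. A single-base convention makes every window computation
unambiguous, at the cost of discarding the (chemistry-dependent) duplicated
target-site footprint, which none of the downstream statistics use.

Read processing makes three decisions, each with a tunable parameter:

* **Minimum genomic length** (`min_genomic_length`, bp, default 20). Reads
  whose best alignment spans less genome than this are discarded: below
  roughly 20 bp an LM-PCR junction fragment cannot be placed uniquely in a
  mammalian-sized genome. The value is a floor on mappability, not a
  biological quantity, and is exposed in `junction_config()`.
* **Ambiguity delta** (`ambiguity_identity_delta`, percentage points of
  alignment identity, default 2). A read is ambiguous when a second
  alignment lies within this delta of the best one. We treat identity as
  percent identity and the delta as an absolute percentage-point
  difference; a raw-score reading is accommodated by passing score-valued
  columns, since only differences are compared.
* **Redundancy key** `(chrom, pos, strand)`. Reads sharing a junction
  coordinate are sheared-DNA or PCR duplicates of one integration event and
  collapse into one site regardless of read length; `support` records how
  many collapsed.

Ambiguous reads are not thrown away: each candidate placement becomes a
flagged site sharing a `match_group`. The repeat analysis
(`build_repeat_set()`) rescues a group when *all* its placements fall in
repeat intervals of the same family — the read is then univocally
attributable to that family even though its coordinate is not known. This
is why a repeat-analysis set is always at least as large as the unique set.

## Window conventions

All annotation windows are **inclusive**: a site exactly 2,500 bp from a
TSS is TSS-proximal. Region classes are exclusive with precedence
TSS-proximal > intragenic > intergenic across overlapping genes, so the
three classes always partition a dataset and their percentages sum to 100.

* `tss_window` = 2,500 bp: the TSS-proximal half-width.
* `feature_window` = 1,000 bp with `min_overlap` = 1 bp: feature tracks
  (CpG, CNC, TFBS, DNase HS, histone marks) are annotated when any interval
  overlaps the ±1 kb window around the site base by at least one
  nucleotide.
* `target_gene_window` = 50,000 bp: genes whose TSS lies within ±50 kb are
  targets of the integration.
* Repeats are the deliberate exception: a repeat is assigned only when the
  site base itself falls inside the repeat interval ("directly targeted"),
  with no window. Overlapping repeats resolve to the smallest interval,
  then lexicographic family name — the smallest element is the most
  specific annotation at that base.

Whether the intragenic test should use the transcription span or some
extended gene body was open; we use the transcription span
`[tx_start, tx_end)` as the only interval both strands define identically.
Transcript isoforms sharing `(chrom, strand, tss, span)` are deduplicated
before classification and target counting to avoid double-counting one
locus.

Signed TSS distances follow the gene's orientation (positive = downstream
of the TSS into the gene); ties between equidistant TSSs break by
lexicographic gene id, which makes the whole annotation deterministic.

## Profiles

TSS-distance histograms come in a coarse (2,500-bp bins over ±50 kb) and a
fine variant. The fine bin width defaults to 50 bp and is configurable to
100 bp — both resolutions are conventional for promoter-scale maps and the
choice only affects visual granularity. Bins are right-closed,
`(start, end]`, with the single value at `−span` kept in the first bin;
distances outside the span are dropped and counted in an attribute, and
fractions are normalised over the sites actually binned, so fractions
always sum to 1 and total mass is invariant under rebinning.

ChIP-fragment density is mean per-base fragment coverage, binned (50 bp) in
a 5-kb window centred on each site and averaged over sites. The profile is
**not** flipped by site strand: integration orientation is essentially
random with respect to chromatin features, and an unflipped window keeps
the genomic orientation interpretable; callers wanting strand-centred
profiles can pre-flip coordinates. Coverage is computed exactly (via
interval arithmetic, not sampling), so density is linear in the fragment
track and a uniform tiling of depth *d* yields a flat profile at *d*.

Chromatin states are combinations of marks within the ±1 kb site window.
The exact combination table used with the original ChIP-seq compendia is
not published, so the default table encodes the conventional reading and is
fully user-overridable:

| State | required | forbidden |
|---|---|---|
| Promoter | H3K4me3 | — |
| Enhancer | H3K4me1 | H3K4me3 |
| Transcribed | H3K36me3 | H3K4me1, H3K4me3 |
| Heterochromatin | H3K27me3 | H3K4me1, H3K4me3, H3K36me3 |

A site receives a state only when **exactly one** rule matches — the
operational meaning of "unambiguously associated with one chromatin
state"; zero or multiple matches leave it unassigned, and the state summary
reports the unassigned fraction so state fractions sum to 1. H3K27ac is
accepted in custom rules but not used by the default table.

## The numerosity-adjusted cluster statistic

Hot-spot detection must be adjusted to dataset size: 3 sites within 50 kb
is startling among 8,000 sites but expected among 100,000. We model the
`n` sites of a dataset as a homogeneous Poisson process of rate `n / L` on
an effective genome of length `L` (chromosome totals minus assembly gaps),
and define the window `w` as the largest value such that the probability
that a given site has at least `k − 1` further sites within `w` downstream
is at most `α`:

$$P\!\left(\mathrm{Poisson}(n w / L) \ge k - 1\right) \le \alpha,
\qquad k = 3,\; \alpha = 0.01 .$$

The left side is monotone in `w`, so the equation is solved by
root-finding on the Poisson tail (machine tolerance on the rate, `w`
reported to 1 bp). For `n = 8,250` and `L` between 2.8 and 3.1 Gb this
yields `w` between roughly 50 and 56 kb; the published threshold of
53,920 bp for a same-sized dataset falls inside that bracket. The exact
algorithm used historically is unpublished, so ours is a documented
formulation in its own right and is not claimed to match it to the base
pair; it reproduces the operative behaviour (window in the tens of
kilobases, shrinking proportionally with `n`). Degenerate limits are
guarded: `α → 1` grows the bracket geometrically before root-finding, and
a derived window below 1 bp warns that the definition is degenerate.

Cluster calling then finds every set of ≥ `k` sites spanning ≤ `w` and
merges overlapping qualifying windows transitively into maximal clusters,
so a site belongs to at most one cluster and arbitrarily large chained
clusters (the published datasets reach 122 members) are representable. The
implementation slides over sorted positions; the test suite proves it
equivalent to exhaustive k-subset enumeration plus transitive merge on
randomized instances. `w` is recomputed per dataset from that dataset's
`n` — that is precisely what "adjusted to the numerosity of the sample"
requires.

Under the null, the expected number of window-qualifying anchor sites is
`n·α` by construction, which gives the calibration check: the false-positive
burden on uniform data scales linearly with `α`.

## Pairwise comparisons

Every between-dataset contrast is a two-sided Fisher's exact test on the
2×2 table (in category / not, per dataset). Two-sided Fisher p-values are
convention-dependent; we use the most common one — the sum of
probabilities of all tables with point probability not exceeding the
observed table's (the `stats::fisher.test` convention) — and cross-check
it against direct hypergeometric enumeration in the tests. The reported
odds ratio is the sample OR `(ad)/(bc)` (with 0/∞ for empty margins), not
the conditional MLE. Significance is `p < 0.01` and no multiple-testing
correction is applied by default, matching the analysis convention the
package reproduces; a `p.adjust` method can be requested. For
reproduction checks against published summary tables, counts are
reconstructed as `round(percent × total / 100)` — used only in tests and
the acceptance script, never in the pipeline.

## What the synthetic generator emulates — and what it does not

`make_genome()` builds a coordinates-only miniature genome: non-overlapping
genes with log-normal lengths (typically 10–60 kb), CpG islands near 60% of
TSSs, scattered CNC/TFBS/DNase intervals at documented densities, a
non-overlapping repeat track (~25% coverage; LINE/SINE/Satellite/LTR/Other
at weights 0.20/0.40/0.05/0.15/0.20), and histone-mark domains placed the
way they sit in real chromatin (H3K4me3 at TSSs, H3K4me1 flanking,
H3K36me3 over gene bodies minus the first 2 kb, H3K27me3 in gene-free
gaps). `generate_sites()` draws from a three-component mixture — Gaussian
around a uniformly chosen TSS (spread 500 bp, so ≥ 99.99% of that
component's mass lies within the ±2.5 kb TSS window), uniform within a
uniformly chosen gene span, uniform over the genome. A Gaussian (rather
than uniform-in-window) TSS component was chosen so fine-binned profiles
have a recoverable peaked shape. `generate_mark_fragments()` samples
fixed-length fragments with a configurable per-base enrichment ratio
(default 10:1) between mark domains and background.

The default study datasets (`simulate_study()`) use the published dataset
sizes — 13,097 gamma-retroviral-like, 8,250 alpharetroviral-like, 31,827
lentiviral-like, 40,000 random-control sites — with mixture weights chosen
once to express the qualitative tropisms: (0.25, 0.35, 0.40) TSS-biased,
(0.05, 0.15, 0.80) near-uniform, (0.03, 0.72, 0.25) gene-body-biased,
(0, 0, 1) control. The random control is uniform over the non-gap genome:
the historical control was "normalized" by an unpublished procedure
(restriction-site and mappability structure), which has no analogue at
synthetic scale, so uniform placement is the documented stand-in.

What passing tests on this generator *show* is that the pipeline's
operations implement their definitions correctly and that parameter
recovery, calibration and enrichment calls behave as designed. What they
do *not* show is fidelity to real genomes: no sequence, no mappability or
amplification bias, no isoform structure, no correlated feature geography
(real CpG/TFBS/DNase tracks co-locate far more than scattered intervals),
and a genome three orders of magnitude smaller. Percentages from synthetic
runs are therefore not comparable to published percentages; only the
statistical *calls* (enrichment directions, calibration, partition
properties) transfer.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere, including on disk (BED,
  refFlat-style TSV, chrom.sizes); sites are one-bp BED intervals.
* Empty inputs are answers, not errors: collapsing no reads gives no
  sites; an empty fragment track gives an all-zero profile; zero clusters
  summarise as count 0 with an absent mean dimension. Profiling an empty
  distance vector *is* an error (there is nothing to normalise).
* Sites on chromosomes absent from the gene table classify intergenic; a
  malformed alignment row is dropped with a warning rather than aborting a
  run.
* All tie-breaks are deterministic and documented: smallest repeat
  interval then lexicographic family; nearest TSS then lexicographic gene
  id; right-closed histogram bins.
* Generators restore the caller's RNG state; every stochastic stage takes
  an explicit seed, and fixed-seed runs are byte-identical.

## Problem sizes

The test suite exercises oracle equivalence on ~1,000-instance batches
(brute-force scans for region, feature and repeat annotation; exhaustive
subset enumeration for clustering at n ≤ 30 per instance), parameter
recovery at n = 10,000 sites on a 20-Mb genome, scan calibration on 20
replicates of 2,000 sites at three α levels, and null calibration of the
Fisher machinery on 500 simulated tables — sizes chosen so the whole suite
runs in about a minute while keeping Monte-Carlo error well inside the
asserted 3σ bands.

## Known limitations

* The cluster window derivation is a principled stand-in for an
  unpublished algorithm; absolute window sizes may differ by a few percent
  from historical analyses (bracketing, not equality, is the tested
  property).
* Chromatin-state output depends entirely on the supplied rule table and
  mark tracks (peaks or raw fragments are both accepted); the default
  table is a convention, not a fitted model.
* No mappability, GC or restriction-site correction of the random
  control; users comparing against real data should supply their own
  matched control sites.
* Exon/intron substructure, splice-site annotation and promoter sequence
  analysis are out of scope.
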