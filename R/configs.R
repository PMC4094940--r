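#' Junction-read processing parameters
#'
#' Controls how raw LM-PCR junction alignments are filtered, how multi-mapping
#' reads are classified as ambiguous, and which coordinates define redundancy.
#'
#' @param min_genomic_length Minimum aligned genomic length (bp) a read's best
#'   hit must reach to survive filtering. LM-PCR recovery of very short
#'   genomic tails cannot be mapped uniquely, so short reads are discarded.
#' @param ambiguity_identity_delta A read is ambiguous when two or more of its
#'   alignments lie within this many percentage points of identity of the best
#'   alignment. The default of 2 treats placements with identity difference
#'   below 2 points as indistinguishable.
#'
#' @return A list of class `junction_config`.
#' @export
#'
#' @examples
#' junction_config(min_genomic_length = 25)
junction_config <- function(min_genomic_length = 20, ambiguity_identity_delta = 2) {
  if (min_genomic_length < 1) abort("`min_genomic_length` must be >= 1")
  if (ambiguity_identity_delta <= 0) abort("`ambiguity_identity_delta` must be > 0")
  structure(
    list(
      min_genomic_length = min_genomic_length,
      ambiguity_identity_delta = ambiguity_identity_delta
    ),
    class = "junction_config"
  )
}

#' Annotation window parameters
#'
#' The window conventions used to classify integration sites against gene
#' models and feature tracks. All windows are inclusive: a site at exactly
#' `tss_window` bp from a TSS is still TSS-proximal.
#'
#' @param tss_window Half-width (bp) of the TSS-proximal window; a site within
#'   +/- this distance of any gene's TSS is classified TSS-proximal.
#' @param feature_window Half-width (bp) of the window around a site used for
#'   feature-track overlap (CpG islands, CNCs, TFBSs, DNase HS, histone marks).
#' @param target_gene_window Half-width (bp) of the window within which genes
#'   count as targets of an integration (distance measured TSS to site).
#' @param min_overlap Minimum overlap (bp) between a feature interval and the
#'   site window for the feature to be annotated.
#'
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(tss_window = 2500, feature_window = 1000,
                              target_gene_window = 50000, min_overlap = 1) {
  stopifnot(tss_window > 0, feature_window > 0, target_gene_window > 0, min_overlap >= 1)
  structure(
    list(
      tss_window = tss_window,
      feature_window = feature_window,
      target_gene_window = target_gene_window,
      min_overlap = min_overlap
    ),
    class = "annotation_config"
  )
}

#' Profile binning parameters
#'
#' Bin layouts for the TSS-distance histograms and the ChIP-fragment density
#' profile around integration sites.
#'
#' @param span Half-width (bp) of the coarse TSS-distance profile.
#' @param coarse_bin Coarse bin width (bp); must divide `span`.
#' @param fine_span Half-width (bp) of the fine TSS-distance profile.
#' @param fine_bin Fine bin width (bp); must divide `fine_span`. 50 by
#'   default; 100 is the other conventional choice.
#' @param chip_window Total width (bp) of the ChIP density window centred on
#'   each site (5 kb default, i.e. +/- 2.5 kb).
#' @param chip_bin ChIP profile bin width (bp); must divide `chip_window`.
#'
#' @return A list of class `profile_config`.
#' @export
profile_config <- function(span = 50000, coarse_bin = 2500,
                           fine_span = 2500, fine_bin = 50,
                           chip_window = 5000, chip_bin = 50) {
  if (span %% coarse_bin != 0) abort("`span` must be divisible by `coarse_bin`")
  if (fine_span %% fine_bin != 0) abort("`fine_span` must be divisible by `fine_bin`")
  if (chip_window %% chip_bin != 0) abort("`chip_window` must be divisible by `chip_bin`")
  structure(
    list(
      span = span, coarse_bin = coarse_bin,
      fine_span = fine_span, fine_bin = fine_bin,
      chip_window = chip_window, chip_bin = chip_bin
    ),
    class = "profile_config"
  )
}

#' Default chromatin-state rule table
#'
#' Each state is defined by a combination of histone marks that must be
#' present and marks that must be absent in the +/- 1 kb window around a
#' site. A site is assigned a state only when exactly one rule matches
#' (unambiguous association); otherwise it is left unassigned.
#'
#' The default table captures the conventional reading of the marks:
#' H3K4me3 marks active/poised promoters, H3K4me1 without H3K4me3 marks
#' enhancers, H3K36me3 marks transcribed gene bodies, and H3K27me3 marks
#' repressed/heterochromatic domains. H3K27ac may be used in custom tables
#' as an additional qualifier.
#'
#' @return A tibble with columns `state`, `required` (list of character),
#'   `forbidden` (list of character).
#' @export
#'
#' @examples
#' chromatin_state_rules()
chromatin_state_rules <- function() {
  tibble(
    state = c("Promoter", "Enhancer", "Transcribed", "Heterochromatin"),
    required = list("H3K4me3", "H3K4me1", "H3K36me3", "H3K27me3"),
    forbidden = list(
      character(0),
      "H3K4me3",
      c("H3K4me1", "H3K4me3"),
      c("H3K4me1", "H3K4me3", "H3K36me3")
    )
  )
}
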