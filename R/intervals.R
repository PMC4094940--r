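# Internal bridges between 0-based half-open tibble intervals and
# IRanges/GenomicRanges (1-based closed). All public interfaces stay tabular.

# tibble with chrom/start/end (0-based half-open) -> GRanges
as_gr <- function(df, start_col = "start", end_col = "end") {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(
      start = df[[start_col]] + 1L,
      end = df[[end_col]]
    )
  )
}

# single-base site positions -> GRanges points
sites_gr <- function(sites, flank = 0) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(
      start = sites$pos + 1L - flank,
      end = sites$pos + 1L + flank
    )
  )
}

# overlap pairs between two 0-based half-open interval tibbles;
# returns tibble(query, subject) of row indices
overlap_pairs <- function(query_gr, subject_gr, min_overlap = 1L) {
  # chromosomes present on one side only simply never overlap; silence the
  # seqlevel-mismatch warning GenomicRanges emits for that situation
  hits <- suppressWarnings(GenomicRanges::findOverlaps(query_gr, subject_gr,
    minoverlap = as.integer(min_overlap)
  ))
  tibble(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits)
  )
}

assert_sites <- function(sites, arg = "sites") {
  needed <- c("chrom", "pos")
  missing <- setdiff(needed, names(sites))
  if (length(missing) > 0) {
    abort(paste0("`", arg, "` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(sites)
}

assert_genes <- function(genes) {
  needed <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  missing <- setdiff(needed, names(genes))
  if (length(missing) > 0) {
    abort(paste0("`genes` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(genes$tx_start >= genes$tx_end)) {
    abort("`genes` has rows with tx_start >= tx_end")
  }
  invisible(genes)
}

# strand-aware TSS: txStart on +, txEnd - 1 on -
with_tss <- function(genes) {
  if (!"tss" %in% names(genes)) {
    genes <- mutate(genes, tss = if_else(.data$strand == "+", .data$tx_start, .data$tx_end - 1L))
  }
  genes
}

# collapse transcript isoforms sharing (chrom, strand, tss, span)
dedup_gene_models <- function(genes) {
  genes %>%
    with_tss() %>%
    arrange(.data$gene_id) %>%
    distinct(.data$chrom, .data$strand, .data$tss, .data$tx_start, .data$tx_end,
      .keep_all = TRUE
    )
}
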