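#' Classify integration sites relative to gene models
#'
#' Each site gets exactly one region class, with precedence
#' TSS-proximal > intragenic > intergenic across any overlapping genes:
#' `TSS_PROXIMAL` when the site lies within +/- `tss_window` bp (inclusive)
#' of the TSS of any gene; `INTRAGENIC` when it falls inside a transcription
#' span `[tx_start, tx_end)` but beyond the TSS window; `INTERGENIC`
#' otherwise. Transcript isoforms sharing (chrom, strand, tss, span) are
#' deduplicated before classification. Sites on chromosomes absent from the
#' gene table are intergenic.
#'
#' @param sites Site tibble with at least `chrom` and `pos` (0-based).
#' @param genes Gene-model tibble: `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end` (0-based half-open); a `tss` column is derived if absent.
#' @param config An [annotation_config()].
#'
#' @return `sites` with an added `region` factor column.
#' @export
#'
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = "G1", chrom = "chr1", strand = "+",
#'   tx_start = 10000L, tx_end = 20000L
#' )
#' sites <- tibble::tibble(chrom = "chr1", pos = c(11500L, 15000L, 50000L))
#' classify_region(sites, genes)$region
classify_region <- function(sites, genes, config = annotation_config()) {
  sites <- assert_sites(as_tibble(sites))
  genes <- dedup_gene_models(assert_genes(as_tibble(genes)))
  region <- rep("INTERGENIC", nrow(sites))
  if (nrow(genes) > 0 && nrow(sites) > 0) {
    pts <- sites_gr(sites)
    w <- config$tss_window
    tss_win <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$tss + 1L - w, end = genes$tss + 1L + w)
    )
    body <- as_gr(genes, "tx_start", "tx_end")
    in_body <- unique(S4Vectors::queryHits(
      suppressWarnings(GenomicRanges::findOverlaps(pts, body))
    ))
    region[in_body] <- "INTRAGENIC"
    near_tss <- unique(S4Vectors::queryHits(
      suppressWarnings(GenomicRanges::findOverlaps(pts, tss_win))
    ))
    region[near_tss] <- "TSS_PROXIMAL"
  }
  sites$region <- factor(region, levels = c("TSS_PROXIMAL", "INTRAGENIC", "INTERGENIC"))
  sites
}

#' Signed distance from each site to its nearest TSS
#'
#' The distance is measured to the nearest TSS on the site's chromosome and
#' signed in the orientation of that gene: positive means downstream of the
#' TSS (into the gene), negative upstream. Ties between equidistant TSSs are
#' broken by lexicographic gene id. Sites with no TSS within
#' +/- `target_gene_window` get `NA` and are excluded from profiles.
#'
#' @inheritParams classify_region
#'
#' @return `sites` with added `tss_distance` (signed bp, `NA` when no gene
#'   is in range) and `tss_gene` columns.
#' @export
tss_distance <- function(sites, genes, config = annotation_config()) {
  sites <- assert_sites(as_tibble(sites))
  genes <- dedup_gene_models(assert_genes(as_tibble(genes)))

  # one representative gene per distinct TSS position (lexicographic id)
  reps <- genes %>%
    group_by(.data$chrom, .data$tss) %>%
    arrange(.data$gene_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()

  dist <- rep(NA_real_, nrow(sites))
  gene <- rep(NA_character_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    g <- reps %>% filter(.data$chrom == ch) %>% arrange(.data$tss)
    idx <- which(sites$chrom == ch)
    if (nrow(g) == 0 || length(idx) == 0) next
    pos <- sites$pos[idx]
    j <- findInterval(pos, g$tss)
    left_d <- ifelse(j >= 1, pos - g$tss[pmax(j, 1)], Inf)
    right_d <- ifelse(j < nrow(g), g$tss[pmin(j + 1, nrow(g))] - pos, Inf)
    use_left <- left_d < right_d |
      (left_d == right_d & ifelse(j >= 1 & j < nrow(g),
        g$gene_id[pmax(j, 1)] <= g$gene_id[pmin(j + 1, nrow(g))], TRUE
      ))
    pick <- ifelse(use_left, pmax(j, 1), pmin(j + 1, nrow(g)))
    absd <- pmin(left_d, right_d)
    strand <- g$strand[pick]
    tss <- g$tss[pick]
    signed <- ifelse(strand == "+", pos - tss, tss - pos)
    in_range <- absd <= config$target_gene_window
    dist[idx[in_range]] <- signed[in_range]
    gene[idx[in_range]] <- g$gene_id[pick][in_range]
  }
  sites$tss_distance <- dist
  sites$tss_gene <- gene
  sites
}

#' Annotate feature-track overlap around each site
#'
#' A feature class is annotated at a site when any interval of that class
#' overlaps the +/- `feature_window` bp window around the site base by at
#' least `min_overlap` bp. This is the convention used for CpG islands,
#' CNCs, conserved TFBSs, DNase I hypersensitive sites and histone-mark
#' intervals alike.
#'
#' @inheritParams classify_region
#' @param features Feature tibble: `class`, `chrom`, `start`, `end`
#'   (0-based half-open).
#'
#' @return `sites` with an added `features_hit` list-column of character
#'   vectors (sorted feature classes hit; empty when none).
#' @export
annotate_features <- function(sites, features, config = annotation_config()) {
  sites <- assert_sites(as_tibble(sites))
  features <- as_tibble(features)
  hit_list <- rep(list(character(0)), nrow(sites))
  if (nrow(features) > 0 && nrow(sites) > 0) {
    win <- sites_gr(sites, flank = config$feature_window)
    pairs <- overlap_pairs(win, as_gr(features), min_overlap = config$min_overlap)
    if (nrow(pairs) > 0) {
      got <- pairs %>%
        mutate(class = features$class[.data$subject]) %>%
        distinct(.data$query, .data$class) %>%
        group_by(.data$query) %>%
        summarise(classes = list(sort(.data$class)), .groups = "drop")
      hit_list[got$query] <- got$classes
    }
  }
  sites$features_hit <- hit_list
  sites
}

#' Assign the repeat family directly targeted by each site
#'
#' Unlike feature-track annotation, repeats count only when the site base
#' itself falls inside the repeat interval (direct targeting), with no
#' window. When overlapping repeats contain the base, the smallest interval
#' wins, then lexicographic family name.
#'
#' @inheritParams classify_region
#' @param repeats Repeat tibble: `chrom`, `start`, `end`, `family`.
#'
#' @return `sites` with an added `repeat_family` column (`NA` when the base
#'   is outside all repeats).
#' @export
assign_repeat <- function(sites, repeats) {
  sites <- assert_sites(as_tibble(sites))
  repeats <- as_tibble(repeats)
  fam <- rep(NA_character_, nrow(sites))
  if (nrow(repeats) > 0 && nrow(sites) > 0) {
    pairs <- overlap_pairs(sites_gr(sites), as_gr(repeats))
    if (nrow(pairs) > 0) {
      best <- pairs %>%
        mutate(
          width = repeats$end[.data$subject] - repeats$start[.data$subject],
          family = repeats$family[.data$subject]
        ) %>%
        arrange(.data$query, .data$width, .data$family) %>%
        distinct(.data$query, .keep_all = TRUE)
      fam[best$query] <- best$family
    }
  }
  sites$repeat_family <- fam
  sites
}

#' Genes targeted by each integration site
#'
#' Every gene whose TSS lies within +/- `target_gene_window` bp of a site is
#' a target of that integration. Isoforms sharing (chrom, strand, tss, span)
#' are deduplicated first.
#'
#' @inheritParams classify_region
#'
#' @return A long tibble with one row per (site, target gene):
#'   `site_id` (row number in `sites`), `gene_id`, `tss_distance` (signed as
#'   in [tss_distance()]), sorted by absolute distance within each site.
#' @export
target_genes <- function(sites, genes, config = annotation_config()) {
  sites <- assert_sites(as_tibble(sites))
  genes <- dedup_gene_models(assert_genes(as_tibble(genes)))
  if (nrow(sites) == 0 || nrow(genes) == 0) {
    return(tibble(site_id = integer(0), gene_id = character(0), tss_distance = numeric(0)))
  }
  w <- config$target_gene_window
  win <- sites_gr(sites, flank = w)
  tss_pts <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$tss + 1L, width = 1L)
  )
  pairs <- overlap_pairs(win, tss_pts)
  pairs %>%
    mutate(
      site_id = .data$query,
      gene_id = genes$gene_id[.data$subject],
      tss = genes$tss[.data$subject],
      strand = genes$strand[.data$subject],
      pos = sites$pos[.data$query],
      tss_distance = ifelse(.data$strand == "+", .data$pos - .data$tss, .data$tss - .data$pos)
    ) %>%
    filter(abs(.data$tss_distance) <= w) %>%
    arrange(.data$site_id, abs(.data$tss_distance), .data$gene_id) %>%
    select("site_id", "gene_id", "tss_distance")
}

#' Fraction of target genes that are actively expressed
#'
#' Joins the distinct target-gene set against an expression table and
#' reports the fraction above a threshold. Genes missing from the table are
#' counted as not expressed and reported separately.
#'
#' @param targets Character vector of gene ids, or a tibble with a
#'   `gene_id` column (e.g. from [target_genes()]).
#' @param expression Tibble with columns `gene_id` and `value`.
#' @param threshold Expression value strictly above which a gene counts as
#'   expressed.
#'
#' @return A one-row tibble: `fraction`, `n_targets`, `n_expressed`,
#'   `n_missing`. `fraction` is `NA` for an empty target set.
#' @export
expressed_target_fraction <- function(targets, expression, threshold = 0) {
  if (is.data.frame(targets)) targets <- targets$gene_id
  targets <- unique(targets)
  if (length(targets) == 0) {
    return(tibble(fraction = NA_real_, n_targets = 0L, n_expressed = 0L, n_missing = 0L))
  }
  expression <- as_tibble(expression)
  val <- expression$value[match(targets, expression$gene_id)]
  n_missing <- sum(is.na(val))
  n_expressed <- sum(!is.na(val) & val > threshold)
  tibble(
    fraction = n_expressed / length(targets),
    n_targets = length(targets),
    n_expressed = as.integer(n_expressed),
    n_missing = as.integer(n_missing)
  )
}

#' Full per-site annotation
#'
#' Convenience wrapper running region classification, TSS distance, feature
#' overlap and repeat-family assignment in one pass.
#'
#' @inheritParams classify_region
#' @param features Optional feature tibble (see [annotate_features()]).
#' @param repeats Optional repeat tibble (see [assign_repeat()]).
#'
#' @return `sites` with `region`, `tss_distance`, `tss_gene`,
#'   `features_hit` (when `features` given) and `repeat_family` (when
#'   `repeats` given) columns added.
#' @export
annotate_sites <- function(sites, genes, features = NULL, repeats = NULL,
                           config = annotation_config()) {
  out <- sites %>%
    classify_region(genes, config) %>%
    tss_distance(genes, config)
  if (!is.null(features)) out <- annotate_features(out, features, config)
  if (!is.null(repeats)) out <- assign_repeat(out, repeats)
  out
}

#' Per-dataset annotation summary
#'
#' Counts and percentages per category (the three region classes plus each
#' feature class hit) per dataset, the shape used for between-dataset
#' enrichment comparisons.
#'
#' @param annotated Output of [annotate_sites()] with a `dataset` column.
#'
#' @return Tibble with columns `dataset`, `category`, `count`, `total`,
#'   `percent`.
#' @export
summarize_annotation <- function(annotated) {
  annotated <- as_tibble(annotated)
  if (!"dataset" %in% names(annotated)) annotated$dataset <- "sites"
  totals <- annotated %>% count(.data$dataset, name = "total")

  reg <- annotated %>%
    count(.data$dataset, category = as.character(.data$region), name = "count")
  out <- reg
  if ("features_hit" %in% names(annotated)) {
    feat <- annotated %>%
      select("dataset", "features_hit") %>%
      tidyr::unnest_longer("features_hit", values_to = "category") %>%
      filter(!is.na(.data$category)) %>%
      count(.data$dataset, .data$category, name = "count")
    out <- bind_rows(out, feat)
  }
  if ("repeat_family" %in% names(annotated)) {
    reps <- annotated %>%
      filter(!is.na(.data$repeat_family)) %>%
      count(.data$dataset, name = "count") %>%
      mutate(category = "Repeat")
    by_fam <- annotated %>%
      filter(!is.na(.data$repeat_family)) %>%
      count(.data$dataset, category = .data$repeat_family, name = "count")
    out <- bind_rows(out, reps, by_fam)
  }
  out %>%
    left_join(totals, by = "dataset") %>%
    mutate(percent = 100 * .data$count / .data$total) %>%
    arrange(.data$dataset, .data$category)
}
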