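#' Effective genome length
#'
#' Total chromosome length minus declared assembly-gap intervals; the
#' denominator of the Poisson rate in [derive_threshold()].
#'
#' @param chrom_sizes Tibble `chrom`, `size`.
#' @param gaps Optional gap tibble `chrom`, `start`, `end` (0-based
#'   half-open); overlapping gaps are merged before subtraction.
#' @return Effective length in bp.
#' @export
effective_genome_length <- function(chrom_sizes, gaps = NULL) {
  total <- sum(chrom_sizes$size)
  if (is.null(gaps) || nrow(as_tibble(gaps)) == 0) return(total)
  gaps <- as_tibble(gaps)
  merged <- GenomicRanges::reduce(as_gr(gaps))
  total - sum(IRanges::width(merged))
}

# default study datasets: the dataset sizes match the published study
# (gamma-retroviral 13,097; alpharetroviral 8,250; lentiviral 31,827;
# random control 40,000); mixture weights give the qualitative tropisms —
# TSS-biased for MLV-like, gene-body-biased for HIV-like, near-uniform for
# ASLV-like, uniform for the control.
default_study_configs <- function(seed = 1) {
  list(
    `SIN-MLV` = site_config(13097, c(0.25, 0.35, 0.40), seed = seed + 1, dataset = "SIN-MLV"),
    `SIN-ASLV` = site_config(8250, c(0.05, 0.15, 0.80), seed = seed + 2, dataset = "SIN-ASLV"),
    `SIN-HIV` = site_config(31827, c(0.03, 0.72, 0.25), seed = seed + 3, dataset = "SIN-HIV"),
    Random = site_config(40000, c(0, 0, 1), seed = seed + 4, dataset = "Random")
  )
}

#' Simulate a complete synthetic study
#'
#' Generates a synthetic genome and a set of integration-site datasets
#' (TSS-biased, gene-body-biased, near-uniform, and a uniform random
#' control by default) and writes every file the analysis consumes:
#' `chrom.sizes`, a refFlat-style gene table, BED4 feature/repeat/mark
#' tracks, and one BED6 site file per dataset. Deterministic for a fixed
#' seed.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_chroms,chrom_len,n_genes Genome dimensions, passed to
#'   [make_genome()].
#' @param site_configs Named list of [site_config()]s; defaults to the
#'   four study-like datasets.
#'
#' @return Invisibly, a list with the `genome` and the named list of site
#'   tibbles.
#' @export
simulate_study <- function(outdir, seed = 1, n_chroms = 2, chrom_len = 1e7,
                           n_genes = 200, site_configs = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(n_chroms, chrom_len, n_genes, seed = seed)
  if (is.null(site_configs)) site_configs <- default_study_configs(seed)

  write_chrom_sizes(genome$chrom_sizes, file.path(outdir, "chrom.sizes"))
  write_refflat(genome$genes, file.path(outdir, "genes.refflat.tsv"))
  write_bed_track(genome$features, file.path(outdir, "features.bed"), "class")
  write_bed_track(genome$repeats, file.path(outdir, "repeats.bed"), "family")
  write_bed_track(genome$marks, file.path(outdir, "marks.bed"), "mark")

  sites <- purrr::map(site_configs, function(cfg) {
    s <- generate_sites(genome, cfg)
    write_bed_sites(s, file.path(outdir, paste0("sites_", cfg$dataset, ".bed")))
    s
  })
  invisible(list(genome = genome, sites = sites))
}

#' Run the full integration-site analysis
#'
#' Ties the stages together on a set of site datasets: per-site annotation
#' and per-dataset summary (region classes and feature hits), repeat-family
#' summary, coarse and fine TSS-distance profiles, ChIP-fragment density
#' profiles per histone mark, chromatin-state summary, per-dataset cluster
#' calling with the numerosity-adjusted threshold, and pairwise Fisher
#' comparisons of every category against every other dataset. Stages whose
#' inputs are absent are skipped with a warning; every produced table is
#' written as TSV under `outdir` together with a manifest recording the
#' parameters.
#'
#' @param sites Either a single site tibble with a `dataset` column or a
#'   named list of site tibbles.
#' @param genes Gene-model tibble.
#' @param chrom_sizes Tibble `chrom`, `size`.
#' @param features Optional feature tibble (`class`, ...).
#' @param repeats Optional repeat tibble (`family`, ...).
#' @param mark_fragments Optional fragment tibble (`mark`, ...) used for
#'   both chromatin-state assignment and density profiles.
#' @param gaps Optional assembly-gap tibble.
#' @param loci Optional named loci tibble for the per-locus report.
#' @param outdir Optional output directory; when `NULL` nothing is written
#'   and the tables are only returned.
#' @param k,alpha Cluster definition parameters.
#' @param ann_config An [annotation_config()].
#' @param prof_config A [profile_config()].
#' @param state_rules A chromatin-state rule table.
#'
#' @return A named list of result tables: `annotated`, `annotation_summary`,
#'   `tss_profile_coarse`, `tss_profile_fine`, `chip_profiles`,
#'   `state_summary`, `cluster_definitions`, `clusters`, `cluster_summary`,
#'   `comparisons`, `locus_report` (entries `NULL` when skipped).
#' @export
run_integration_analysis <- function(sites, genes, chrom_sizes,
                                     features = NULL, repeats = NULL,
                                     mark_fragments = NULL, gaps = NULL,
                                     loci = NULL, outdir = NULL,
                                     k = 3, alpha = 0.01,
                                     ann_config = annotation_config(),
                                     prof_config = profile_config(),
                                     state_rules = chromatin_state_rules()) {
  if (is.data.frame(sites)) {
    all_sites <- as_tibble(sites)
    if (!"dataset" %in% names(all_sites)) all_sites$dataset <- "sites"
  } else {
    all_sites <- bind_rows(sites)
  }
  res <- list()

  ann <- annotate_sites(all_sites, genes, features = features,
    repeats = repeats, config = ann_config)
  res$annotated <- ann
  res$annotation_summary <- summarize_annotation(ann)

  res$tss_profile_coarse <- tss_profile(ann, "coarse", prof_config)
  res$tss_profile_fine <- tss_profile(ann, "fine", prof_config)

  if (!is.null(mark_fragments) && nrow(as_tibble(mark_fragments)) > 0) {
    mark_fragments <- as_tibble(mark_fragments)
    res$chip_profiles <- purrr::map(
      split(all_sites, all_sites$dataset),
      function(ds) {
        purrr::imap(
          split(mark_fragments, mark_fragments$mark),
          ~ chip_density(ds, .x, prof_config)
        )
      }
    )
    st <- assign_chromatin_state(all_sites, mark_fragments,
      rules = state_rules, config = ann_config)
    res$state_summary <- state_summary(st)
  } else {
    warn("no mark fragments supplied; ChIP-density and chromatin-state stages skipped")
    res$chip_profiles <- NULL
    res$state_summary <- NULL
  }

  L <- effective_genome_length(chrom_sizes, gaps)
  per_ds <- split(all_sites, all_sites$dataset)
  res$cluster_definitions <- purrr::imap(per_ds, function(ds, nm) {
    derive_threshold(n = nrow(ds), L = L, k = k, alpha = alpha)
  })
  res$clusters <- purrr::imap(per_ds, function(ds, nm) {
    call_clusters(ds, res$cluster_definitions[[nm]])
  }) %>% bind_rows()
  res$cluster_summary <- purrr::imap(per_ds, function(ds, nm) {
    cluster_summary(res$clusters %>% filter(.data$dataset == nm), nrow(ds)) %>%
      mutate(dataset = nm, w = res$cluster_definitions[[nm]]$w, .before = 1)
  }) %>% bind_rows()

  res$comparisons <- if (length(per_ds) >= 2) {
    compare_categories(res$annotation_summary, alpha = alpha)
  } else {
    NULL
  }

  res$locus_report <- if (!is.null(loci)) {
    locus_report(all_sites, loci, res$clusters)
  } else {
    NULL
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (!is.null(df)) {
        readr::write_tsv(as_tibble(df), file.path(outdir, paste0(name, ".tsv")),
          progress = FALSE)
      }
    }
    wr(res$annotation_summary, "annotation_summary")
    wr(res$tss_profile_coarse, "tss_profile_coarse")
    wr(res$tss_profile_fine, "tss_profile_fine")
    wr(res$state_summary, "state_summary")
    wr(res$clusters, "clusters")
    wr(res$cluster_summary, "cluster_summary")
    wr(res$comparisons, "comparisons")
    wr(res$locus_report, "locus_report")
    if (!is.null(res$chip_profiles)) {
      prof_tbl <- purrr::imap(res$chip_profiles, function(marks, ds) {
        purrr::imap(marks, ~ as_tibble(.x) %>% mutate(dataset = ds, mark = .y)) %>%
          bind_rows()
      }) %>% bind_rows()
      wr(prof_tbl, "chip_profiles")
    }
    manifest <- c(
      sprintf("retrosite %s", as.character(utils::packageVersion("retrosite"))),
      sprintf("datasets: %s", paste(names(per_ds), collapse = ", ")),
      sprintf("n_sites: %s", paste(vapply(per_ds, nrow, 1L), collapse = ", ")),
      sprintf("effective_genome_length: %.0f", L),
      sprintf("cluster_k: %d  cluster_alpha: %g", k, alpha),
      sprintf("tss_window: %d  feature_window: %d  target_gene_window: %d",
        ann_config$tss_window, ann_config$feature_window,
        ann_config$target_gene_window)
    )
    writeLines(manifest, file.path(outdir, "manifest.txt"))
  }
  res
}
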