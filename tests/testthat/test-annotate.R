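test_that("region classification follows the windowed precedence rules", {
  genes <- fix_genes() # GA: + strand, [10000, 20000), tss 10000
  r <- classify_region(fix_sites(c(11500, 15000, 90000)), genes)$region
  expect_equal(as.character(r), c("TSS_PROXIMAL", "INTRAGENIC", "INTERGENIC"))

  # minus-strand gene GB: tss at tx_end - 1 = 59999
  r2 <- classify_region(fix_sites(c(58000, 45000)), genes)$region
  expect_equal(as.character(r2), c("TSS_PROXIMAL", "INTRAGENIC"))

  # the +/- 2.5 kb boundary is inclusive
  r3 <- classify_region(fix_sites(c(12500, 12501)), genes)$region
  expect_equal(as.character(r3), c("TSS_PROXIMAL", "INTRAGENIC"))

  # chromosome absent from the gene table is intergenic, not an error
  r4 <- classify_region(fix_sites(5000, chrom = "chrX"), genes)$region
  expect_equal(as.character(r4), "INTERGENIC")
})

test_that("TSS-proximal precedence wins over another gene's body", {
  genes <- tibble::tibble(
    gene_id = c("A", "B"), chrom = "chr1", strand = "+",
    tx_start = c(1000L, 0L), tx_end = c(9000L, 50000L)
  )
  # site inside B's body but within 2.5 kb of A's TSS
  r <- classify_region(fix_sites(2000), genes)$region
  expect_equal(as.character(r), "TSS_PROXIMAL")
})

test_that("signed TSS distance is strand-aware with nearest-TSS tie-breaking", {
  genes <- fix_genes()
  # minus-strand gene GB, tss 59999: site upstream on minus strand
  d <- tss_distance(fix_sites(58000), genes)
  expect_equal(d$tss_distance, 59999 - 58000) # downstream of TSS: positive
  expect_equal(d$tss_gene, "GB")

  # site exactly at a TSS
  expect_equal(tss_distance(fix_sites(10000), genes)$tss_distance, 0)

  # nearest of two TSSs wins: tss GA 10000, tss GB 59999; pos 13000
  d2 <- tss_distance(fix_sites(13000), genes)
  expect_equal(d2$tss_distance, 3000)
  expect_equal(d2$tss_gene, "GA")

  # beyond the target window the distance is absent
  far <- tibble::tibble(
    gene_id = "F", chrom = "chr3", strand = "+",
    tx_start = 500000L, tx_end = 520000L
  )
  expect_true(is.na(tss_distance(fix_sites(100000, chrom = "chr3"), far)$tss_distance))
})

test_that("equidistant TSSs resolve by lexicographic gene id", {
  genes <- tibble::tibble(
    gene_id = c("ZZ", "AA"), chrom = "chr1", strand = c("+", "+"),
    tx_start = c(1000L, 5000L), tx_end = c(2000L, 6000L)
  )
  d <- tss_distance(fix_sites(3000), genes) # 2000 from both TSSs
  expect_equal(d$tss_gene, "AA")
  expect_equal(d$tss_distance, -2000) # upstream of AA's TSS
})

test_that("feature overlap uses the +/- 1 kb window with >= 1 bp overlap", {
  cpg <- tibble::tibble(class = "CpG", chrom = "chr1", start = 5000, end = 5200)
  got <- annotate_features(fix_sites(6100), cpg)$features_hit[[1]]
  expect_equal(got, "CpG") # window [5100, 7101) overlaps 100 bp

  cpg2 <- tibble::tibble(class = "CpG", chrom = "chr1", start = 5000, end = 5099)
  got2 <- annotate_features(fix_sites(6100), cpg2)$features_hit[[1]]
  expect_equal(got2, character(0)) # window starts at 5100: zero overlap
})

test_that("feature annotation is monotone in the window size", {
  set.seed(21)
  feats <- tibble::tibble(
    class = sample(c("CpG", "CNC", "TFBS"), 200, replace = TRUE),
    chrom = "chr1",
    start = sample.int(2e5, 200),
    end = 0
  )
  feats$end <- feats$start + sample(50:500, 200, replace = TRUE)
  sites <- fix_sites(sample.int(2e5, 100))
  small <- annotate_features(sites, feats, annotation_config(feature_window = 500))
  big <- annotate_features(sites, feats, annotation_config(feature_window = 2000))
  for (i in seq_len(nrow(sites))) {
    expect_true(all(small$features_hit[[i]] %in% big$features_hit[[i]]))
  }
})

test_that("repeat family uses the site base itself with smallest-interval tie-break", {
  reps <- tibble::tibble(
    family = c("SINE", "LINE"),
    chrom = "chr1",
    start = c(100, 50),
    end = c(400, 2000) # nested: LINE contains SINE
  )
  expect_equal(assign_repeat(fix_sites(250), reps)$repeat_family, "SINE")
  expect_equal(assign_repeat(fix_sites(1000), reps)$repeat_family, "LINE")
  # half-open right boundary: pos 400 is outside the SINE
  expect_equal(assign_repeat(fix_sites(400), reps)$repeat_family, "LINE")
  expect_true(is.na(assign_repeat(fix_sites(5000), reps)$repeat_family))
})

test_that("target genes are all TSSs within +/- 50 kb, sorted by distance", {
  mk <- function(id, tss) {
    tibble::tibble(
      gene_id = id, chrom = "chr1", strand = "+",
      tx_start = as.integer(tss), tx_end = as.integer(tss + 1000)
    )
  }
  genes <- dplyr::bind_rows(mk("near", 100000), mk("edge", 149999), mk("out", 150001))
  tg <- target_genes(fix_sites(100000), genes)
  expect_equal(tg$gene_id, c("near", "edge")) # 49,999 in; 50,001 out
  expect_equal(tg$tss_distance, c(0, -49999))
})

test_that("target-gene listing equals a linear scan oracle", {
  set.seed(23)
  genes <- random_genes(60)
  sites <- fix_sites(sample.int(1e6, 50), chrom = sample(c("chr1", "chr2"), 50, replace = TRUE))
  tg <- target_genes(sites, genes)
  deduped <- genes |>
    dplyr::mutate(tss = ifelse(strand == "+", tx_start, tx_end - 1L)) |>
    dplyr::arrange(gene_id) |>
    dplyr::distinct(chrom, strand, tss, tx_start, tx_end, .keep_all = TRUE)
  for (i in seq_len(nrow(sites))) {
    expected <- character(0)
    for (j in seq_len(nrow(deduped))) {
      if (deduped$chrom[j] == sites$chrom[i] &&
        abs(deduped$tss[j] - sites$pos[i]) <= 50000) {
        expected <- c(expected, deduped$gene_id[j])
      }
    }
    expect_setequal(tg$gene_id[tg$site_id == i], expected)
  }
})

test_that("expressed-target fraction joins and counts missing genes", {
  expr <- tibble::tibble(gene_id = sprintf("G%02d", 1:100), value = c(rep(5, 70), rep(0, 30)))
  out <- expressed_target_fraction(sprintf("G%02d", 1:100), expr, threshold = 1)
  expect_equal(out$fraction, 0.70)

  expect_equal(expressed_target_fraction("G01", expr, 1)$fraction, 1.0)
  expect_equal(expressed_target_fraction("G99", expr, 1)$fraction, 0.0)
  miss <- expressed_target_fraction(c("G01", "NOPE"), expr, 1)
  expect_equal(miss$n_missing, 1L)
  expect_equal(miss$fraction, 0.5)
  expect_true(is.na(expressed_target_fraction(character(0), expr, 1)$fraction))
})

test_that("region classes partition every dataset", {
  set.seed(25)
  genes <- random_genes(40)
  sites <- fix_sites(sample.int(1e6, 500))
  summ <- summarize_annotation(annotate_sites(sites, genes))
  reg <- summ[summ$category %in% c("TSS_PROXIMAL", "INTRAGENIC", "INTERGENIC"), ]
  expect_equal(sum(reg$count), nrow(sites))
  expect_equal(sum(reg$percent), 100)
})

test_that("annotation is invariant under a constant genomic translation", {
  set.seed(26)
  genes <- random_genes(30)
  feats <- tibble::tibble(
    class = "CNC", chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
    start = sample.int(9e5, 100), end = 0
  )
  feats$end <- feats$start + 300
  sites <- fix_sites(sample.int(8e5, 200), chrom = sample(c("chr1", "chr2"), 200, replace = TRUE))
  shift <- 12345L
  ann1 <- annotate_sites(sites, genes, features = feats)
  ann2 <- annotate_sites(
    dplyr::mutate(sites, pos = pos + shift),
    dplyr::mutate(genes, tx_start = tx_start + shift, tx_end = tx_end + shift),
    features = dplyr::mutate(feats, start = start + shift, end = end + shift)
  )
  expect_equal(as.character(ann1$region), as.character(ann2$region))
  expect_equal(ann1$tss_distance, ann2$tss_distance)
  expect_equal(ann1$features_hit, ann2$features_hit)
})
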