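test_that("TSS histogram bins by hand-checkable edges", {
  p <- tss_profile(c(-3000, -1000, 1000, 30000))
  tb <- tibble::as_tibble(p)
  occupied <- tb[tb$count > 0, ]
  expect_equal(occupied$bin_start, c(-5000, -2500, 0, 27500))
  expect_equal(occupied$fraction, rep(0.25, 4))

  # all mass in the bin containing zero
  p0 <- tss_profile(rep(0, 10))
  tb0 <- tibble::as_tibble(p0)
  expect_equal(sum(tb0$count > 0), 1)
  expect_equal(tb0$fraction[tb0$count > 0], 1)

  expect_error(tss_profile(numeric(0)), "no usable")
  expect_error(tss_profile(c(NA, NA)), "no usable")
})

test_that("histogram fractions sum to one and mass survives rebinning", {
  set.seed(31)
  d <- rnorm(2000, 0, 15000)
  coarse <- tibble::as_tibble(tss_profile(d))
  expect_equal(sum(coarse$fraction), 1, tolerance = 1e-9)
  finer <- tibble::as_tibble(tss_profile(d, config = profile_config(coarse_bin = 500)))
  expect_equal(sum(finer$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(finer$count), sum(coarse$count))
})

test_that("fine TSS profile of a TSS-biased dataset peaks near zero", {
  g <- make_genome(n_chroms = 1, chrom_len = 2e6, n_genes = 30, seed = 33)
  s <- generate_sites(g, site_config(5000, c(1, 0, 0), tss_spread = 500, seed = 34))
  d <- tss_distance(s, g$genes)$tss_distance
  p <- tibble::as_tibble(tss_profile(d, "fine"))
  mode_mid <- p$bin_mid[which.max(p$fraction)]
  expect_lte(abs(mode_mid), 500)
})

test_that("ChIP density recovers uniform tiling and single-fragment coverage", {
  # tiling at depth 1: every base covered once
  tiles <- tibble::tibble(
    chrom = "chr1",
    start = seq(0, 2e4, by = 500), end = seq(0, 2e4, by = 500) + 500
  )
  prof <- chip_density(fix_sites(10000), tiles)
  expect_true(all(abs(prof$density - 1) < 1e-12))

  # single 100-bp fragment centred on the site: only the two central bins
  one <- chip_density(
    fix_sites(10000),
    tibble::tibble(chrom = "chr1", start = 9950, end = 10050)
  )
  expect_equal(one$density[one$offset_start %in% c(-50, 0)], c(1, 1))
  expect_equal(sum(one$density > 0), 2)

  # empty fragment track: all-zero profile is valid
  empty <- chip_density(fix_sites(10000), tibble::tibble(
    chrom = character(0), start = numeric(0), end = numeric(0)
  ))
  expect_true(all(empty$density == 0))
})

test_that("ChIP density is additive over disjoint fragment tracks", {
  set.seed(35)
  mk <- function(n) {
    st <- sample(seq(0, 49000, by = 120), n)
    tibble::tibble(chrom = "chr1", start = st, end = st + 100)
  }
  a <- mk(120)
  b <- mk(130) |> dplyr::mutate(start = start + 25000, end = end + 25000)
  sites <- fix_sites(sample(5000:70000, 40))
  pa <- chip_density(sites, a)$density
  pb <- chip_density(sites, b)$density
  pab <- chip_density(sites, dplyr::bind_rows(a, b))$density
  expect_equal(pab, pa + pb, tolerance = 1e-12)
})

test_that("chromatin states follow the unambiguous rule-match semantics", {
  mark_track <- function(marks, pos = 5000) {
    tibble::tibble(mark = marks, chrom = "chr1", start = pos - 500, end = pos + 500)
  }
  st <- function(marks) {
    assign_chromatin_state(fix_sites(5000), mark_track(marks))$chrom_state
  }
  expect_equal(st("H3K4me3"), "Promoter")
  expect_equal(st("H3K4me1"), "Enhancer")
  expect_equal(st("H3K36me3"), "Transcribed")
  expect_equal(st("H3K27me3"), "Heterochromatin")
  # promoter + transcribed marks: Transcribed is blocked by its forbidden set
  expect_equal(st(c("H3K4me3", "H3K36me3")), "Promoter")
  # no marks: no rule matches
  expect_true(is.na(assign_chromatin_state(
    fix_sites(5000),
    tibble::tibble(mark = character(0), chrom = character(0), start = numeric(0), end = numeric(0))
  )$chrom_state))
})

test_that("every mark combination is either unassigned or a unique rule match", {
  rules <- chromatin_state_rules()
  all_marks <- c("H3K4me1", "H3K4me3", "H3K36me3", "H3K27me3")
  for (bits in 0:15) {
    present <- all_marks[bitwAnd(bits, 2^(0:3)) > 0]
    track <- tibble::tibble(
      mark = present, chrom = "chr1",
      start = rep(4500, length(present)), end = rep(5500, length(present))
    )
    got <- assign_chromatin_state(fix_sites(5000), track, rules)$chrom_state
    # independent rule evaluation
    matches <- character(0)
    for (i in seq_len(nrow(rules))) {
      if (all(rules$required[[i]] %in% present) &&
        !any(rules$forbidden[[i]] %in% present)) {
        matches <- c(matches, rules$state[i])
      }
    }
    if (length(matches) == 1) {
      expect_equal(got, matches)
      # a state's forbidden marks are never present when it is returned
      i <- which(rules$state == got)
      expect_false(any(rules$forbidden[[i]] %in% present))
    } else {
      expect_true(is.na(got))
    }
  }
})

test_that("rule-table validation catches duplicates and contradictions", {
  dup <- chromatin_state_rules()
  dup$state[2] <- "Promoter"
  expect_error(assign_chromatin_state(fix_sites(1), tibble::tibble(
    mark = "H3K4me3", chrom = "chr1", start = 0, end = 10
  ), dup), "duplicate")
  bad <- chromatin_state_rules()
  bad$forbidden[[1]] <- "H3K4me3"
  expect_error(assign_chromatin_state(fix_sites(1), tibble::tibble(
    mark = "H3K4me3", chrom = "chr1", start = 0, end = 10
  ), bad), "required and forbidden")
})

test_that("state summary fractions sum to one and cover the unassigned", {
  g <- make_genome(n_chroms = 1, chrom_len = 2e6, n_genes = 30, seed = 37)
  s <- generate_sites(g, site_config(2000, c(0, 0, 1), seed = 38))
  st <- assign_chromatin_state(s, g$marks)
  summ <- state_summary(st)
  expect_equal(sum(summ$fraction), 1, tolerance = 1e-9)

  # no mark tracks: everything unassigned
  st0 <- assign_chromatin_state(s, g$marks[0, ])
  summ0 <- state_summary(st0)
  expect_equal(summ0$state, "unassigned")
  expect_equal(summ0$fraction, 1)
})

test_that("TSS-biased sites are more promoter/enhancer-associated than uniform", {
  g <- make_genome(n_chroms = 2, chrom_len = 2e6, n_genes = 60, seed = 39)
  tssy <- generate_sites(g, site_config(3000, c(1, 0, 0), seed = 40, dataset = "tssy"))
  unif <- generate_sites(g, site_config(3000, c(0, 0, 1), seed = 41, dataset = "unif"))
  both <- dplyr::bind_rows(tssy, unif)
  summ <- state_summary(assign_chromatin_state(both, g$marks))
  frac <- function(ds) {
    sum(summ$fraction[summ$dataset == ds & summ$state %in% c("Promoter", "Enhancer")])
  }
  expect_gt(frac("tssy"), frac("unif"))
})
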