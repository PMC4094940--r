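test_that("short-read filtering keeps reads whose best hit is long enough", {
  hits <- dplyr::bind_rows(
    hit("r1", aligned_length = 15L),
    hit("r2", aligned_length = 80L)
  )
  kept <- filter_reads(hits, junction_config(min_genomic_length = 20))
  expect_equal(unique(kept$read_id), "r2")

  # length exactly at the threshold survives
  kept2 <- filter_reads(hit("r3", aligned_length = 20L), junction_config())
  expect_equal(unique(kept2$read_id), "r3")
})

test_that("filtering matches a direct scan of best-hit lengths", {
  set.seed(4)
  lens <- sample(10:60, 100, replace = TRUE)
  hits <- dplyr::bind_rows(lapply(seq_along(lens), function(i) {
    hit(sprintf("r%03d", i), start = i * 100L, end = i * 100L + lens[i])
  }))
  kept <- filter_reads(hits, junction_config(min_genomic_length = 20))
  expect_setequal(unique(kept$read_id), sprintf("r%03d", which(lens >= 20)))
})

test_that("malformed hit coordinates are dropped with a warning, not an error", {
  hits <- dplyr::bind_rows(
    hit("ok"),
    hit("bad", start = 500L, end = 400L)
  )
  expect_warning(kept <- filter_reads(hits), "malformed")
  expect_equal(kept$read_id, "ok")
})

test_that("ambiguity classification follows the identity-delta rule", {
  two <- function(id1, id2) {
    dplyr::bind_rows(
      hit("r", start = 1000L, identity = id1),
      hit("r", chrom = "chr2", start = 5000L, identity = id2)
    )
  }
  expect_equal(classify_ambiguity(two(98, 97))$status, "ambiguous") # delta 1 < 2
  expect_equal(classify_ambiguity(two(99, 95))$status, "unique") # delta 4 >= 2
  expect_equal(classify_ambiguity(hit("r", identity = 100))$status, "unique")
  # reads absent from the hit table are unmapped
  cl <- classify_ambiguity(hit("r1"), reads = tibble::tibble(read_id = c("r1", "r9")))
  expect_equal(cl$status[cl$read_id == "r9"], "unmapped")
})

test_that("ambiguity classification is invariant under hit-list permutation", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    h <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      hit("r", start = i * 1000L, identity = runif(1, 90, 100))
    }))
    ref <- classify_ambiguity(h)$status
    perm <- classify_ambiguity(h[sample.int(n), ])$status
    expect_equal(perm, ref)
  }
})

test_that("redundant unique reads collapse to one site with support counted", {
  hits <- dplyr::bind_rows(
    hit("r1", start = 1000L, end = 1050L),
    hit("r2", start = 1000L, end = 1090L), # different read length, same junction
    hit("r3", start = 1000L, end = 1075L)
  )
  sites <- collapse_to_sites(hits, "ds")
  expect_equal(nrow(sites), 1)
  expect_equal(sites$pos, 1000L)
  expect_equal(sites$support, 3L)

  # strand is part of the redundancy key
  hits2 <- dplyr::bind_rows(
    hit("r1", start = 1000L, end = 1050L, strand = "+"),
    hit("r2", start = 951L, end = 1001L, strand = "-")
  )
  sites2 <- collapse_to_sites(hits2, "ds")
  expect_equal(nrow(sites2), 2)
  # minus-strand junction base is end - 1
  expect_equal(sort(sites2$pos), c(1000L, 1000L))
  expect_setequal(sites2$strand, c("+", "-"))
})

test_that("collapsing equals a group-by oracle on random duplicated reads", {
  set.seed(11)
  pos <- sample(seq(1000L, 5000L, by = 100L), 50, replace = TRUE)
  strand <- sample(c("+", "-"), 50, replace = TRUE)
  hits <- dplyr::bind_rows(lapply(1:50, function(i) {
    if (strand[i] == "+") {
      hit(sprintf("r%02d", i), start = pos[i], end = pos[i] + 60L, strand = "+")
    } else {
      hit(sprintf("r%02d", i), start = pos[i] - 59L, end = pos[i] + 1L, strand = "-")
    }
  }))
  sites <- collapse_to_sites(hits, "ds")
  expected <- table(paste(pos, strand))
  got <- stats::setNames(sites$support, paste(sites$pos, sites$strand))
  expect_equal(got[names(expected)], stats::setNames(as.integer(expected), names(expected)))
  expect_equal(sum(sites$support), 50L)
})

test_that("collapsing is idempotent on its own output", {
  set.seed(12)
  pos <- sample(seq(1000L, 3000L, by = 50L), 40, replace = TRUE)
  hits <- dplyr::bind_rows(lapply(seq_along(pos), function(i) {
    hit(sprintf("r%02d", i), start = pos[i], end = pos[i] + 60L)
  }))
  once <- collapse_to_sites(hits, "ds")
  again <- collapse_to_sites(
    sites_as_hits(once[rep(seq_len(nrow(once)), once$support), ]), "ds"
  )
  expect_equal(
    again[c("chrom", "pos", "strand", "support")],
    once[c("chrom", "pos", "strand", "support")]
  )
})

test_that("ambiguous reads emit one flagged site per placement in a match group", {
  hits <- dplyr::bind_rows(
    hit("amb", start = 1000L, identity = 98),
    hit("amb", chrom = "chr2", start = 2000L, identity = 97.5)
  )
  sites <- collapse_to_sites(hits, "ds")
  expect_equal(nrow(sites), 2)
  expect_true(all(sites$ambiguous))
  expect_equal(unique(sites$match_group), "amb")
})

test_that("repeat set rescues ambiguous groups confined to one repeat family", {
  repeats <- tibble::tibble(
    family = c("SINE", "SINE", "SINE", "LINE"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(900, 4900, 1900, 7900),
    end = c(1200, 5200, 2200, 8200)
  )
  sites <- dplyr::bind_rows(
    fix_sites(30000),
    tibble::tibble(
      chrom = c("chr1", "chr1", "chr2"), pos = c(1000L, 5000L, 2000L),
      strand = "+", dataset = "test", support = 1L, ambiguous = TRUE,
      match_group = "g1"
    ),
    tibble::tibble(
      chrom = c("chr1", "chr2"), pos = c(1000L, 8000L),
      strand = "+", dataset = "test", support = 1L, ambiguous = TRUE,
      match_group = "g2" # SINE + LINE: dropped
    )
  )
  rs <- build_repeat_set(sites, repeats)
  expect_equal(nrow(rs), 2) # 1 non-ambiguous + 1 rescued group
  rescued <- rs[rs$ambiguous, ]
  expect_equal(rescued$repeat_family, "SINE")
  expect_equal(rescued$match_group, "g1")
  # repeat set is never smaller than the non-ambiguous set
  expect_gte(nrow(rs), sum(!sites$ambiguous))

  # no ambiguous groups: output is the input
  plain <- fix_sites(c(100, 30000))
  expect_equal(nrow(build_repeat_set(plain, repeats)), 2)
})
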