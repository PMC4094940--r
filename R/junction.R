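#' Filter junction-read alignment hits
#'
#' Removes reads whose genomic portion is too short to map reliably. A read
#' survives when its best alignment (highest percent identity, ties broken by
#' aligned length) spans at least `min_genomic_length` bp of genome. Reads
#' with no alignments at all are unmapped and simply absent from the hit
#' table. Malformed hit rows (non-positive span, negative start, missing
#' coordinates) are dropped with a warning rather than stopping the run.
#'
#' @param hits A tibble of alignment hits with columns `read_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `identity` (percent),
#'   `aligned_length` (bp).
#' @param config A [junction_config()].
#'
#' @return The hit tibble restricted to retained reads, input order preserved.
#' @export
filter_reads <- function(hits, config = junction_config()) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(hits)
  bad <- is.na(hits$start) | is.na(hits$end) | hits$start < 0 | hits$end <= hits$start
  if (any(bad)) {
    warn(sprintf("dropping %d malformed alignment hit(s)", sum(bad)))
    hits <- hits[!bad, , drop = FALSE]
  }
  best <- hits %>%
    group_by(.data$read_id) %>%
    arrange(dplyr::desc(.data$identity), dplyr::desc(.data$aligned_length), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  keep <- best$read_id[best$aligned_length >= config$min_genomic_length]
  hits %>% filter(.data$read_id %in% keep)
}

#' Classify reads as uniquely or ambiguously mapped
#'
#' A read maps uniquely when it has a single alignment, or when its best
#' alignment's percent identity exceeds the runner-up's by at least
#' `ambiguity_identity_delta` percentage points. When two or more alignments
#' lie within that delta of the best, the read is ambiguous: its true
#' placement cannot be resolved. The result does not depend on the order of
#' the hit rows.
#'
#' @inheritParams filter_reads
#' @param reads Optional tibble with a `read_id` column (e.g. parsed FASTA
#'   headers); reads present here but absent from `hits` are reported as
#'   `"unmapped"`.
#'
#' @return A tibble with columns `read_id`, `status` (`"unique"`,
#'   `"ambiguous"` or `"unmapped"`) and `n_hits`.
#' @export
classify_ambiguity <- function(hits, config = junction_config(), reads = NULL) {
  hits <- as_tibble(hits)
  out <- hits %>%
    group_by(.data$read_id) %>%
    summarise(
      n_hits = n(),
      best = max(.data$identity),
      runner_up = if (n() > 1) sort(.data$identity, decreasing = TRUE)[2] else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(
      status = if_else(
        .data$n_hits == 1 |
          (.data$best - .data$runner_up) >= config$ambiguity_identity_delta,
        "unique", "ambiguous",
        missing = "unique"
      )
    ) %>%
    select("read_id", "status", "n_hits")
  if (!is.null(reads)) {
    unmapped <- setdiff(unique(reads$read_id), out$read_id)
    if (length(unmapped) > 0) {
      out <- bind_rows(out, tibble(read_id = unmapped, status = "unmapped", n_hits = 0L))
    }
  }
  out
}

# strand-aware junction base of a hit: the first genomic base after the
# 3'-LTR junction. + strand reads extend rightward from the junction, so the
# site is the hit start; - strand reads extend leftward, so it is end - 1.
junction_pos <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

#' Collapse filtered junction reads into unique integration sites
#'
#' Uniquely mapped reads sharing the same junction coordinate
#' (chrom, pos, strand) are sheared-DNA duplicates of one integration event
#' and collapse into a single site whose `support` counts the collapsed
#' reads; read length plays no part in the key. Ambiguous reads emit one
#' site per candidate placement (every alignment within the identity delta
#' of the best), flagged `ambiguous` and tied together by `match_group` so a
#' later step can decide their fate.
#'
#' @inheritParams filter_reads
#' @param dataset Label to attach to every emitted site.
#'
#' @return A site tibble: `chrom`, `pos` (0-based junction base), `strand`,
#'   `dataset`, `support`, `ambiguous`, `match_group`.
#' @export
collapse_to_sites <- function(hits, dataset, config = junction_config()) {
  hits <- as_tibble(hits)
  empty <- tibble(
    chrom = character(0), pos = integer(0), strand = character(0),
    dataset = character(0), support = integer(0), ambiguous = logical(0),
    match_group = character(0)
  )
  if (nrow(hits) == 0) return(empty)

  status <- classify_ambiguity(hits, config)
  hits <- left_join(hits, status, by = "read_id")

  uniq <- hits %>%
    filter(.data$status == "unique") %>%
    group_by(.data$read_id) %>%
    arrange(dplyr::desc(.data$identity), dplyr::desc(.data$aligned_length), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    mutate(pos = junction_pos(.data$start, .data$end, .data$strand)) %>%
    count(.data$chrom, .data$pos, .data$strand, name = "support") %>%
    mutate(
      dataset = dataset, ambiguous = FALSE, match_group = NA_character_,
      pos = as.integer(.data$pos)
    )

  ambig <- hits %>% filter(.data$status == "ambiguous")
  ambig <- if (nrow(ambig) == 0) empty else ambig %>%
    group_by(.data$read_id) %>%
    filter(.data$identity >= max(.data$identity) - config$ambiguity_identity_delta) %>%
    ungroup() %>%
    mutate(
      pos = as.integer(junction_pos(.data$start, .data$end, .data$strand)),
      dataset = dataset, support = 1L, ambiguous = TRUE,
      match_group = .data$read_id
    ) %>%
    select("chrom", "pos", "strand", "dataset", "support", "ambiguous", "match_group")

  bind_rows(uniq, ambig) %>%
    select("chrom", "pos", "strand", "dataset", "support", "ambiguous", "match_group") %>%
    arrange(.data$chrom, .data$pos, .data$strand)
}

#' Build the repeat-analysis site set
#'
#' The repeat analysis can rescue ambiguous reads: when every candidate
#' placement of an ambiguous read falls inside repeat intervals of the same
#' family, the read is univocally attributable to that repeat family even
#' though its exact coordinate is not known, and contributes one site. Groups
#' whose placements hit different families (or fall outside repeats) are
#' dropped. Non-ambiguous sites always pass through, so the repeat set is at
#' least as large as the unique set.
#'
#' @param sites A site tibble from [collapse_to_sites()].
#' @param repeats Repeat track tibble: `chrom`, `start`, `end` (0-based
#'   half-open), `family` (e.g. LINE, SINE, Satellite, LTR, Other).
#'
#' @return The site tibble with a `repeat_family` column (family containing
#'   the site base, `NA` outside repeats); ambiguous groups collapsed to one
#'   representative row or dropped as described.
#' @export
build_repeat_set <- function(sites, repeats) {
  sites <- assert_sites(as_tibble(sites))
  fam <- assign_repeat(sites, repeats)$repeat_family
  sites$repeat_family <- fam

  non_amb <- sites %>% filter(!.data$ambiguous)
  amb <- sites %>% filter(.data$ambiguous)
  if (nrow(amb) > 0) {
    keep <- amb %>%
      group_by(.data$match_group) %>%
      filter(!any(is.na(.data$repeat_family)) && dplyr::n_distinct(.data$repeat_family) == 1) %>%
      arrange(.data$chrom, .data$pos, .data$strand, .by_group = TRUE) %>%
      slice(1) %>%
      ungroup()
  } else {
    keep <- amb
  }
  bind_rows(non_amb, keep) %>% arrange(.data$chrom, .data$pos, .data$strand)
}
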