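#' TSS-distance histogram
#'
#' Bins signed site-to-TSS distances into a symmetric histogram around the
#' TSS, either coarse (2.5-kb bins over +/- 50 kb by default) or fine (50-bp
#' bins over +/- 2.5 kb). Bins are right-closed (`(start, end]`; a distance
#' on a bin edge counts in the lower bin), with the single value equal to
#' `-span` counted in the first bin. Distances outside the span (and `NA`s)
#' are dropped and reported via the `n_dropped` attribute; fractions are
#' normalised over the sites actually used.
#'
#' @param x A numeric vector of signed distances, or a tibble with a
#'   `tss_distance` column (and optionally `dataset`, in which case profiles
#'   are computed per dataset).
#' @param resolution `"coarse"` or `"fine"`.
#' @param config A [profile_config()].
#'
#' @return A tibble of class `tss_profile` with columns `dataset`,
#'   `bin_start`, `bin_end`, `bin_mid`, `count`, `fraction`; attributes
#'   `n_used`, `n_dropped`, `resolution`, `bin_width`.
#' @export
tss_profile <- function(x, resolution = c("coarse", "fine"), config = profile_config()) {
  resolution <- match.arg(resolution)
  span <- if (resolution == "coarse") config$span else config$fine_span
  bin <- if (resolution == "coarse") config$coarse_bin else config$fine_bin

  if (is.data.frame(x)) {
    df <- as_tibble(x)
    if (!"dataset" %in% names(df)) df$dataset <- "sites"
    d <- df$tss_distance
    ds <- df$dataset
  } else {
    d <- as.numeric(x)
    ds <- rep("sites", length(d))
  }
  ok <- !is.na(d)
  d <- d[ok]; ds <- ds[ok]
  if (length(d) == 0) abort("no usable TSS distances to profile")
  inside <- d >= -span & d <= span
  n_dropped <- sum(!inside)
  d <- d[inside]; ds <- ds[inside]
  if (length(d) == 0) abort("all TSS distances fall outside the profile span")

  edges <- seq(-span, span, by = bin)
  bin_idx <- pmax(ceiling((d + span) / bin), 1L)
  out <- tibble(dataset = ds, idx = bin_idx) %>%
    count(.data$dataset, .data$idx, name = "count") %>%
    tidyr::complete(
      dataset = unique(ds), idx = seq_len(length(edges) - 1L),
      fill = list(count = 0L)
    ) %>%
    group_by(.data$dataset) %>%
    mutate(fraction = .data$count / sum(.data$count)) %>%
    ungroup() %>%
    mutate(
      bin_start = edges[.data$idx],
      bin_end = edges[.data$idx + 1L],
      bin_mid = (.data$bin_start + .data$bin_end) / 2
    ) %>%
    select("dataset", "bin_start", "bin_end", "bin_mid", "count", "fraction")
  structure(out,
    class = c("tss_profile", class(out)),
    n_used = length(d), n_dropped = n_dropped,
    resolution = resolution, bin_width = bin
  )
}

#' Mean ChIP-fragment density around integration sites
#'
#' Computes per-base fragment coverage in a window centred on each site
#' (5 kb total by default), averages it across sites, and reports the mean
#' coverage per bin. Profiles are not flipped by site strand: the window is
#' laid out in genomic orientation (configurable upstream by pre-flipping
#' coordinates if desired).
#'
#' @param sites Site tibble (`chrom`, `pos`).
#' @param fragments Fragment/peak tibble: `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param config A [profile_config()].
#'
#' @return A tibble of class `chip_profile`: `offset_start`, `offset_mid`
#'   (bp relative to the site base), `density` (mean per-base fragment
#'   coverage in the bin, averaged over sites).
#' @export
chip_density <- function(sites, fragments, config = profile_config()) {
  sites <- assert_sites(as_tibble(sites))
  if (nrow(sites) == 0) abort("`sites` is empty")
  fragments <- as_tibble(fragments)
  half <- config$chip_window / 2
  nbin <- config$chip_window / config$chip_bin
  win_start <- sites$pos - half # 0-based window start, half-open [start, start+cw)

  cov_total <- numeric(config$chip_window)
  if (nrow(fragments) > 0) {
    win <- GenomicRanges::GRanges(
      seqnames = sites$chrom,
      ranges = IRanges::IRanges(start = win_start + 1, width = config$chip_window)
    )
    pairs <- overlap_pairs(win, as_gr(fragments))
    if (nrow(pairs) > 0) {
      rs <- pmax(fragments$start[pairs$subject], win_start[pairs$query]) -
        win_start[pairs$query]
      re <- pmin(fragments$end[pairs$subject], win_start[pairs$query] + config$chip_window) -
        win_start[pairs$query]
      covr <- IRanges::coverage(
        IRanges::IRanges(start = rs + 1, end = re),
        width = config$chip_window
      )
      cov_total <- as.numeric(covr)
    }
  }
  per_bin <- colSums(matrix(cov_total, nrow = config$chip_bin)) /
    (config$chip_bin * nrow(sites))
  offs <- seq(-half, half - config$chip_bin, by = config$chip_bin)
  out <- tibble(
    offset_start = offs,
    offset_mid = offs + config$chip_bin / 2,
    density = per_bin
  )
  structure(out,
    class = c("chip_profile", class(out)),
    n_sites = nrow(sites), bin_width = config$chip_bin
  )
}

#' Assign an epigenetically defined chromatin state to each site
#'
#' Mark presence at a site means the mark's track overlaps the
#' +/- `feature_window` bp window around the site base (the same rule as
#' feature annotation). All rules in the table are then evaluated on the
#' presence set; a site receives a state only when exactly one rule matches
#' — the unambiguous-association requirement. Zero or multiple matches
#' leave the site unassigned (`NA`).
#'
#' @param sites Site tibble.
#' @param marks Mark-track tibble: `mark`, `chrom`, `start`, `end`.
#' @param rules A rule table as produced by [chromatin_state_rules()]:
#'   columns `state`, `required` (list), `forbidden` (list). Duplicate
#'   state labels are a configuration error.
#' @param config An [annotation_config()] (supplies `feature_window`).
#'
#' @return `sites` with an added `chrom_state` column.
#' @export
assign_chromatin_state <- function(sites, marks, rules = chromatin_state_rules(),
                                   config = annotation_config()) {
  sites <- assert_sites(as_tibble(sites))
  rules <- as_tibble(rules)
  if (anyDuplicated(rules$state)) abort("duplicate state labels in rule table")
  bad <- purrr::map2_lgl(rules$required, rules$forbidden, ~ length(intersect(.x, .y)) > 0)
  if (any(bad)) abort("a rule lists the same mark as required and forbidden")

  marks <- as_tibble(marks)
  all_marks <- unique(c(unlist(rules$required), unlist(rules$forbidden)))
  present <- matrix(FALSE, nrow = nrow(sites), ncol = length(all_marks),
    dimnames = list(NULL, all_marks)
  )
  if (nrow(marks) > 0 && nrow(sites) > 0) {
    mk <- marks %>% filter(.data$mark %in% all_marks)
    if (nrow(mk) > 0) {
      win <- sites_gr(sites, flank = config$feature_window)
      pairs <- overlap_pairs(win, as_gr(mk), min_overlap = config$min_overlap)
      if (nrow(pairs) > 0) {
        present[cbind(pairs$query, match(mk$mark[pairs$subject], all_marks))] <- TRUE
      }
    }
  }
  n_match <- integer(nrow(sites))
  state <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(rules))) {
    req <- rules$required[[i]]
    forb <- rules$forbidden[[i]]
    m <- rep(TRUE, nrow(sites))
    for (mk_ in req) m <- m & present[, mk_]
    for (mk_ in forb) m <- m & !present[, mk_]
    state[m & n_match == 0] <- rules$state[i]
    n_match <- n_match + m
  }
  state[n_match != 1] <- NA_character_
  sites$chrom_state <- state
  sites
}

#' Chromatin-state composition per dataset
#'
#' Fraction of sites in each chromatin state plus the unassigned fraction;
#' fractions sum to 1 within each dataset.
#'
#' @param sites Output of [assign_chromatin_state()] (with `chrom_state`),
#'   optionally carrying a `dataset` column.
#'
#' @return Tibble: `dataset`, `state` (including `"unassigned"`), `count`,
#'   `fraction`.
#' @export
state_summary <- function(sites) {
  sites <- as_tibble(sites)
  if (!"dataset" %in% names(sites)) sites$dataset <- "sites"
  sites %>%
    mutate(state = if_else(is.na(.data$chrom_state), "unassigned", .data$chrom_state)) %>%
    count(.data$dataset, .data$state, name = "count") %>%
    group_by(.data$dataset) %>%
    mutate(fraction = .data$count / sum(.data$count)) %>%
    ungroup()
}
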