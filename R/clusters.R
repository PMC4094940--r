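#' Numerosity-adjusted cluster window
#'
#' Derives the window `w` defining an integration cluster (hot spot) of
#' order `k`, adjusted to the size of the dataset: integration sites are
#' modelled as a homogeneous Poisson process with rate `n / L` (`n` sites
#' over an effective genome of `L` bp), and `w` is the largest window such
#' that the probability that a given site has at least `k - 1` further
#' sites within `w` downstream is at most `alpha`. Larger datasets
#' therefore get a tighter window. The equation
#' `P(Poisson(n w / L) >= k - 1) = alpha` is solved by monotone
#' root-finding to 1 bp.
#'
#' @param n Number of integration sites in the dataset.
#' @param L Effective genome length in bp (total chromosome length minus
#'   assembly gaps).
#' @param k Minimum number of sites forming a cluster (default 3).
#' @param alpha Significance level of the cluster definition (default 0.01).
#'
#' @return An object of class `cluster_definition`: a list with `k`, `w`
#'   (bp), `alpha`, `n`, `L`, and `lambda` (= n w / L at the root).
#' @export
#'
#' @examples
#' derive_threshold(n = 1000, L = 1e8)
derive_threshold <- function(n, L, k = 3, alpha = 0.01) {
  if (k < 2) abort("`k` must be >= 2")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (L <= 0) abort("`L` must be positive")
  if (n < k) abort("cluster order exceeds dataset size")
  # P(X >= k - 1), X ~ Poisson(lambda), increases monotonically in lambda
  tail_p <- function(lambda) ppois(k - 2, lambda, lower.tail = FALSE)
  upper <- 1
  while (tail_p(upper) < alpha && upper < 1e12) upper <- upper * 10
  lambda <- uniroot(function(l) tail_p(l) - alpha, c(0, upper),
    tol = .Machine$double.eps^0.5
  )$root
  w <- floor(lambda * L / n)
  if (w < 1) {
    warn("derived window is below 1 bp; cluster definition is degenerate")
  }
  structure(
    list(k = k, w = w, alpha = alpha, n = n, L = L, lambda = lambda),
    class = "cluster_definition"
  )
}

#' @export
print.cluster_definition <- function(x, ...) {
  cat(sprintf(
    "Cluster definition: >= %d sites within %s bp (alpha = %g, n = %s, L = %s bp)\n",
    x$k, format(x$w, big.mark = ","), x$alpha,
    format(x$n, big.mark = ","), format(x$L, big.mark = ",")
  ))
  invisible(x)
}

#' Call integration clusters (hot spots)
#'
#' A qualifying window is any set of at least `k` sites spanning at most
#' `w` bp; overlapping or chained qualifying windows merge into one maximal
#' cluster, so every site belongs to at most one cluster. Sites are pooled
#' across strands and processed per chromosome (and per dataset when a
#' `dataset` column is present).
#'
#' @param sites Site tibble (`chrom`, `pos`, optionally `dataset`).
#' @param definition A [derive_threshold()] result, or any list with
#'   elements `k` and `w`.
#'
#' @return Tibble: `dataset`, `chrom`, `start` (first site), `end` (last
#'   site, inclusive), `n_sites`, `span` (= end - start).
#' @export
call_clusters <- function(sites, definition) {
  sites <- assert_sites(as_tibble(sites))
  if (!"dataset" %in% names(sites)) sites$dataset <- "sites"
  k <- definition$k
  w <- definition$w
  empty <- tibble(
    dataset = character(0), chrom = character(0), start = numeric(0),
    end = numeric(0), n_sites = integer(0), span = numeric(0)
  )
  if (nrow(sites) < k) return(empty)

  sites %>%
    group_by(.data$dataset, .data$chrom) %>%
    arrange(.data$pos, .by_group = TRUE) %>%
    group_modify(function(df, key) {
      pos <- df$pos
      m <- length(pos)
      if (m < k) return(empty[, c("start", "end", "n_sites", "span")])
      anchors <- which(pos[seq_len(m - k + 1) + (k - 1)] - pos[seq_len(m - k + 1)] <= w)
      if (length(anchors) == 0) return(empty[, c("start", "end", "n_sites", "span")])
      # merge index windows [a, a + k - 1] that share at least one site
      lo <- anchors
      hi <- anchors + (k - 1)
      brk <- c(TRUE, lo[-1] > head(hi, -1))
      grp <- cumsum(brk)
      lo_min <- as.integer(tapply(lo, grp, min))
      hi_max <- as.integer(tapply(hi, grp, max))
      tibble(
        start = pos[lo_min],
        end = pos[hi_max],
        n_sites = hi_max - lo_min + 1L,
        span = pos[hi_max] - pos[lo_min]
      )
    }) %>%
    ungroup()
}

#' Summary statistics of a cluster set
#'
#' @param clusters Output of [call_clusters()].
#' @param n Total number of sites in the dataset the clusters were called
#'   on (used for the clustered percentage).
#'
#' @return One-row tibble: `n_clusters`, `clustered_sites`,
#'   `pct_sites_in_clusters`, `mean_cluster_dimension` (`NA` when no
#'   clusters), `max_cluster_dimension`, `mean_span`, `max_span`.
#' @export
cluster_summary <- function(clusters, n) {
  clusters <- as_tibble(clusters)
  if (nrow(clusters) == 0) {
    return(tibble(
      n_clusters = 0L, clustered_sites = 0L, pct_sites_in_clusters = 0,
      mean_cluster_dimension = NA_real_, max_cluster_dimension = NA_integer_,
      mean_span = NA_real_, max_span = NA_real_
    ))
  }
  tibble(
    n_clusters = nrow(clusters),
    clustered_sites = sum(clusters$n_sites),
    pct_sites_in_clusters = 100 * sum(clusters$n_sites) / n,
    mean_cluster_dimension = sum(clusters$n_sites) / nrow(clusters),
    max_cluster_dimension = max(clusters$n_sites),
    mean_span = mean(clusters$span),
    max_span = max(clusters$span)
  )
}

#' Per-locus site and cluster counts
#'
#' Reports, for each named genomic locus and each dataset, how many sites
#' fall inside the locus, how many called clusters overlap it, and the site
#' density per Mb — the per-locus view used to inspect known hot spots.
#'
#' @param sites Site tibble with a `dataset` column.
#' @param loci Named intervals: tibble `name`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param clusters Optional [call_clusters()] output for the same sites.
#'
#' @return Tibble: `name`, `dataset`, `n_sites`, `n_clusters`,
#'   `sites_per_mb`.
#' @export
locus_report <- function(sites, loci, clusters = NULL) {
  sites <- assert_sites(as_tibble(sites))
  if (!"dataset" %in% names(sites)) sites$dataset <- "sites"
  loci <- as_tibble(loci)
  unknown <- setdiff(unique(loci$chrom), unique(sites$chrom))
  if (length(unknown) > 0) {
    warn(paste0(
      "loci on chromosome(s) absent from the site set: ",
      paste(unknown, collapse = ", ")
    ))
  }
  datasets <- unique(sites$dataset)
  grid <- tidyr::expand_grid(name = loci$name, dataset = datasets) %>%
    left_join(loci, by = "name")

  pairs <- overlap_pairs(as_gr(loci), sites_gr(sites))
  site_counts <- pairs %>%
    mutate(name = loci$name[.data$query], dataset = sites$dataset[.data$subject]) %>%
    count(.data$name, .data$dataset, name = "n_sites")

  out <- grid %>%
    left_join(site_counts, by = c("name", "dataset")) %>%
    mutate(
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      sites_per_mb = .data$n_sites / ((.data$end - .data$start) / 1e6)
    )
  if (!is.null(clusters) && nrow(as_tibble(clusters)) > 0) {
    clusters <- as_tibble(clusters)
    cl_gr <- GenomicRanges::GRanges(
      seqnames = clusters$chrom,
      ranges = IRanges::IRanges(start = clusters$start + 1, end = clusters$end + 1)
    )
    cp <- overlap_pairs(as_gr(loci), cl_gr)
    cl_counts <- cp %>%
      mutate(name = loci$name[.data$query], dataset = clusters$dataset[.data$subject]) %>%
      count(.data$name, .data$dataset, name = "n_clusters")
    out <- out %>%
      left_join(cl_counts, by = c("name", "dataset")) %>%
      mutate(n_clusters = dplyr::coalesce(.data$n_clusters, 0L))
  } else {
    out$n_clusters <- 0L
  }
  out %>% select("name", "dataset", "n_sites", "n_clusters", "sites_per_mb")
}
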