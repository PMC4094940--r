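#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Tests whether a category is differentially represented between two
#' datasets. The table is laid out as rows = datasets, columns =
#' in-category / not-in-category: `a` and `b` are the first dataset's
#' counts, `c` and `d` the second's. The two-sided p-value follows the
#' standard convention: the sum of probabilities of all tables (with the
#' same margins) whose point hypergeometric probability does not exceed the
#' observed table's. The odds ratio reported is the sample odds ratio
#' `(a d) / (b c)` (0 and infinity when a margin cell is empty; `NA` when
#' indeterminate).
#'
#' @param a,b Counts for dataset 1: in category, not in category.
#' @param c,d Counts for dataset 2: in category, not in category.
#' @param alpha Significance level used to set the `significant` flag.
#'
#' @return An object of class `contingency_result`: list with `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `p_two_sided`, `alpha`, `significant`.
#' @export
#'
#' @examples
#' fisher_two_sided(2, 8, 8, 2)
fisher_two_sided <- function(a, b, c, d, alpha = 0.01) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0)) abort("counts must be non-negative")
  if (a + b == 0 || c + d == 0) abort("a dataset margin is zero")
  tab <- matrix(c(a, c, b, d), nrow = 2)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
  structure(
    list(
      a = a, b = b, c = c, d = d,
      odds_ratio = or, p_two_sided = p,
      alpha = alpha, significant = p < alpha
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf(
    "2x2 Fisher: [%d %d; %d %d]  OR = %.4g  p = %.4g%s\n",
    x$a, x$b, x$c, x$d, x$odds_ratio, x$p_two_sided,
    if (x$significant) sprintf("  (significant at %g)", x$alpha) else ""
  ))
  invisible(x)
}

#' Pairwise category comparisons between datasets
#'
#' For every unordered pair of datasets and every category, builds the 2x2
#' table (in category vs not, per dataset) and runs the two-sided Fisher's
#' exact test. No multiple-testing correction is applied by default; set
#' `correct` to a [stats::p.adjust()] method name to add an adjusted
#' p-value column.
#'
#' @param summary A per-dataset category summary as produced by
#'   [summarize_annotation()]: columns `dataset`, `category`, `count`,
#'   `total`.
#' @param categories Optional character vector restricting the categories
#'   compared.
#' @param alpha Significance level for the `star` flag.
#' @param correct `NULL` (default, no correction) or a method name for
#'   [stats::p.adjust()].
#'
#' @return Tibble: `dataset_1`, `dataset_2`, `category`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `p`, `star` (logical, p < alpha), and `p_adj` when
#'   `correct` is given. Categories missing from one dataset of a pair are
#'   skipped with a warning.
#' @export
compare_categories <- function(summary, categories = NULL, alpha = 0.01,
                               correct = NULL) {
  summary <- as_tibble(summary)
  if (!is.null(categories)) {
    summary <- summary %>% filter(.data$category %in% categories)
  }
  datasets <- unique(summary$dataset)
  if (length(datasets) < 2) abort("need at least two datasets to compare")
  pairs <- utils::combn(datasets, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    s1 <- summary %>% filter(.data$dataset == pr[1])
    s2 <- summary %>% filter(.data$dataset == pr[2])
    cats <- union(s1$category, s2$category)
    missing <- setdiff(cats, intersect(s1$category, s2$category))
    if (length(missing) > 0) {
      warn(paste0(
        "category absent in one dataset of (", pr[1], ", ", pr[2], "): ",
        paste(missing, collapse = ", ")
      ))
    }
    purrr::map(intersect(s1$category, s2$category), function(cat) {
      r1 <- s1 %>% filter(.data$category == cat)
      r2 <- s2 %>% filter(.data$category == cat)
      fr <- fisher_two_sided(
        r1$count, r1$total - r1$count,
        r2$count, r2$total - r2$count,
        alpha = alpha
      )
      tibble(
        dataset_1 = pr[1], dataset_2 = pr[2], category = cat,
        a = fr$a, b = fr$b, c = fr$c, d = fr$d,
        odds_ratio = fr$odds_ratio, p = fr$p_two_sided, star = fr$significant
      )
    }) %>% bind_rows()
  }) %>% bind_rows()
  if (!is.null(correct)) {
    rows$p_adj <- stats::p.adjust(rows$p, method = correct)
  }
  rows
}

#' Reconstruct a count from a printed percentage and total
#'
#' Utility for reproduction checks against published summary tables that
#' print percentages and dataset totals: the in-category count is the
#' nearest integer to `percent * total / 100`. Not used by the pipeline
#' itself.
#'
#' @param percent Printed percentage.
#' @param total Dataset size.
#' @return Integer count.
#' @export
count_from_percent <- function(percent, total) {
  as.integer(round(percent * total / 100))
}
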