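#' Tidy a 2x2 Fisher comparison
#'
#' @param x A [fisher_two_sided()] result.
#' @param ... Unused.
#' @return A one-row tibble with the counts, odds ratio, p-value and
#'   significance flag.
#' @method tidy contingency_result
#' @export
tidy.contingency_result <- function(x, ...) {
  tibble(
    a = x$a, b = x$b, c = x$c, d = x$d,
    odds_ratio = x$odds_ratio, p_value = x$p_two_sided,
    significant = x$significant
  )
}

#' Tidy a cluster definition
#'
#' @param x A [derive_threshold()] result.
#' @param ... Unused.
#' @return A one-row tibble with `k`, `w`, `alpha`, `n`, `L`, `lambda`.
#' @method tidy cluster_definition
#' @export
tidy.cluster_definition <- function(x, ...) {
  tibble(k = x$k, w = x$w, alpha = x$alpha, n = x$n, L = x$L, lambda = x$lambda)
}

#' One-row summary of a cluster definition
#'
#' @param x A [derive_threshold()] result.
#' @param ... Unused.
#' @return A one-row tibble with the window and the expected number of
#'   qualifying anchor sites under the Poisson null (`n * alpha`).
#' @method glance cluster_definition
#' @export
glance.cluster_definition <- function(x, ...) {
  tibble(w = x$w, expected_null_anchors = x$n * x$alpha)
}

#' @export
generics::tidy

#' @export
generics::glance
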