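# Independent brute-force oracles: plain loops over all pairs/subsets,
# sharing no code with the package implementations.

oracle_classify_region <- function(chrom, pos, genes, tss_window = 2500) {
  res <- "INTERGENIC"
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    tss <- if (genes$strand[i] == "+") genes$tx_start[i] else genes$tx_end[i] - 1
    if (abs(pos - tss) <= tss_window) return("TSS_PROXIMAL")
    if (pos >= genes$tx_start[i] && pos < genes$tx_end[i]) res <- "INTRAGENIC"
  }
  res
}

oracle_features <- function(chrom, pos, features, window = 1000, min_overlap = 1) {
  hit <- character(0)
  ws <- pos - window
  we <- pos + window + 1 # half-open window end
  for (i in seq_len(nrow(features))) {
    if (features$chrom[i] != chrom) next
    ov <- min(features$end[i], we) - max(features$start[i], ws)
    if (ov >= min_overlap) hit <- c(hit, features$class[i])
  }
  sort(unique(hit))
}

oracle_repeat <- function(chrom, pos, repeats) {
  best <- NA_character_
  best_w <- Inf
  for (i in seq_len(nrow(repeats))) {
    if (repeats$chrom[i] != chrom) next
    if (pos >= repeats$start[i] && pos < repeats$end[i]) {
      w <- repeats$end[i] - repeats$start[i]
      if (w < best_w || (w == best_w && repeats$family[i] < best)) {
        best <- repeats$family[i]
        best_w <- w
      }
    }
  }
  best
}

# exhaustive k-subset enumeration + transitive merge; positions one chromosome
oracle_clusters <- function(pos, k, w) {
  pos <- sort(pos)
  n <- length(pos)
  if (n < k) return(data.frame(start = numeric(0), end = numeric(0), n_sites = integer(0)))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  in_cluster <- rep(FALSE, n)
  cmb <- utils::combn(n, k)
  for (j in seq_len(ncol(cmb))) {
    idx <- cmb[, j]
    if (pos[max(idx)] - pos[min(idx)] <= w) {
      in_cluster[idx] <- TRUE
      r <- find(idx[1])
      for (x in idx[-1]) {
        rx <- find(x)
        if (rx != r) parent[rx] <- r
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  keep <- which(in_cluster)
  if (length(keep) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0), n_sites = integer(0)))
  }
  comp <- split(keep, roots[keep])
  out <- data.frame(
    start = vapply(comp, function(i) min(pos[i]), 1),
    end = vapply(comp, function(i) max(pos[i]), 1),
    n_sites = vapply(comp, length, 1L)
  )
  out[order(out$start), , drop = FALSE]
}

# exact two-sided Fisher p by direct hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  kk <- a + c
  lo <- max(0, kk - n2)
  hi <- min(kk, m)
  probs <- stats::dhyper(lo:hi, m, n2, kk)
  p_obs <- stats::dhyper(a, m, n2, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
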