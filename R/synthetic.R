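# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# place n non-overlapping intervals of the given widths on the genome;
# uniform proposals with rejection, bounded attempts
place_nonoverlapping <- function(chrom_sizes, widths, max_tries = 200, what = "interval") {
  n <- length(widths)
  placed <- vector("list", length = nrow(chrom_sizes))
  names(placed) <- chrom_sizes$chrom
  out_chrom <- character(n)
  out_start <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample.int(nrow(chrom_sizes), 1, prob = chrom_sizes$size)
      size <- chrom_sizes$size[ci]
      if (size <= widths[i]) next
      st <- floor(runif(1, 0, size - widths[i]))
      ivs <- placed[[ci]]
      clash <- !is.null(ivs) &&
        any(st < ivs[, 2] & (st + widths[i]) > ivs[, 1])
      if (!clash) {
        placed[[ci]] <- rbind(ivs, c(st, st + widths[i]))
        out_chrom[i] <- chrom_sizes$chrom[ci]
        out_start[i] <- st
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf(
        "could not place %s %d of %d without overlap after %d attempts; genome too crowded",
        what, i, n, max_tries
      ))
    }
  }
  tibble(chrom = out_chrom, start = out_start, end = out_start + widths)
}

#' Generate a miniature synthetic genome annotation
#'
#' Builds a small genome (coordinates only, no sequence) with the
#' annotation layers the integration-site analysis consumes: non-overlapping
#' gene models, feature tracks (CpG islands near TSSs; scattered CNCs,
#' conserved TFBSs and DNase I hypersensitive sites), a non-overlapping
#' repeat track with family labels, and histone-mark domains laid out the
#' way they sit in real chromatin: H3K4me3 over TSSs, H3K4me1 flanking
#' them, H3K36me3 over transcribed gene bodies, H3K27me3 in gene-free
#' domains.
#'
#' Densities (documented defaults): CpG islands at 60% of TSSs; 10 CNCs
#' (300 bp), 30 TFBSs (200 bp) and 15 DNase sites (500 bp) per Mb; repeats
#' drawn from families LINE/SINE/Satellite/LTR/Other with weights
#' 0.20/0.40/0.05/0.15/0.20 until ~25% of the genome is repeat-covered.
#'
#' @param n_chroms Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_len Length of each chromosome in bp.
#' @param n_genes Number of genes to place genome-wide; an error naming the
#'   constraint is raised when they cannot be placed without overlap.
#' @param seed Integer seed; the output is deterministic for a fixed seed
#'   and the caller's RNG state is left untouched.
#'
#' @return An object of class `synthetic_genome`: a list with tibbles
#'   `chrom_sizes` (`chrom`, `size`), `genes`, `features` (`class`,
#'   `chrom`, `start`, `end`), `repeats` (`family`, ...), `marks`
#'   (`mark`, ...).
#' @export
#'
#' @examples
#' g <- make_genome(n_chroms = 1, chrom_len = 1e6, n_genes = 10, seed = 1)
#' g$genes
make_genome <- function(n_chroms = 2, chrom_len = 1e7, n_genes = 200, seed = 1) {
  with_seed(seed, {
    chrom_sizes <- tibble(
      chrom = paste0("chr", seq_len(n_chroms)),
      size = rep(as.numeric(chrom_len), n_chroms)
    )
    genome_len <- sum(chrom_sizes$size)

    # genes: log-normal lengths, typical 10-60 kb, placed without overlap
    if (n_genes > 0) {
      glen <- pmin(pmax(round(exp(rnorm(n_genes, log(2e4), 0.6))), 2000), 1e5)
      gpos <- place_nonoverlapping(chrom_sizes, glen, what = "gene")
      genes <- gpos %>%
        mutate(
          gene_id = sprintf("GENE%04d", seq_len(n_genes)),
          strand = sample(c("+", "-"), n_genes, replace = TRUE),
          tx_start = as.integer(.data$start),
          tx_end = as.integer(.data$end)
        ) %>%
        select("gene_id", "chrom", "strand", "tx_start", "tx_end") %>%
        with_tss() %>%
        arrange(.data$chrom, .data$tx_start)
    } else {
      genes <- tibble(
        gene_id = character(0), chrom = character(0), strand = character(0),
        tx_start = integer(0), tx_end = integer(0), tss = integer(0)
      )
    }

    clip <- function(df) {
      df %>%
        left_join(chrom_sizes, by = "chrom") %>%
        mutate(
          start = pmax(.data$start, 0),
          end = pmin(.data$end, .data$size)
        ) %>%
        filter(.data$end > .data$start) %>%
        select(-"size")
    }

    # CpG islands near a subset of TSSs
    has_cpg <- if (n_genes > 0) runif(n_genes) < 0.6 else logical(0)
    cpg <- if (any(has_cpg)) {
      gg <- genes[has_cpg, ]
      width <- round(runif(nrow(gg), 400, 1500))
      st <- gg$tss - round(runif(nrow(gg), 200, 800))
      clip(tibble(chrom = gg$chrom, start = st, end = st + width)) %>%
        mutate(class = "CpG")
    } else {
      tibble(chrom = character(0), start = numeric(0), end = numeric(0), class = character(0))
    }

    scatter <- function(per_mb, width, label) {
      n <- round(per_mb * genome_len / 1e6)
      ci <- sample.int(nrow(chrom_sizes), n, replace = TRUE, prob = chrom_sizes$size)
      st <- floor(runif(n, 0, chrom_sizes$size[ci] - width))
      tibble(
        chrom = chrom_sizes$chrom[ci], start = st, end = st + width,
        class = label
      )
    }
    features <- bind_rows(
      cpg,
      scatter(10, 300, "CNC"),
      scatter(30, 200, "TFBS"),
      scatter(15, 500, "DNase")
    ) %>%
      select("class", "chrom", "start", "end") %>%
      arrange(.data$class, .data$chrom, .data$start)

    # repeats: non-overlapping, family-labelled, ~25% genome coverage
    fam_w <- c(LINE = 0.20, SINE = 0.40, Satellite = 0.05, LTR = 0.15, Other = 0.20)
    fam_len <- list(
      LINE = c(1000, 6000), SINE = c(150, 400), Satellite = c(1000, 3000),
      LTR = c(500, 1500), Other = c(200, 800)
    )
    target_bp <- 0.25 * genome_len
    fams <- character(0)
    widths <- numeric(0)
    total <- 0
    while (total < target_bp) {
      f <- sample(names(fam_w), 1, prob = fam_w)
      wdt <- round(runif(1, fam_len[[f]][1], fam_len[[f]][2]))
      fams <- c(fams, f)
      widths <- c(widths, wdt)
      total <- total + wdt
    }
    repeats <- place_nonoverlapping(chrom_sizes, widths, what = "repeat") %>%
      mutate(family = fams) %>%
      select("family", "chrom", "start", "end") %>%
      arrange(.data$chrom, .data$start)

    # histone-mark domains anchored on the gene layout
    if (n_genes > 0) {
      k4me3 <- tibble(
        mark = "H3K4me3", chrom = genes$chrom,
        start = genes$tss - 1000, end = genes$tss + 1000
      )
      k4me1 <- bind_rows(
        tibble(
          mark = "H3K4me1", chrom = genes$chrom,
          start = genes$tss - 5000, end = genes$tss - 1000
        ),
        tibble(
          mark = "H3K4me1", chrom = genes$chrom,
          start = genes$tss + 1000, end = genes$tss + 5000
        )
      )
      body_start <- if_else(genes$strand == "+", genes$tx_start + 2000, genes$tx_start)
      body_end <- if_else(genes$strand == "+", genes$tx_end, genes$tx_end - 2000)
      k36 <- tibble(
        mark = "H3K36me3", chrom = genes$chrom,
        start = body_start, end = body_end
      ) %>% filter(.data$end - .data$start >= 2500)
    } else {
      k4me3 <- k4me1 <- k36 <- tibble(
        mark = character(0), chrom = character(0),
        start = numeric(0), end = numeric(0)
      )
    }
    # heterochromatic domains in gene-free gaps (genes padded by 5 kb)
    n_het <- round(2 * genome_len / 1e6)
    het <- NULL
    if (n_het > 0) {
      pad <- if (n_genes > 0) {
        GenomicRanges::reduce(GenomicRanges::GRanges(
          genes$chrom,
          IRanges::IRanges(pmax(genes$tx_start + 1 - 5000, 1), genes$tx_end + 5000)
        ))
      } else {
        GenomicRanges::GRanges()
      }
      whole <- GenomicRanges::GRanges(
        chrom_sizes$chrom, IRanges::IRanges(1, chrom_sizes$size)
      )
      free <- GenomicRanges::setdiff(whole, pad)
      free <- free[IRanges::width(free) >= 5000]
      if (length(free) > 0) {
        gi <- sample.int(length(free), n_het, replace = TRUE,
          prob = IRanges::width(free))
        want_w <- round(runif(n_het, 30000, 60000))
        hw <- pmin(want_w, floor(0.9 * IRanges::width(free)[gi]))
        hs <- floor(runif(
          n_het, IRanges::start(free)[gi] - 1,
          IRanges::end(free)[gi] - hw
        ))
        het <- tibble(
          mark = "H3K27me3",
          chrom = as.character(GenomicRanges::seqnames(free))[gi],
          start = hs, end = hs + hw
        )
      }
    }
    marks <- bind_rows(k4me3, k4me1, k36, het) %>%
      select("mark", "chrom", "start", "end") %>%
      clip() %>%
      arrange(.data$mark, .data$chrom, .data$start)

    structure(
      list(
        chrom_sizes = chrom_sizes, genes = genes, features = features,
        repeats = repeats, marks = marks
      ),
      class = "synthetic_genome"
    )
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "Synthetic genome: %d chromosome(s), %s bp; %d genes, %d feature intervals, %d repeats, %d mark domains\n",
    nrow(x$chrom_sizes), format(sum(x$chrom_sizes$size), big.mark = ","),
    nrow(x$genes), nrow(x$features), nrow(x$repeats), nrow(x$marks)
  ))
  invisible(x)
}

#' Site-generator configuration
#'
#' Defines one synthetic integration-site dataset as a three-component
#' placement mixture: a Gaussian around a uniformly chosen TSS (modelling
#' TSS-tropic, gamma-retrovirus-like vectors), uniform within a uniformly
#' chosen gene span (lentivirus-like gene-body tropism), and uniform over
#' the whole genome (alpharetrovirus-like / random control).
#'
#' @param n_sites Number of sites to draw (>= 1).
#' @param weights Numeric length-3 vector `c(p_tss, p_genebody, p_uniform)`,
#'   non-negative, summing to 1 within 1e-9.
#' @param tss_spread Standard deviation (bp) of the Gaussian TSS component.
#' @param seed Integer seed.
#' @param dataset Label attached to the generated sites.
#'
#' @return A list of class `site_config`.
#' @export
site_config <- function(n_sites, weights = c(0, 0, 1), tss_spread = 500,
                        seed = 1, dataset = "synthetic") {
  if (n_sites < 1) abort("`n_sites` must be >= 1")
  if (length(weights) != 3 || any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must be 3 non-negative values summing to 1")
  }
  structure(
    list(
      n_sites = as.integer(n_sites),
      weights = setNames(as.numeric(weights), c("p_tss", "p_genebody", "p_uniform")),
      tss_spread = tss_spread, seed = seed, dataset = dataset
    ),
    class = "site_config"
  )
}

#' Draw synthetic integration sites from a placement mixture
#'
#' Each site is assigned to one mixture component (TSS-Gaussian, gene-body,
#' uniform) with the configured weights, then placed accordingly; TSS
#' placements are truncated to the chromosome. Strands are uniform.
#' Deterministic for a fixed seed.
#'
#' @param genome A [make_genome()] result (or a list with `chrom_sizes` and
#'   `genes` tibbles).
#' @param config A [site_config()].
#'
#' @return A site tibble: `chrom`, `pos`, `strand`, `dataset`,
#'   `support`, `ambiguous`, `match_group`, `component`.
#' @export
generate_sites <- function(genome, config) {
  if (!inherits(config, "site_config")) {
    abort("`config` must be a site_config()")
  }
  genes <- genome$genes
  cs <- genome$chrom_sizes
  w <- config$weights
  if (nrow(genes) == 0 && (w[["p_tss"]] > 0 || w[["p_genebody"]] > 0)) {
    abort("genome has no genes but a gene-anchored mixture weight is positive")
  }
  with_seed(config$seed, {
    n <- config$n_sites
    comp <- sample(c("tss", "genebody", "uniform"), n, replace = TRUE, prob = w)
    chrom <- character(n)
    pos <- numeric(n)

    i_t <- which(comp == "tss")
    if (length(i_t) > 0) {
      g <- sample.int(nrow(genes), length(i_t), replace = TRUE)
      chrom[i_t] <- genes$chrom[g]
      size <- cs$size[match(genes$chrom[g], cs$chrom)]
      pos[i_t] <- pmin(pmax(round(rnorm(length(i_t), genes$tss[g], config$tss_spread)), 0), size - 1)
    }
    i_g <- which(comp == "genebody")
    if (length(i_g) > 0) {
      g <- sample.int(nrow(genes), length(i_g), replace = TRUE)
      chrom[i_g] <- genes$chrom[g]
      pos[i_g] <- floor(runif(length(i_g), genes$tx_start[g], genes$tx_end[g]))
    }
    i_u <- which(comp == "uniform")
    if (length(i_u) > 0) {
      ci <- sample.int(nrow(cs), length(i_u), replace = TRUE, prob = cs$size)
      chrom[i_u] <- cs$chrom[ci]
      pos[i_u] <- floor(runif(length(i_u), 0, cs$size[ci]))
    }
    tibble(
      chrom = chrom, pos = as.integer(pos),
      strand = sample(c("+", "-"), n, replace = TRUE),
      dataset = config$dataset, support = 1L, ambiguous = FALSE,
      match_group = NA_character_, component = comp
    ) %>% arrange(.data$chrom, .data$pos)
  })
}

#' Sample ChIP-seq-like fragments for a histone mark
#'
#' Draws fixed-length fragments from a mixture of the mark's enriched
#' domains (as laid out by [make_genome()]) and uniform genomic background.
#' With per-base enrichment ratio `enrichment`, the probability that a
#' fragment originates in an enriched domain is
#' `enrichment * E / (enrichment * E + (G - E))` where `E` is the domain
#' footprint and `G` the genome length; `enrichment = 0` gives a flat,
#' all-background track.
#'
#' @param genome A [make_genome()] result.
#' @param mark Mark name; must exist in `genome$marks` (an error lists the
#'   available marks otherwise).
#' @param fragment_length Fragment length in bp.
#' @param depth Number of fragments to draw (0 gives an empty track).
#' @param seed Integer seed.
#' @param enrichment Per-base rate ratio of enriched domains over
#'   background (default 10).
#'
#' @return Fragment tibble: `mark`, `chrom`, `start`, `end`.
#' @export
generate_mark_fragments <- function(genome, mark, fragment_length = 200,
                                    depth = 10000, seed = 1, enrichment = 10) {
  avail <- unique(genome$marks$mark)
  if (!mark %in% avail) {
    abort(sprintf(
      "unknown mark '%s'; available marks: %s", mark,
      paste(avail, collapse = ", ")
    ))
  }
  cs <- genome$chrom_sizes
  dom <- genome$marks %>% filter(.data$mark == .env$mark)
  if (depth == 0) {
    return(tibble(
      mark = character(0), chrom = character(0),
      start = numeric(0), end = numeric(0)
    ))
  }
  with_seed(seed, {
    G <- sum(cs$size)
    E <- sum(dom$end - dom$start)
    q <- enrichment * E / (enrichment * E + (G - E))
    from_dom <- runif(depth) < q
    chrom <- character(depth)
    start <- numeric(depth)

    n_d <- sum(from_dom)
    if (n_d > 0) {
      di <- sample.int(nrow(dom), n_d, replace = TRUE, prob = dom$end - dom$start)
      base <- floor(runif(n_d, dom$start[di], dom$end[di]))
      chrom[from_dom] <- dom$chrom[di]
      start[from_dom] <- base - floor(fragment_length / 2)
    }
    n_b <- depth - n_d
    if (n_b > 0) {
      ci <- sample.int(nrow(cs), n_b, replace = TRUE, prob = cs$size)
      chrom[!from_dom] <- cs$chrom[ci]
      start[!from_dom] <- floor(runif(n_b, 0, cs$size[ci] - fragment_length))
    }
    size <- cs$size[match(chrom, cs$chrom)]
    start <- pmin(pmax(start, 0), size - fragment_length)
    tibble(mark = mark, chrom = chrom, start = start, end = start + fragment_length) %>%
      arrange(.data$chrom, .data$start)
  })
}
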