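# Small fixtures built in code.

fix_genes <- function() {
  tibble::tibble(
    gene_id = c("GA", "GB", "GC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tx_start = c(10000L, 40000L, 5000L),
    tx_end = c(20000L, 60000L, 9000L)
  )
}

fix_sites <- function(pos, chrom = "chr1", dataset = "test") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), strand = "+",
    dataset = dataset, support = 1L, ambiguous = FALSE,
    match_group = NA_character_
  )
}

# one alignment hit row
hit <- function(read_id, chrom = "chr1", start = 1000L, end = 1080L,
                strand = "+", identity = 100, aligned_length = NULL) {
  tibble::tibble(
    read_id = read_id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = strand, identity = identity,
    aligned_length = if (is.null(aligned_length)) as.integer(end - start) else as.integer(aligned_length)
  )
}

random_genes <- function(n, chroms = c("chr1", "chr2"), chrom_len = 1e6) {
  len <- sample(2000:20000, n, replace = TRUE)
  st <- sapply(len, function(l) sample.int(chrom_len - l, 1))
  tibble::tibble(
    gene_id = sprintf("R%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    tx_start = as.integer(st),
    tx_end = as.integer(st + len)
  )
}

# mimic sites as one-hit reads (for idempotence checks)
sites_as_hits <- function(sites) {
  tibble::tibble(
    read_id = sprintf("rd%05d", seq_len(nrow(sites))),
    chrom = sites$chrom,
    start = ifelse(sites$strand == "+", sites$pos, sites$pos - 79L),
    end = ifelse(sites$strand == "+", sites$pos + 80L, sites$pos + 1L),
    strand = sites$strand,
    identity = 100,
    aligned_length = 80L
  )
}
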