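# Readers and writers for the plain-text genomics formats the pipeline
# consumes and produces. All coordinates are 0-based half-open on disk and
# in memory; sites are one-bp BED intervals (start = pos, end = pos + 1).

#' Read and write integration sites as BED6
#'
#' Sites are stored as one-bp intervals: `start` is the 0-based junction
#' base, `name` the dataset label, `score` the read support, plus strand.
#'
#' @param path File path.
#' @return `read_bed_sites()`: a site tibble (`chrom`, `pos`, `strand`,
#'   `dataset`, `support`).
#' @export
read_bed_sites <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", comment = "#", progress = FALSE
  )
  tibble(
    chrom = df$chrom, pos = df$start, strand = df$strand,
    dataset = df$name, support = df$score,
    ambiguous = FALSE, match_group = NA_character_
  )
}

#' @rdname read_bed_sites
#' @param sites Site tibble.
#' @export
write_bed_sites <- function(sites, path) {
  sites <- assert_sites(as_tibble(sites))
  if (!"dataset" %in% names(sites)) sites$dataset <- "sites"
  if (!"support" %in% names(sites)) sites$support <- 1L
  if (!"strand" %in% names(sites)) sites$strand <- "+"
  out <- tibble(
    chrom = sites$chrom, start = sites$pos, end = sites$pos + 1,
    name = sites$dataset, score = sites$support, strand = sites$strand
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write UCSC chrom.sizes files
#'
#' @param path File path.
#' @return `read_chrom_sizes()`: tibble `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "size"), col_types = "cd",
    comment = "#", progress = FALSE
  )
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Tibble `chrom`, `size`.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  readr::write_tsv(chrom_sizes, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write refFlat-style gene tables
#'
#' Five columns: gene id, chromosome, strand, txStart, txEnd (0-based
#' half-open). The TSS column is derived on read.
#'
#' @param path File path.
#' @return `read_refflat()`: gene-model tibble with a derived `tss`.
#' @export
read_refflat <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("gene_id", "chrom", "strand", "tx_start", "tx_end"),
    col_types = "cccii", comment = "#", progress = FALSE
  )
  with_tss(df)
}

#' @rdname read_refflat
#' @param genes Gene-model tibble.
#' @export
write_refflat <- function(genes, path) {
  out <- genes %>% select("gene_id", "chrom", "strand", "tx_start", "tx_end")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write BED4 feature tracks
#'
#' The name column carries the feature class (CpG, CNC, TFBS, DNase, a
#' repeat family, or a histone mark).
#'
#' @param path File path.
#' @param name_col What to call the name column in the returned tibble
#'   (`"class"` for feature tracks, `"family"` for repeats, `"mark"` for
#'   mark tracks).
#' @return `read_bed_track()`: tibble `chrom`, `start`, `end` plus the
#'   name column.
#' @export
read_bed_track <- function(path, name_col = "class") {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name"),
    col_types = "cddc", comment = "#", progress = FALSE
  )
  df[[name_col]] <- df$name
  df %>% select(dplyr::all_of(c(name_col, "chrom", "start", "end")))
}

#' @rdname read_bed_track
#' @param track Tibble with `chrom`, `start`, `end` and a name column.
#' @export
write_bed_track <- function(track, path, name_col = "class") {
  out <- tibble(
    chrom = track$chrom, start = track$start, end = track$end,
    name = track[[name_col]]
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read tabular junction-read alignment hits
#'
#' Expects a BLAST-outfmt6-like tab-separated table. The default column
#' mapping is `read_id`, `chrom`, `start`, `end`, `strand`, `identity`,
#' `aligned_length`; pass `col_map` to adapt other dialects (a named
#' character vector mapping those canonical names to column positions or
#' names in the file).
#'
#' @param path File path.
#' @param col_map Optional named vector mapping canonical column names to
#'   file column indices.
#' @return Hit tibble in the canonical layout.
#' @export
read_alignment_hits <- function(path, col_map = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
    progress = FALSE, show_col_types = FALSE)
  canonical <- c("read_id", "chrom", "start", "end", "strand", "identity", "aligned_length")
  idx <- if (is.null(col_map)) setNames(seq_along(canonical), canonical) else col_map
  out <- tibble(
    read_id = as.character(raw[[idx[["read_id"]]]]),
    chrom = as.character(raw[[idx[["chrom"]]]]),
    start = as.integer(raw[[idx[["start"]]]]),
    end = as.integer(raw[[idx[["end"]]]]),
    strand = as.character(raw[[idx[["strand"]]]]),
    identity = as.numeric(raw[[idx[["identity"]]]]),
    aligned_length = as.integer(raw[[idx[["aligned_length"]]]])
  )
  out
}

#' Write a profile as bedGraph
#'
#' Exports a [chip_density()] profile anchored at a reference position (for
#' browser display of one window) or any tibble with `chrom`, `start`,
#' `end`, `value` columns.
#'
#' @param df Tibble with `chrom`, `start`, `end`, `value`.
#' @param path File path.
#' @param track_name Track name written in the bedGraph header line.
#' @export
write_bedgraph <- function(df, path, track_name = "profile") {
  lines <- c(
    sprintf('track type=bedGraph name="%s"', track_name),
    sprintf("%s\t%s\t%s\t%s", df$chrom,
      format(df$start, scientific = FALSE, trim = TRUE),
      format(df$end, scientific = FALSE, trim = TRUE),
      format(df$value, trim = TRUE))
  )
  writeLines(lines, path)
  invisible(path)
}
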