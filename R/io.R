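#' Read RNA sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file and returns the
#' records as a tibble. DNA alphabet is accepted and converted to RNA
#' (`T` becomes `U`); any other symbol is an error.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_rna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  tibble(
    id = sub("\\s.*$", "", names(set)),
    seq = sanitize_rna(as.character(set))
  )
}

#' Write RNA sequences to a FASTA file
#'
#' @param x A tibble with columns `id` and `seq`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(x, path) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read transcript region annotation from GFF3
#'
#' Expects `five_prime_UTR`, `CDS` and `three_prime_UTR` features in
#' transcript coordinates (seqid = transcript id, 1-based inclusive).
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `transcript_id`, `region`
#'   (one of `"5UTR"`, `"CDS"`, `"3UTR"`), `start`, `end`.
#' @export
read_region_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("five_prime_UTR", "CDS", "three_prime_UTR")
  gr <- gr[keep]
  map <- c(five_prime_UTR = "5UTR", CDS = "CDS", three_prime_UTR = "3UTR")
  tibble(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    region = unname(map[as.character(gr$type)]),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  ) %>%
    dplyr::arrange(.data$transcript_id, .data$start)
}

#' Write transcript region annotation as GFF3
#'
#' @param regions A tibble with columns `transcript_id`, `region`, `start`,
#'   `end` (1-based inclusive, transcript coordinates).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_gff3 <- function(regions, path) {
  map <- c(`5UTR` = "five_prime_UTR", CDS = "CDS", `3UTR` = "three_prime_UTR")
  gr <- GenomicRanges::GRanges(
    seqnames = regions$transcript_id,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end),
    strand = "+",
    type = unname(map[regions$region]),
    source = "lrescan",
    phase = ifelse(regions$region == "CDS", 0L, NA_integer_)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write predicted sites as BED6
#'
#' Emits one interval per site covering stem positions -1 through +1
#' (5 nt), 0-based half-open as BED requires. The name field carries the
#' pattern string and the score field `1000 * min(score / 1.8, 1)` rounded
#' to an integer, so a "strong" site saturates at 1000.
#'
#' @param sites A tibble of predicted sites (see [scan_transcript()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- tibble(
    chrom = sites$transcript_id,
    start = sites$pos - 1L,
    end = sites$pos + 4L,
    name = sites$pattern,
    score = as.integer(round(1000 * pmin(sites$score / 1.8, 1))),
    strand = "+"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read / write plain TSV tables
#'
#' Thin wrappers around readr with the package's conventions (tab separated,
#' header row, no quoting surprises).
#'
#' @param path File path.
#' @return A tibble (`read_table_tsv`) or `path`, invisibly.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_table_tsv
#' @param x A data frame to write.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
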