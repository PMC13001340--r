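#' File-format helpers
#'
#' Thin wrappers over Biostrings / rtracklayer for the package's external
#' interfaces: FASTA for assemblies, BED6 for annotations, TSV for
#' fragments and tables. Fragment TSVs are 0-based half-open
#' (chrom/start/end), the BED convention.
#'
#' @name io
NULL

#' @rdname io
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname io
#' @param df data.frame with chrom/start/end (0-based half-open) plus
#'   optional name, score, strand columns.
#' @export
write_bed6 <- function(df, path) {
  bed <- data.frame(
    chrom = df$chrom, start = as.integer(df$start), end = as.integer(df$end),
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0,
    strand = if ("strand" %in% names(df)) df$strand else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr))
  md <- GenomicRanges::mcols(gr)
  if ("name" %in% names(md)) out$name <- md$name
  st <- as.character(GenomicRanges::strand(gr))
  if (!all(st == "*")) out$strand <- st
  out
}

#' @rdname io
#' @export
write_fragments_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_fragments_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
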