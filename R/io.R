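# File I/O for the standard formats the pipeline consumes and emits.
#
# Internal convention: exon tables are data.frames with columns
# transcript_id, gene_id, chrom, strand, start, end using 0-based half-open
# coordinates. GTF i/o converts to/from 1-based inclusive via rtracklayer;
# BED is natively 0-based half-open.

#' Convert an exon table to a GRanges object
#'
#' @param exons exon table (0-based half-open `start`/`end` columns).
#' @return a [GenomicRanges::GRanges] with `transcript_id` and `gene_id`
#'   metadata columns (1-based inclusive, as GRanges requires).
#' @export
exons_to_granges <- function(exons) {
  GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = ifelse(exons$strand %in% c("+", "-"), exons$strand, "*"),
    transcript_id = exons$transcript_id,
    gene_id = exons$gene_id
  )
}

granges_to_exons <- function(gr) {
  data.frame(
    transcript_id = S4Vectors::mcols(gr)$transcript_id,
    gene_id = S4Vectors::mcols(gr)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write an exon table as a GTF file
#'
#' Emits one `exon` feature per row (1-based inclusive coordinates).
#'
#' @param exons exon table (see [exons_to_granges()]).
#' @param path output file.
#' @export
write_gtf <- function(exons, path) {
  gr <- exons_to_granges(exons)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "lincforge"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GTF file into an exon table
#'
#' Keeps `exon` features only; coordinates converted to 0-based half-open.
#'
#' @param path GTF file.
#' @return exon table data.frame.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  }
  df <- granges_to_exons(gr)
  df[order(df$transcript_id, df$start), , drop = FALSE]
}

#' Write sequences to FASTA (60-column wrap)
#' @param seqs named character vector or XStringSet.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a DNA FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads to FASTQ with constant quality
#' @param seqs named character vector of reads.
#' @param path output file.
#' @param quality_char Phred+33 quality character applied to every base.
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  dna <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n) {
    strrep(quality_char, n)
  }, character(1)))
  q <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(q, path)
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Read BED3 intervals (0-based half-open)
#' @param path BED file.
#' @return data.frame with chrom, start, end.
#' @export
read_bed3 <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write BED3 intervals
#' @param df data.frame with chrom, start, end (0-based half-open).
#' @param path output file.
#' @export
write_bed3 <- function(df, path) {
  write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
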