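# Plain-text interchange: FASTA, BED-like TSV, and a minimal SV VCF.
# Internal coordinates are 0-based half-open; VCF output is 1-based.

#' Write named sequences to FASTA
#' @param seqs named character vector or list
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a data.frame as TSV (no quoting, no row names)
#' @param df data.frame
#' @param path output file
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write SV records as a minimal VCF 4.2
#'
#' Symbolic ALT (<DEL>/<DUP>/<INV>) with INFO END/SVTYPE/SVLEN;
#' converts the internal 0-based half-open interval to VCF's 1-based
#' inclusive convention.
#'
#' @param svs data.frame with chrom, start, end, sv_type
#' @param path output file
#' @param sample_id sample name recorded in the header
#' @export
write_sv_vcf <- function(svs, path, sample_id = "S1") {
  svt <- ifelse(svs$sv_type == "mCNV", "DUP", svs$sv_type)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=temrkit"),
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=DUP,Description=\"Duplication\">",
           "##ALT=<ID=INV,Description=\"Inversion\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           sprintf("##SAMPLE=<ID=%s>", sample_id),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  svlen <- ifelse(svt == "DEL", -(svs$end - svs$start), svs$end - svs$start)
  body <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tEND=%d;SVTYPE=%s;SVLEN=%d",
                  svs$chrom, svs$start + 1L,
                  sprintf("sv%04d", seq_len(nrow(svs))),
                  svt, svs$end, svt, svlen)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a symbolic-SV VCF into the package's call-table layout
#'
#' Uses VariantAnnotation when available; only PASS records with
#' SVTYPE in DEL/DUP/INV are returned, converted back to 0-based
#' half-open coordinates.
#'
#' @param path VCF file
#' @return data.frame with chrom, start, end, sv_type
#' @export
read_sv_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_sv_vcf needs the VariantAnnotation package")
  v <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(v)
  flt <- as.character(rr$FILTER)
  info <- VariantAnnotation::info(v)
  keep <- flt %in% c("PASS", ".") & info$SVTYPE %in% c("DEL", "DUP", "INV")
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr))[keep],
             start = GenomicRanges::start(rr)[keep] - 1L,
             end = as.integer(info$END[keep]),
             sv_type = as.character(info$SVTYPE[keep]),
             stringsAsFactors = FALSE)
}
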