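#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (Phred+33 qualities).
#' @return a `data.table` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a read table as FASTQ (Phred+33)
#'
#' @param reads a data.table/data.frame with `id`, `seq`, `qual` columns, or
#'   with `seq`, `qual`, `count` (records are expanded `count` times with
#'   serial ids).
#' @param path output file path.
#' @export
write_fastq <- function(reads, path) {
  reads <- as.data.table(reads)
  if (!"id" %in% names(reads)) {
    if ("count" %in% names(reads)) {
      idx <- rep(seq_len(nrow(reads)), reads$count)
      reads <- reads[idx, .(seq, qual)]
    }
    reads[, id := sprintf("read_%d", seq_len(.N))]
  }
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(lines, con)
  invisible(path)
}

#' Write a minimal VCF v4.2 known-variant file
#'
#' @param variants data.table with `contig`, `pos0` (0-based), `id`, `ref`,
#'   `alt` columns.
#' @param path output path.
#' @param contig_lengths named integer vector for the header.
#' @export
write_variants_vcf <- function(variants, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=mirED")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants)) sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                                      variants$contig, variants$pos0 + 1L,
                                      variants$id, variants$ref, variants$alt)
          else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a known-variant VCF into a variant table
#'
#' Only positions and alleles are retained; any overlapping record disqualifies
#' a candidate editing site regardless of its alternate allele.
#' @param path VCF file.
#' @return data.table with `contig`, `pos0`, `id`, `ref`, `alt`.
#' @export
read_variants_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- vapply(as.list(VariantAnnotation::alt(v)), function(a)
    paste(as.character(a), collapse = ","), character(1))
  data.table(contig = as.character(GenomicRanges::seqnames(rr)),
             pos0 = GenomicRanges::start(rr) - 1L,
             id = names(rr) %||% NA_character_,
             ref = as.character(VariantAnnotation::ref(v)),
             alt = alt)
}

write_tsv <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with at least `sample_id` and `stage` columns; an optional
#' `group` column carries the tumor/normal contrast. The stage order is
#' user-declared, never inferred from the labels.
#' @param path TSV file.
#' @param stages character vector giving the stage order.
#' @return data.table with `sample_id`, `stage` (factor, ordered as given),
#'   `group`.
#' @export
read_sample_sheet <- function(path, stages) {
  s <- as.data.table(read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("sample_id", "stage") %in% names(s)))
  if (!all(s$stage %in% stages))
    stopf("sample sheet contains stages not in the declared order: %s",
          paste(setdiff(s$stage, stages), collapse = ", "))
  s$stage <- factor(s$stage, levels = stages)
  if (!"group" %in% names(s)) s$group <- NA_character_
  s
}
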