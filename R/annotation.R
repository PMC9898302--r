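#' miRNA annotation table
#'
#' The annotation is a `data.table` with one row per feature and class
#' `mir_annotation`. Features are pre-miRNA hairpins (`type == "pre_mirna"`)
#' and their processed mature arms (`type == "mature"`, linked to the hairpin
#' through `derives_from`). Coordinates are stored 0-based, half-open
#' (`start0`, `end0`); GFF3 input/output converts to the 1-based closed
#' convention of that format. `mito` marks features on mitochondrial contigs.
#'
#' @param contig,start0,end0,strand,type,id,derives_from,mito vectors of equal
#'   length describing the features.
#' @return a `mir_annotation` data.table.
#' @export
mir_annotation <- function(contig, start0, end0, strand, type, id,
                           derives_from = NA_character_, mito = FALSE) {
  a <- data.table(
    contig = as.character(contig), start0 = as.integer(start0),
    end0 = as.integer(end0), strand = as.character(strand),
    type = as.character(type), id = as.character(id),
    derives_from = as.character(derives_from), mito = as.logical(mito)
  )
  stopifnot(all(a$end0 > a$start0), all(a$strand %in% c("+", "-")),
            all(a$type %in% c("pre_mirna", "mature")))
  setattr(a, "class", c("mir_annotation", class(data.table())))
  a[]
}

premirnas <- function(annotation) annotation[annotation$type == "pre_mirna", ]
matures   <- function(annotation) annotation[annotation$type == "mature", ]

#' Write a miRNA annotation as GFF3
#'
#' Features carry `ID`, `Derives_from` and `mito=true|false` attributes.
#' @param annotation a [mir_annotation()] table.
#' @param path output file path.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(start = annotation$start0 + 1L,
                              end = annotation$end0),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$type <- ifelse(annotation$type == "pre_mirna",
                                      "miRNA_primary_transcript", "miRNA")
  S4Vectors::mcols(gr)$source <- "mirED"
  S4Vectors::mcols(gr)$ID <- annotation$id
  S4Vectors::mcols(gr)$Derives_from <- annotation$derives_from
  S4Vectors::mcols(gr)$mito <- ifelse(annotation$mito, "true", "false")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a miRBase-style GFF3 annotation
#'
#' Accepts `miRNA_primary_transcript` / `miRNA` feature types (pre-miRNA and
#' mature arm); the optional `mito` attribute flags mitochondrial features and
#' defaults to false.
#' @param path GFF3 file.
#' @return a [mir_annotation()] table (0-based half-open coordinates).
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(gr$type)
  keep <- ty %in% c("miRNA_primary_transcript", "miRNA")
  gr <- gr[keep]; ty <- ty[keep]
  mito <- if (!is.null(gr$mito)) tolower(as.character(gr$mito)) == "true"
          else rep(FALSE, length(gr))
  df <- if (!is.null(gr$Derives_from)) {
    v <- gr$Derives_from
    if (is(v, "List") || is.list(v))
      vapply(v, function(x) if (length(x)) as.character(x[1]) else NA_character_,
             character(1))
    else as.character(v)
  } else rep(NA_character_, length(gr))
  mir_annotation(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = ifelse(ty == "miRNA_primary_transcript", "pre_mirna", "mature"),
    id = as.character(gr$ID),
    derives_from = df,
    mito = mito
  )
}

# map a genomic 0-based position to 1-based position within a feature row,
# respecting strand (position 1 is the feature's 5' end on its own strand)
feature_position <- function(pos0, feat_start0, feat_end0, feat_strand) {
  plus <- rep_len(feat_strand == "+", length(pos0))
  ifelse(plus, pos0 - feat_start0 + 1L, feat_end0 - pos0)
}

#' Extract mature miRNA sequences in sense (miRNA-strand) orientation
#'
#' @param genome a named `DNAStringSet`.
#' @param annotation a [mir_annotation()] table.
#' @return named character vector of DNA sequences, one per mature arm.
#' @export
mature_sequences <- function(genome, annotation) {
  m <- matures(annotation)
  out <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    s <- as.character(Biostrings::subseq(genome[[m$contig[i]]],
                                         start = m$start0[i] + 1L,
                                         end = m$end0[i]))
    out[i] <- if (m$strand[i] == "-") revcomp_chr(s) else s
  }
  names(out) <- m$id
  out
}
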