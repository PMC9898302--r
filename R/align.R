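#' Read trimming configuration
#'
#' Mirrors the common small-RNA preprocessing contract: 3' adapter removal at
#' the best (leftmost, longest) exact match with a minimum 3-nt overlap,
#' followed by 3' quality trimming at Q20, followed by a 15-28 nt length
#' gate.
#'
#' @param adapter 3' adapter sequence ("" disables adapter trimming).
#' @param quality_cutoff Phred cutoff for 3' quality trimming.
#' @param quality_base Phred offset (33).
#' @param min_len,max_len length gate applied after trimming.
#' @param min_adapter_overlap minimum adapter/read 3' overlap.
#' @return a `trim_config` list.
#' @export
trim_config <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                        quality_cutoff = 20L, quality_base = 33L,
                        min_len = 15L, max_len = 28L,
                        min_adapter_overlap = 3L) {
  if (min_len <= 0L || min_len > max_len)
    stopf("require 0 < min_len <= max_len")
  if (quality_cutoff < 0L) stopf("quality_cutoff must be >= 0")
  structure(list(adapter = toupper(adapter),
                 quality_cutoff = as.integer(quality_cutoff),
                 quality_base = as.integer(quality_base),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_adapter_overlap = as.integer(min_adapter_overlap)),
            class = "trim_config")
}

# 3' quality trim: BWA/cutadapt partial-sum algorithm. Returns the number of
# bases to keep.
quality_keep_len <- function(qualstr, cutoff) {
  n <- nchar(qualstr)
  if (n == 0L) return(0L)
  qs <- phred_ints(qualstr)
  v <- rev(cumsum(rev(cutoff - qs)))  # v[i] = sum_{j>=i} (cutoff - q_j)
  i <- which.max(v)
  if (v[i] > 0) i - 1L else n
}

#' Trim small-RNA reads
#'
#' Adapter trimming precedes quality trimming; surviving reads keep their
#' input order. The report's per-reason counts sum to the input count.
#'
#' @param fastq_in FASTQ path, or a data.table/data.frame with `seq` and
#'   `qual` columns (optionally `id`, `count`).
#' @param config a [trim_config()].
#' @return list with `reads` (trimmed survivors, same columns as input) and
#'   `report` (data.table of `reason` in kept/too_short/too_long and
#'   `count`).
#' @export
trim_reads <- function(fastq_in, config = trim_config()) {
  reads <- if (is.character(fastq_in) && length(fastq_in) == 1L)
    read_fastq(fastq_in) else as.data.table(fastq_in)
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  if (nrow(reads) && any(nchar(reads$seq) != nchar(reads$qual)))
    stopf("malformed FASTQ record at index %d: sequence/quality length mismatch",
          which(nchar(reads$seq) != nchar(reads$qual))[1])
  n <- nrow(reads)
  if (n == 0L)
    return(list(reads = reads,
                report = data.table(reason = "kept", count = 0L)))
  seq <- toupper(reads$seq); qual <- reads$qual
  len <- nchar(seq)

  # ---- adapter removal (exact, leftmost-longest, >= min_overlap) ----
  keep <- len
  ad <- config$adapter
  if (nzchar(ad)) {
    alen <- nchar(ad)
    hit <- regexpr(ad, seq, fixed = TRUE)     # full adapter anywhere
    found <- hit > 0L
    keep[found] <- hit[found] - 1L
    for (k in seq(alen - 1L, config$min_adapter_overlap)) {
      cand <- which(!found & len >= k)
      if (!length(cand)) next
      at <- len[cand] - k + 1L
      ok <- substr(seq[cand], at, len[cand]) == substr(ad, 1L, k)
      idx <- cand[ok]
      keep[idx] <- at[ok] - 1L
      found[idx] <- TRUE
    }
  }
  seq <- substr(seq, 1L, keep); qual <- substr(qual, 1L, keep)

  # ---- 3' quality trimming (deduplicated per distinct quality string) ----
  uq <- unique(qual)
  cutlen <- vapply(uq, quality_keep_len, integer(1),
                   cutoff = config$quality_cutoff)
  keep2 <- cutlen[match(qual, uq)]
  seq <- substr(seq, 1L, keep2); qual <- substr(qual, 1L, keep2)

  out_len <- nchar(seq)
  reason <- ifelse(out_len < config$min_len, "too_short",
            ifelse(out_len > config$max_len, "too_long", "kept"))
  w <- if ("count" %in% names(reads)) reads$count else rep(1L, n)
  report <- data.table(
    reason = factor(reason, levels = c("kept", "too_short", "too_long")),
    count = w)[, .(count = sum(count)), by = reason]
  report <- report[CJ(reason = factor(levels(report$reason),
                                      levels = levels(report$reason))),
                   on = "reason"]
  report[is.na(count), count := 0L]
  report[, reason := as.character(reason)]
  keep_idx <- which(reason == "kept")
  kept <- copy(reads[keep_idx])
  trimmed_seq <- seq[keep_idx]; trimmed_qual <- qual[keep_idx]
  kept[, `:=`(seq = trimmed_seq, qual = trimmed_qual)]
  list(reads = kept, report = report[])
}

#' Mapper configuration
#'
#' The mapper is ungapped, ignores the final `trim3` bases of each read, and
#' reports a read only when its best mismatch stratum (0, then 1) contains
#' exactly one location across both strands of the whole reference
#' ("no cross mapping"). The quality-sum ceiling of the emulated aligner is
#' not reproduced; mismatch count alone gates alignment.
#'
#' @param max_mismatches 0 or 1.
#' @param trim3 number of 3' bases ignored for alignment (soft-clipped in
#'   SAM output).
#' @return a `map_config` list.
#' @export
map_config <- function(max_mismatches = 1L, trim3 = 2L) {
  if (!max_mismatches %in% c(0L, 1L)) stopf("max_mismatches must be 0 or 1")
  if (trim3 < 0L) stopf("trim3 must be >= 0")
  structure(list(max_mismatches = as.integer(max_mismatches),
                 trim3 = as.integer(trim3)), class = "map_config")
}

# map a vector of unique core sequences against the reference; returns a
# data.table keyed by core with contig/start0/strand/nm/mapped/reason.
#
# Bulk strategy: group patterns by width and search with PDict. With at most
# one mismatch allowed, any hit matches one half of the pattern exactly, so
# two trusted-band passes (exact left half / exact right half) enumerate all
# candidate locations; exact mismatch counts are then recomputed per
# candidate.
map_unique_cores <- function(cores, subjects, config) {
  contigs <- names(subjects)
  contig_chr <- vapply(subjects, as.character, character(1))
  n <- length(cores)
  if (!n) return(data.table(core = character(0), contig = character(0),
                            start0 = integer(0), strand = character(0),
                            nm = integer(0), mapped = logical(0),
                            reason = character(0)))
  widths <- nchar(cores)
  hit_list <- list()
  collect <- function(midx, pat_global_idx, cg, st) {
    starts <- BiocGenerics::start(BiocGenerics::unlist(midx))
    if (!length(starts)) return(NULL)
    reps <- S4Vectors::elementNROWS(midx)
    data.table(pat = rep(pat_global_idx, reps), contig = cg,
               start0 = starts - 1L, strand = st)
  }
  for (w in unique(widths)) {
    idx <- which(widths == w)
    for (st in c("+", "-")) {
      pats <- if (st == "+") cores[idx] else revcomp_chr(cores[idx])
      pset <- Biostrings::DNAStringSet(pats)
      pds <- if (config$max_mismatches == 0L) list(Biostrings::PDict(pset))
      else {
        h <- w %/% 2L
        list(Biostrings::PDict(pset, tb.start = 1L, tb.end = h),
             Biostrings::PDict(pset, tb.start = h + 1L, tb.end = w))
      }
      for (cg in contigs) for (pd in pds) {
        m <- Biostrings::matchPDict(pd, subjects[[cg]],
                                    max.mismatch = config$max_mismatches)
        h <- collect(m, idx, cg, st)
        if (!is.null(h)) hit_list[[length(hit_list) + 1L]] <- h
      }
    }
  }
  hits <- if (length(hit_list)) unique(rbindlist(hit_list)) else NULL
  out <- data.table(core = cores, contig = NA_character_,
                    start0 = NA_integer_, strand = NA_character_,
                    nm = NA_integer_, mapped = FALSE,
                    reason = "no_alignment")
  if (!is.null(hits) && nrow(hits)) {
    w <- widths[hits$pat]
    refseq <- substr(contig_chr[hits$contig], hits$start0 + 1L,
                     hits$start0 + w)
    patseq <- ifelse(hits$strand == "+", cores[hits$pat],
                     revcomp_chr(cores[hits$pat]))
    hits[, nm := vapply(seq_len(.N), function(i)
      sum(charToRaw(refseq[i]) != charToRaw(patseq[i])), integer(1))]
    hits <- hits[nm <= config$max_mismatches]
    best <- hits[, .(best = min(nm), nbest = sum(nm == min(nm))), by = pat]
    uniq <- best[nbest == 1L]
    multi <- best[nbest > 1L]
    if (nrow(uniq)) {
      hb <- hits[uniq, on = c("pat", nm = "best")]
      out[hb$pat, `:=`(contig = hb$contig, start0 = hb$start0,
                       strand = hb$strand, nm = hb$nm, mapped = TRUE,
                       reason = NA_character_)]
    }
    if (nrow(multi))
      out[multi$pat, reason := "multimapper"]
  }
  out
}

#' Map trimmed reads to the reference
#'
#' @param reads trimmed reads: FASTQ path, data.table with `seq` (and
#'   optionally `id`, `qual`, `count`), or a character vector of sequences.
#' @param reference a named `DNAStringSet`, a [make_reference()] bundle, or a
#'   FASTA path.
#' @param config a [map_config()].
#' @return data.table of alignment records: `id`, `seq` (full read, as
#'   given), `qual`, `count`, `contig`, `start0` (0-based, reference-forward
#'   start of the aligned core), `strand`, `core_fwd` (aligned bases in
#'   reference-forward orientation), `clip3` (ignored 3' bases), `nm`,
#'   `mapped`, `reason` (NA, "multimapper" or "no_alignment").
#' @export
map_reads <- function(reads, reference, config = map_config()) {
  if (is.character(reads) && is.null(dim(reads))) {
    reads <- if (length(reads) == 1L && file.exists(reads)) read_fastq(reads)
             else data.table(seq = reads)
  } else reads <- copy(as.data.table(reads))
  if (!"id" %in% names(reads)) reads[, id := sprintf("read_%d", .I)]
  if (!"qual" %in% names(reads)) reads[, qual := strrep("I", nchar(seq))]
  if (!"count" %in% names(reads)) reads[, count := 1L]
  reference <- resolve_reference(reference)
  if (length(reference) == 0L || sum(Biostrings::width(reference)) == 0L)
    stopf("empty reference")
  subjects <- lapply(as.character(reference), Biostrings::DNAString)

  reads[, core := substr(toupper(seq), 1L,
                         pmax(nchar(seq) - config$trim3, 0L))]
  reads[, clip3 := substr(toupper(seq), nchar(core) + 1L, nchar(seq))]
  um <- map_unique_cores(unique(reads$core), subjects, config)
  out <- um[reads, on = "core"]
  out[strand == "-", core_fwd := revcomp_chr(core)]
  out[strand == "+" | is.na(strand), core_fwd := core]
  out[, .(id, seq, qual, count, contig, start0, strand, core_fwd, clip3,
          nm, mapped, reason)]
}

resolve_reference <- function(reference) {
  if (is(reference, "mir_reference")) return(reference$genome)
  if (is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    x <- Biostrings::readDNAStringSet(reference)
    names(x) <- sub("\\s.*", "", names(x))
    return(x)
  }
  if (is.character(reference)) return(Biostrings::DNAStringSet(reference))
  stopf("cannot interpret reference")
}

#' Write alignment records as SAM
#'
#' Mapped records carry the `NM` tag; the ignored 3' bases appear as soft
#' clips. Unmapped and suppressed reads are emitted with the unmapped flag
#' and an `XR:Z:` reason tag.
#'
#' @param alignments a [map_reads()] record table.
#' @param reference the reference used (for `@SQ` headers).
#' @param path output SAM path.
#' @export
write_sam <- function(alignments, reference, path) {
  reference <- resolve_reference(reference)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   Biostrings::width(reference)),
           "@PG\tID:mirED\tPN:mirED")
  a <- as.data.table(alignments)
  if ("count" %in% names(a) && any(a$count > 1L))
    a <- a[rep(seq_len(nrow(a)), a$count)][
      , id := sprintf("%s_d%d", id, seq_len(.N)), by = id]
  lines <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    r <- a[i]
    if (isTRUE(r$mapped)) {
      w <- nchar(r$core_fwd); cl <- nchar(r$clip3)
      if (r$strand == "+") {
        flag <- 0L; seqout <- paste0(r$core_fwd, r$clip3)
        cig <- paste0(w, "M", if (cl) paste0(cl, "S"))
        qout <- r$qual
      } else {
        flag <- 16L; seqout <- paste0(revcomp_chr(r$clip3), r$core_fwd)
        cig <- paste0(if (cl) paste0(cl, "S"), w, "M")
        qout <- paste(rev(strsplit(r$qual, "")[[1]]), collapse = "")
      }
      lines[i] <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                          r$id, flag, r$contig, r$start0 + 1L, cig,
                          seqout, qout, r$nm)
    } else {
      lines[i] <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s\tXR:Z:%s",
                          r$id, toupper(r$seq), r$qual, r$reason)
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}

#' Read a SAM file into alignment records
#'
#' Secondary and supplementary records are dropped; soft-clipped bases are
#' excluded from the aligned core (and hence from pileup evidence). Only
#' ungapped CIGARs (M/=/X with optional soft/hard clips) are supported.
#'
#' @param path SAM file with `@SQ` headers.
#' @param annotation optional [mir_annotation()]; contigs in the SAM body
#'   must appear in the annotation.
#' @return alignment record table in the [map_reads()] layout.
#' @export
read_sam <- function(path, annotation = NULL) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq",
             "qual"),
    tag = "NM")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- bitwAnd(b$flag, 0x100L) == 0L & bitwAnd(b$flag, 0x800L) == 0L
  n <- sum(keep)
  dt <- data.table(id = b$qname[keep], flag = b$flag[keep],
                   contig = as.character(b$rname[keep]),
                   pos = b$pos[keep], cigar = b$cigar[keep],
                   seq = as.character(b$seq[keep]),
                   qual = as.character(b$qual[keep]),
                   nm = if (!is.null(b$tag$NM)) as.integer(b$tag$NM[keep])
                        else rep(NA_integer_, n))
  dt[, mapped := bitwAnd(flag, 0x4L) == 0L]
  if (!is.null(annotation)) {
    bad <- setdiff(unique(dt$contig[dt$mapped]), unique(annotation$contig))
    if (length(bad))
      stopf("SAM contig(s) absent from annotation: %s",
            paste(bad, collapse = ", "))
  }
  dt[, c("core_fwd", "start0", "clip3", "strand", "reason") :=
       list(NA_character_, NA_integer_, "", NA_character_, NA_character_)]
  for (i in which(dt$mapped)) {
    ops <- parse_cigar(dt$cigar[i])
    if (any(!ops$op %in% c("M", "=", "X", "S", "H")))
      stopf("unsupported CIGAR operation in record '%s': %s", dt$id[i],
            dt$cigar[i])
    s <- dt$seq[i]
    lead <- if (nrow(ops) && ops$op[1] == "S") ops$len[1] else 0L
    tail_ <- if (nrow(ops) && ops$op[nrow(ops)] == "S") ops$len[nrow(ops)]
             else 0L
    core <- substr(s, lead + 1L, nchar(s) - tail_)
    dt[i, `:=`(core_fwd = core, start0 = pos - 1L,
               strand = if (bitwAnd(flag, 0x10L)) "-" else "+")]
  }
  dt[mapped == FALSE, reason := "unmapped"]
  dt[, count := 1L]
  dt[, .(id, seq, qual, count, contig, start0, strand, core_fwd, clip3, nm,
         mapped, reason)]
}

parse_cigar <- function(cig) {
  m <- gregexpr("\\d+[A-Z=]", cig)[[1]]
  toks <- regmatches(cig, list(m))[[1]]
  data.table(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks))
}
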