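#' Run the editing-hotspot pipeline on one cohort
#'
#' Trims every sample's reads, maps them (a shared cache maps each distinct
#' sequence once across the cohort), piles them up strand-aware (outside
#' positions retained so the annotation filter can flag them), calls and
#' filters editing sites per sample, quantifies mature-miRNA TPM, assembles
#' the cohort editing matrix and applies the requested candidate-selection
#' rule. Every site that was significant anywhere is accounted for in the
#' run log with the single filter that removed it (or an empty string for
#' surviving candidates).
#'
#' @param bundle a [make_reference()] bundle.
#' @param reads a `sim_reads` object from [simulate_reads()], or a named
#'   character vector of FASTQ paths (names = sample ids).
#' @param samples sample sheet (required when `reads` are FASTQ paths).
#' @param rule candidate-selection rule, `"catholic"` (stage trend) or
#'   `"tcga"` (tumor vs normal).
#' @param config a [call_config()].
#' @param trim a [trim_config()] (defaults to the design adapter when reads
#'   come from the simulator).
#' @param map a [map_config()].
#' @param delta,alpha stage-trend rise floor and two-group alpha.
#' @param library_size notional per-sample library size for the TPM
#'   denominator (defaults to the simulator design's; 0 disables the
#'   background).
#' @return list with `candidates`, `matrix` (the [cohort_editing_matrix()]),
#'   `log` (site_id, mirna_id, mature_position, removed_by), `trim_reports`.
#' @export
run_editing_pipeline <- function(bundle, reads, samples = NULL,
                                 rule = c("catholic", "tcga"),
                                 config = call_config(), trim = NULL,
                                 map = map_config(), delta = 0.01,
                                 alpha = 0.05, library_size = NULL) {
  rule <- match.arg(rule)
  if (is(reads, "sim_reads")) {
    samples <- reads$samples
    if (is.null(trim)) trim <- trim_config(adapter = reads$design$adapter)
    if (is.null(library_size)) library_size <- reads$design$library_size
    read_tabs <- reads$reads
  } else {
    stopifnot(!is.null(samples), !is.null(names(reads)))
    if (is.null(trim)) trim <- trim_config()
    if (is.null(library_size)) library_size <- 0
    read_tabs <- lapply(reads, read_fastq)
  }
  stopifnot(all(samples$sample_id %in% names(read_tabs)))

  trimmed <- list(); trim_reports <- list()
  for (s in samples$sample_id) {
    tr <- trim_reads(read_tabs[[s]], trim)
    trimmed[[s]] <- tr$reads
    trim_reports[[s]] <- tr$report
  }

  # one shared mapping pass over every distinct trimmed sequence
  all_seqs <- unique(unlist(lapply(trimmed, function(t)
    if (nrow(t)) toupper(t$seq) else character(0))))
  subjects <- lapply(as.character(bundle$genome), Biostrings::DNAString)
  seq_dt <- data.table(seq = all_seqs)
  seq_dt[, core := substr(seq, 1L, pmax(nchar(seq) - map$trim3, 0L))]
  seq_dt[, clip3 := substr(seq, nchar(core) + 1L, nchar(seq))]
  um <- map_unique_cores(unique(seq_dt$core), subjects, map)
  seq_aln <- um[seq_dt, on = "core"]
  seq_aln[strand == "-", core_fwd := revcomp_chr(core)]
  seq_aln[strand == "+" | is.na(strand), core_fwd := core]

  per_sample_sites <- list(); per_sample_tpm <- list()
  for (s in samples$sample_id) {
    t <- trimmed[[s]]
    if (!"count" %in% names(t)) t[, count := 1L]
    aln <- seq_aln[data.table(seq = toupper(t$seq), count = t$count),
                   on = "seq"]
    pu <- pileup(aln, bundle$annotation, bundle$genome, restrict = FALSE)
    called <- call_editing_sites(pu, config)
    flagged <- filter_sites(called, bundle$annotation, bundle$variants)
    per_sample_sites[[s]] <- flagged$sites
    mapped_total <- sum(aln$count[aln$mapped], na.rm = TRUE)
    per_sample_tpm[[s]] <- quantify_expression(
      aln, bundle$annotation,
      background_reads = max(library_size - mapped_total, 0))
  }

  cm <- cohort_editing_matrix(per_sample_sites, per_sample_tpm, samples)
  sel <- select_candidates(cm, rule = rule, config = config, delta = delta,
                           alpha = alpha)

  # unified run log over every site significant in >= 1 sample
  all_sites <- rbindlist(per_sample_sites, idcol = "sample_id")
  all_sites[, site_id := paste0(contig, ":", pos0 + 1L)]
  sig <- all_sites[significant == TRUE]
  log <- unique(sig[, .(site_id, contig, pos0, mirna_id, mature_id,
                        mature_position, in_seed,
                        filter_flags)])[order(contig, pos0)]
  log[, removed_by := ifelse(filter_flags != "",
                             sub(",.*", "", filter_flags), "")]
  sel_log <- setNames(sel$log$removed_by, sel$log$site_id)
  open <- log$removed_by == "" & log$site_id %in% names(sel_log)
  log[open, removed_by := sel_log[site_id]]
  log[, filter_flags := NULL]

  list(candidates = sel$candidates, matrix = cm, log = log,
       trim_reports = trim_reports)
}
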