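#' Editing-call configuration
#'
#' @param alpha_bonferroni family-wise significance level on the
#'   Bonferroni-adjusted p-value.
#' @param min_coverage minimum per-site coverage for testing.
#' @param error_rate per-base substitution error probability, or `"auto"` to
#'   pool it from the pileup with [estimate_error_rate()].
#' @param min_mean_editing cohort mean editing-level floor (0.05 = 5%).
#' @param min_tpm host-miRNA mean TPM floor for the mean-and-TPM cohort rule.
#' @param min_samples_at_threshold minimum number of samples at or above
#'   `min_mean_editing` for the n-samples cohort rule.
#' @return a `call_config` list.
#' @export
call_config <- function(alpha_bonferroni = 0.1, min_coverage = 10L,
                        error_rate = "auto", min_mean_editing = 0.05,
                        min_tpm = 1.0, min_samples_at_threshold = 10L) {
  stopifnot(alpha_bonferroni >= 0, alpha_bonferroni <= 1, min_coverage >= 1)
  if (is.numeric(error_rate) && (error_rate < 0 || error_rate > 1))
    stopf("error_rate must lie in [0, 1]")
  structure(list(alpha_bonferroni = alpha_bonferroni,
                 min_coverage = as.integer(min_coverage),
                 error_rate = error_rate,
                 min_mean_editing = min_mean_editing,
                 min_tpm = min_tpm,
                 min_samples_at_threshold = as.integer(min_samples_at_threshold)),
            class = "call_config")
}

#' Strand-aware per-site pileup over annotated pre-miRNAs
#'
#' Bases are complemented into miRNA-strand space for minus-strand
#' pre-miRNAs, so the A-to-I editing signature always reads A-to-G. Counts
#' are weighted by the `count` column of the alignment records.
#'
#' @param alignments alignment records from [map_reads()] or [read_sam()].
#' @param annotation a [mir_annotation()] table.
#' @param genome named `DNAStringSet` (reference bases).
#' @param restrict drop positions outside any pre-miRNA (the default); with
#'   `FALSE`, outside positions are emitted with `mirna_id = NA` so that the
#'   site filter can flag them.
#' @return data.table with `contig`, `pos0`, `ref_base` (miRNA strand),
#'   `A`/`C`/`G`/`T` (miRNA-strand counts), `coverage`, `mirna_id`,
#'   `mature_id`, `mature_position`, `in_seed`, `mito`, `strand`.
#' @export
pileup <- function(alignments, annotation, genome, restrict = TRUE) {
  a <- as.data.table(alignments)[mapped == TRUE]
  bad <- setdiff(unique(a$contig), names(genome))
  if (length(bad))
    stopf("alignment on unknown contig(s): %s", paste(bad, collapse = ", "))
  if (!"count" %in% names(a)) a[, count := 1L]
  if (!nrow(a)) return(empty_pileup())
  a[, w := nchar(core_fwd)]
  long <- a[, {
    chars <- do.call(rbind, strsplit(core_fwd, "", fixed = TRUE))
    W <- w[1]
    list(contig = rep(contig, W),
         pos0 = as.integer(outer(start0, 0:(W - 1L), `+`)),
         base = as.vector(chars),
         n = rep(count, W))
  }, by = w][, w := NULL]
  tal <- long[base %in% DNA_BASES,
              .(n = sum(n)), by = .(contig, pos0, base)]
  wide <- dcast(tal, contig + pos0 ~ base, value.var = "n", fill = 0L)
  for (b in DNA_BASES) if (!b %in% names(wide)) wide[, (b) := 0L]
  # reference (forward-strand) base
  wide[, ref_fwd := {
    s <- as.character(genome[[contig[1]]])
    substr(rep(s, .N), pos0 + 1L, pos0 + 1L)
  }, by = contig]

  # assign covering pre-miRNA / mature features
  pre <- premirnas(annotation); mat <- matures(annotation)
  wide[, `:=`(mirna_id = NA_character_, strand = "+", mito = FALSE,
              mature_id = NA_character_, mature_position = NA_integer_)]
  for (i in seq_len(nrow(pre))) {
    idx <- wide$contig == pre$contig[i] & wide$pos0 >= pre$start0[i] &
      wide$pos0 < pre$end0[i]
    wide[idx, `:=`(mirna_id = pre$id[i], strand = pre$strand[i],
                   mito = pre$mito[i])]
  }
  for (i in seq_len(nrow(mat))) {
    idx <- wide$contig == mat$contig[i] & wide$pos0 >= mat$start0[i] &
      wide$pos0 < mat$end0[i]
    wide[idx, mature_id := mat$id[i]]
    wide[idx, mature_position := feature_position(pos0, mat$start0[i],
                                                  mat$end0[i], mat$strand[i])]
  }
  if (restrict) wide <- wide[!is.na(mirna_id)]
  # orient into miRNA-strand space
  minus <- wide$strand == "-"
  wide[, ref_base := ref_fwd]
  wide[minus, ref_base := complement_chr(ref_fwd)]
  if (any(minus)) {
    tmp <- wide[minus, .(A, C, G, T)]
    wide[minus, `:=`(A = tmp$T, C = tmp$G, G = tmp$C, T = tmp$A)]
  }
  wide[, coverage := A + C + G + T]
  wide[, in_seed := !is.na(mature_position) & mature_position >= 2L &
         mature_position <= 8L]
  setorder(wide, contig, pos0)
  wide[, .(contig, pos0, ref_base, A, C, G, T, coverage, mirna_id,
           mature_id, mature_position, in_seed, mito, strand)]
}

empty_pileup <- function() {
  data.table(contig = character(0), pos0 = integer(0),
             ref_base = character(0), A = integer(0), C = integer(0),
             G = integer(0), T = integer(0), coverage = integer(0),
             mirna_id = character(0), mature_id = character(0),
             mature_position = integer(0), in_seed = logical(0),
             mito = logical(0), strand = character(0))
}

#' Estimate the sequencing error rate from a pileup
#'
#' Pools mismatches that cannot be A-to-I editing: all mismatches at C/G/T
#' reference sites plus A-to-C and A-to-T at A sites; A-to-G reads are
#' excluded from both numerator and denominator. The estimate is floored at
#' 1e-6.
#'
#' @param pileups a [pileup()] table.
#' @param min_coverage sites below this coverage are ignored.
#' @param floor lower bound of the returned rate.
#' @return the pooled per-base error probability.
#' @export
estimate_error_rate <- function(pileups, min_coverage = 10L, floor = 1e-6) {
  p <- as.data.table(pileups)[coverage >= min_coverage &
                                ref_base %in% DNA_BASES]
  if (!nrow(p))
    stopf(paste("no site with coverage >= %d; set error_rate explicitly in",
                "call_config()"), min_coverage)
  is_a <- p$ref_base == "A"
  match_n <- mapply(function(rb, a, c, g, t) switch(rb, A = a, C = c, G = g,
                                                    T = t),
                    p$ref_base, p$A, p$C, p$G, p$T)
  mism <- p$coverage - match_n
  mism[is_a] <- p$C[is_a] + p$T[is_a]          # exclude the A->G signature
  denom <- p$coverage
  denom[is_a] <- p$coverage[is_a] - p$G[is_a]
  max(sum(mism) / sum(denom), floor)
}

#' Call candidate A-to-G editing sites
#'
#' For every A-reference site at or above the coverage floor, the editing
#' level is G/(A+G) and the raw p-value is the exact binomial upper tail of
#' observing at least G successes in A+G trials when each base is miscalled
#' A-to-G with probability `error_rate / 3` (uniform substitution spectrum).
#' The Bonferroni family is the number of sites tested in this pileup (one
#' sample).
#'
#' @param pileups a [pileup()] table for one sample.
#' @param config a [call_config()].
#' @return data.table of editing sites with `editing_level`, `p_raw`,
#'   `p_bonferroni`, `n_tests`, `significant`, and an empty `filter_flags`
#'   column to be populated by [filter_sites()].
#' @export
call_editing_sites <- function(pileups, config = call_config()) {
  p <- as.data.table(pileups)
  er <- config$error_rate
  if (identical(er, "auto"))
    er <- estimate_error_rate(p, min_coverage = config$min_coverage)
  sites <- p[ref_base == "A" & coverage >= config$min_coverage & A + G > 0L]
  n_tests <- nrow(sites)
  if (!n_tests) {
    out <- cbind(empty_pileup(),
                 data.table(editing_level = numeric(0), p_raw = numeric(0),
                            p_bonferroni = numeric(0), n_tests = integer(0),
                            significant = logical(0),
                            filter_flags = character(0)))
    return(out)
  }
  sites[, editing_level := G / (A + G)]
  sites[, p_raw := pbinom(G - 1L, A + G, er / 3, lower.tail = FALSE)]
  sites[, p_bonferroni := pmin(1, p_raw * n_tests)]
  sites[, n_tests := n_tests]
  sites[, significant := p_bonferroni <= config$alpha_bonferroni]
  sites[, filter_flags := ""]
  sites[]
}

#' Flag and remove sites failing the annotation and known-variant filters
#'
#' A site is dropped iff it lies outside any pre-miRNA, on a mitochondrial
#' contig, or overlaps any known-variant record by position (the alternate
#' allele is irrelevant: any recorded variation disqualifies the site).
#'
#' @param sites a [call_editing_sites()] table.
#' @param annotation a [mir_annotation()] table.
#' @param known_variants a variant table from [read_variants_vcf()] (or a VCF
#'   path).
#' @return list with `sites` (all sites, `filter_flags` populated) and
#'   `retained` (surviving sites, empty flag sets).
#' @export
filter_sites <- function(sites, annotation, known_variants) {
  if (is.character(known_variants))
    known_variants <- read_variants_vcf(known_variants)
  v <- as.data.table(known_variants)
  s <- copy(as.data.table(sites))
  flags <- vector("list", nrow(s))
  mito_contigs <- unique(annotation$contig[annotation$mito])
  for (i in seq_len(nrow(s))) {
    f <- character(0)
    if (is.na(s$mirna_id[i])) f <- c(f, "NOT_PREMIRNA")
    if (s$contig[i] %in% mito_contigs || isTRUE(s$mito[i]))
      f <- c(f, "MITOCHONDRIAL")
    if (nrow(v) && any(v$contig == s$contig[i] & v$pos0 == s$pos0[i]))
      f <- c(f, "KNOWN_SNP")
    flags[[i]] <- f
  }
  s[, filter_flags := vapply(flags, paste, character(1), collapse = ",")]
  list(sites = s, retained = s[filter_flags == ""])
}

#' Quantify mature miRNA expression as TPM
#'
#' A read counts toward a mature miRNA when its alignment midpoint lies in
#' the mature interval. TPM is the length-normalized rate scaled to one
#' million; with `background_reads = 0` the TPMs of the annotated miRNAs sum
#' to 1e6. When the reference covers only a slice of the miRNome (as in the
#' simulator), `background_reads` declares the unobserved remainder of the
#' library so TPM is on the realistic scale.
#'
#' @param alignments alignment records.
#' @param annotation a [mir_annotation()] table.
#' @param background_reads notional reads outside the annotated set.
#' @param background_mean_length mean length of those reads (nt).
#' @return data.table with `mirna_id` (mature id), `count`, `length`, `tpm`.
#' @export
quantify_expression <- function(alignments, annotation, background_reads = 0,
                                background_mean_length = 22) {
  a <- as.data.table(alignments)[mapped == TRUE]
  if (!"count" %in% names(a)) a[, count := 1L]
  mat <- matures(annotation)
  counts <- numeric(nrow(mat))
  if (nrow(a)) {
    mid <- a$start0 + nchar(a$core_fwd) %/% 2L
    for (i in seq_len(nrow(mat))) {
      idx <- a$contig == mat$contig[i] & mid >= mat$start0[i] &
        mid < mat$end0[i]
      counts[i] <- sum(a$count[idx])
    }
  }
  len <- mat$end0 - mat$start0
  rate <- counts / (len / 1000)
  bg_rate <- background_reads / (background_mean_length / 1000)
  total <- sum(rate) + bg_rate
  if (total == 0) {
    warnf("zero total counts; all TPM values are 0")
    tpm <- rep(0, nrow(mat))
  } else tpm <- rate / total * 1e6
  data.table(mirna_id = mat$id, count = counts, length = len, tpm = tpm)
}

#' Assemble a cohort editing matrix
#'
#' A site enters the matrix if it is Bonferroni-significant and unflagged in
#' at least one sample; its editing level in every sample where it was
#' testable (coverage at or above the floor) fills the matrix, with `NA`
#' elsewhere.
#'
#' @param per_sample_sites named list (by sample) of [filter_sites()]
#'   results' `sites` tables.
#' @param per_sample_tpm named list of [quantify_expression()] tables.
#' @param samples sample sheet (`sample_id`, `stage` factor, `group`).
#' @return a `cohort_matrix`: `sites` (site info with `site_id`), `editing`
#'   (sites x samples), `tpm` (mature miRNAs x samples), `samples`,
#'   `stages`.
#' @export
cohort_editing_matrix <- function(per_sample_sites, per_sample_tpm, samples) {
  stopifnot(all(samples$sample_id %in% names(per_sample_sites)))
  all_sites <- rbindlist(lapply(names(per_sample_sites), function(s)
    cbind(per_sample_sites[[s]], sample_id = s)), fill = TRUE)
  all_sites[, site_id := paste0(contig, ":", pos0 + 1L)]
  cand <- all_sites[significant == TRUE & filter_flags == "",
                    unique(site_id)]
  info <- unique(all_sites[site_id %in% cand,
                           .(site_id, contig, pos0, mirna_id, mature_id,
                             mature_position, in_seed, mito)])
  setorder(info, contig, pos0)
  editing <- matrix(NA_real_, nrow(info), nrow(samples),
                    dimnames = list(info$site_id, samples$sample_id))
  for (s in samples$sample_id) {
    t <- all_sites[sample_id == s & site_id %in% info$site_id]
    editing[t$site_id, s] <- t$editing_level
  }
  mirnas <- sort(unique(unlist(lapply(per_sample_tpm, `[[`, "mirna_id"))))
  tpm <- matrix(NA_real_, length(mirnas), nrow(samples),
                dimnames = list(mirnas, samples$sample_id))
  for (s in samples$sample_id) {
    t <- per_sample_tpm[[s]]
    tpm[t$mirna_id, s] <- t$tpm
  }
  structure(list(sites = info, editing = editing, tpm = tpm,
                 samples = as.data.table(samples),
                 stages = levels(samples$stage)),
            class = "cohort_matrix")
}

#' Apply a cohort-level retention rule
#'
#' `MEAN_AND_TPM` keeps sites whose mean editing level across covered samples
#' is at least `min_mean_editing` and whose host mature miRNA has mean TPM at
#' least `min_tpm`. `N_SAMPLES` keeps sites with editing at or above
#' `min_mean_editing` in at least `min_samples_at_threshold` samples.
#'
#' @param matrix a [cohort_editing_matrix()].
#' @param rule `"MEAN_AND_TPM"` or `"N_SAMPLES"`.
#' @param config a [call_config()].
#' @return list with `retained` (site ids) and `detail` (per-site pass
#'   diagnostics with a `reason` for dropped sites).
#' @export
apply_cohort_filters <- function(matrix, rule = c("MEAN_AND_TPM", "N_SAMPLES"),
                                 config = call_config()) {
  rule <- match.arg(rule)
  info <- matrix$sites
  if (!nrow(info))
    return(list(retained = character(0),
                detail = data.table(site_id = character(0),
                                    reason = character(0))))
  mean_ed <- rowMeans(matrix$editing, na.rm = TRUE)
  if (rule == "MEAN_AND_TPM") {
    host_tpm <- vapply(info$mature_id, function(m) {
      if (is.na(m) || !m %in% rownames(matrix$tpm)) return(NA_real_)
      mean(matrix$tpm[m, ], na.rm = TRUE)
    }, numeric(1))
    pass_ed <- mean_ed >= config$min_mean_editing
    pass_tpm <- !is.na(host_tpm) & host_tpm >= config$min_tpm
    detail <- data.table(site_id = info$site_id, mean_editing = mean_ed,
                         host_mean_tpm = host_tpm,
                         reason = ifelse(!pass_ed, "LOW_MEAN_EDITING",
                                  ifelse(!pass_tpm, "LOW_TPM", "")))
  } else {
    n_at <- rowSums(matrix$editing >= config$min_mean_editing, na.rm = TRUE)
    pass <- n_at >= config$min_samples_at_threshold
    detail <- data.table(site_id = info$site_id, n_samples_at_threshold = n_at,
                         reason = ifelse(!pass, "TOO_FEW_SAMPLES", ""))
  }
  list(retained = detail[reason == "", site_id], detail = detail)
}
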