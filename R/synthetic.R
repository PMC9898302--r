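#' Cohort simulation design
#'
#' Describes the synthetic small-RNA study: the ordered disease stages, the
#' number of samples per stage, sequencing depth and error rate, the library
#' layout (3' adapter, machine read length, optional low-quality tail) and the
#' notional total library size used as the TPM denominator (the simulated
#' reference covers only a tiny slice of the miRNome, so TPM is computed
#' against a declared library size rather than the handful of simulated
#' miRNAs).
#'
#' @param stages ordered character vector of stage labels (first label is the
#'   "normal" group, last is the "tumor" group for two-group contrasts).
#' @param samples_per_stage samples simulated per stage (>= 1).
#' @param depth_per_mirna mean read count per expressed mature miRNA (Poisson).
#' @param error_rate per-base substitution error probability in \[0, 0.1\].
#' @param rng_seed integer seed; all randomness in the simulators derives from
#'   it.
#' @param adapter 3' adapter ligated after the insert ("" disables adapter
#'   simulation and emits bare inserts).
#' @param read_length machine read length; raw reads are insert + adapter
#'   truncated to this length (ignored when `adapter == ""`).
#' @param low_q_tail number of 3' bases emitted at Q10 instead of Q30, to
#'   exercise quality trimming.
#' @param library_size notional total small-RNA library size per sample
#'   (reads), used as the TPM denominator background.
#' @return a `sim_design` list.
#' @export
sim_design <- function(stages = c("NORMAL", "CH", "CIRRHOSIS", "DN", "HCC"),
                       samples_per_stage = 8L,
                       depth_per_mirna = 5000,
                       error_rate = 0.01,
                       rng_seed = 1L,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 36L,
                       low_q_tail = 0L,
                       library_size = 5e6) {
  stages <- as.character(stages)
  if (length(stages) < 1L || anyDuplicated(stages))
    stopf("stages must be a non-empty ordered vector of unique labels")
  if (samples_per_stage < 1L) stopf("samples_per_stage must be >= 1")
  if (error_rate < 0 || error_rate > 0.1)
    stopf("error_rate must lie in [0, 0.1]")
  structure(list(stages = stages,
                 samples_per_stage = as.integer(samples_per_stage),
                 depth_per_mirna = depth_per_mirna,
                 error_rate = error_rate,
                 rng_seed = as.integer(rng_seed),
                 adapter = toupper(adapter),
                 read_length = as.integer(read_length),
                 low_q_tail = as.integer(low_q_tail),
                 library_size = library_size),
            class = "sim_design")
}

#' Planted editing event
#'
#' @param mirna_id mature miRNA id in the reference bundle.
#' @param mature_position 1-based position within the mature sequence; the
#'   reference base there must be A (validated when reads are simulated).
#' @param stage_fractions numeric vector of true editing fractions, one per
#'   stage (recycled if length 1), each in \[0, 1\].
#' @param trend if `TRUE` (a "trend" plant) the fractions must be
#'   nondecreasing along the stage order.
#' @param kind free-text label recorded in the truth table.
#' @return a `planted_edit` list.
#' @export
planted_edit <- function(mirna_id, mature_position, stage_fractions,
                         trend = TRUE, kind = "plant") {
  if (any(stage_fractions < 0 | stage_fractions > 1))
    stopf("stage_fractions must lie in [0, 1]")
  if (trend && length(stage_fractions) > 1 &&
      any(diff(stage_fractions) < 0))
    stopf("trend plant on '%s': stage fractions must be nondecreasing",
          mirna_id)
  structure(list(mirna_id = mirna_id,
                 mature_position = as.integer(mature_position),
                 stage_fractions = stage_fractions,
                 trend = trend, kind = kind),
            class = "planted_edit")
}

DECOY_KINDS <- c("SNP_SITE", "MITO_SITE", "OUTSIDE_PREMIRNA",
                 "LOW_EXPRESSION", "NON_SEED", "FLAT_TREND")

#' Decoy specification
#'
#' Each decoy violates exactly one documented pipeline filter, so that filter
#' tests are attributable: `SNP_SITE` overlaps a known-variant record,
#' `MITO_SITE` sits on the mitochondrial contig, `OUTSIDE_PREMIRNA` is a
#' mismatch site in intergenic sequence, `LOW_EXPRESSION` is hosted by a miRNA
#' whose mean TPM falls below the expression floor, `NON_SEED` lies outside
#' mature positions 2-8, and `FLAT_TREND` carries a stage-flat editing
#' fraction.
#'
#' @param kind one of `r paste(DECOY_KINDS, collapse=", ")`.
#' @param ... kind-specific placement overrides (`mirna_id`,
#'   `mature_position`, `fractions`, `expressed_samples`, `expressed_depth`).
#' @return a `decoy_spec` list.
#' @export
decoy_spec <- function(kind, ...) {
  kind <- match.arg(kind, DECOY_KINDS)
  structure(c(list(kind = kind), list(...)), class = "decoy_spec")
}

# default rising per-stage editing-fraction profile (used by trend decoys)
rising_fractions <- function(n_stages, lo = 0.02, hi = 0.25) {
  if (n_stages == 1L) return(hi)
  lo + (hi - lo) * ((seq_len(n_stages) - 1) / (n_stages - 1))^1.3
}

#' Generate a synthetic pre-miRNA reference bundle
#'
#' Builds a small genome with an autosomal contig (`chr1`) and a mitochondrial
#' contig (`chrM`), pre-miRNA hairpins of 60-110 nt each carrying one mature
#' arm of 20-24 nt, a miRBase-style GFF3 annotation, and a known-variant VCF
#' whose records overlap a declared subset of mature-arm adenosines (the
#' SNP-decoy anchor positions). At least one pre-miRNA is on the minus strand
#' and the last one is mitochondrial. Every mature arm is forced to carry an
#' adenosine at the positions in `ensure_a_at` so that seed (position 3) and
#' non-seed (position 12) edits can always be planted.
#'
#' @param n_mirnas number of pre-miRNAs (>= 1).
#' @param rng_seed integer seed; output is byte-identical for a fixed seed.
#' @param outdir if non-NULL, write `reference.fa`, `annotation.gff3` and
#'   `known_variants.vcf` there.
#' @param ensure_a_at mature positions guaranteed to hold A.
#' @return a `mir_reference` bundle: `genome` (DNAStringSet), `annotation`
#'   ([mir_annotation()]), `variants`, `mature_seqs` (sense DNA),
#'   `snp_mirnas`, `mito_mirnas`, `paths`.
#' @export
make_reference <- function(n_mirnas, rng_seed = 1L, outdir = NULL,
                           ensure_a_at = c(3L, 12L)) {
  if (!is.numeric(n_mirnas) || length(n_mirnas) != 1L || n_mirnas < 1)
    stopf("n_mirnas must be a single integer >= 1")
  n_mirnas <- as.integer(n_mirnas)
  with_rng(rng_seed, {
    strands <- sample(c("+", "-"), n_mirnas, replace = TRUE)
    strands[min(2L, n_mirnas)] <- "-"   # guarantee a minus-strand gene
    mito_idx <- n_mirnas                # last gene lives on chrM

    pre_len <- sample(60:110, n_mirnas, replace = TRUE)
    mat_len <- sample(20:24, n_mirnas, replace = TRUE)
    # mature arm offset from the hairpin 5' end (miRNA strand), keeping a
    # few flanking bases on each side
    mat_off <- vapply(seq_len(n_mirnas), function(i)
      sample.int(pre_len[i] - mat_len[i] - 10L, 1L) + 4L, integer(1))

    # hairpin sequence in miRNA-strand orientation, with forced adenosines
    pre_sense <- character(n_mirnas)
    for (i in seq_len(n_mirnas)) {
      s <- strsplit(random_dna(pre_len[i]), "", fixed = TRUE)[[1]]
      keep <- ensure_a_at[ensure_a_at <= mat_len[i]]
      s[mat_off[i] + keep] <- "A"
      pre_sense[i] <- paste(s, collapse = "")
    }

    rows <- list(); genome <- list()
    build_contig <- function(idxs, contig) {
      parts <- character(0); cursor <- 0L
      for (i in idxs) {
        gap <- random_dna(sample(100:300, 1L))
        parts <- c(parts, gap); cursor <- cursor + nchar(gap)
        gseq <- if (strands[i] == "+") pre_sense[i] else revcomp_chr(pre_sense[i])
        pre_start <- cursor; pre_end <- cursor + pre_len[i]
        if (strands[i] == "+") {
          m_start <- pre_start + mat_off[i]; m_end <- m_start + mat_len[i]
        } else {
          m_end <- pre_end - mat_off[i]; m_start <- m_end - mat_len[i]
        }
        rows[[length(rows) + 1L]] <<- data.table(
          contig = contig,
          start0 = c(pre_start, m_start), end0 = c(pre_end, m_end),
          strand = strands[i], type = c("pre_mirna", "mature"),
          id = c(sprintf("sim-mir-%d", i), sprintf("sim-miR-%d-3p", i)),
          derives_from = c(NA_character_, sprintf("sim-mir-%d", i)),
          mito = contig == "chrM")
        parts <- c(parts, gseq); cursor <- cursor + pre_len[i]
      }
      parts <- c(parts, random_dna(sample(100:300, 1L)))
      paste(parts, collapse = "")
    }
    auto_idx <- setdiff(seq_len(n_mirnas), mito_idx)
    genome$chr1 <- if (length(auto_idx)) build_contig(auto_idx, "chr1")
                   else random_dna(500L)
    genome$chrM <- build_contig(mito_idx, "chrM")

    ann <- do.call(rbind, rows)
    setattr(ann, "class", c("mir_annotation", class(data.table())))
    genome <- Biostrings::DNAStringSet(unlist(genome))

    # known variants at the seed anchor (mature position 3) of a declared
    # subset of non-mitochondrial miRNAs
    snp_idx <- which(seq_len(n_mirnas) %% 4L == 0L & seq_len(n_mirnas) != mito_idx)
    mat <- matures(ann)
    variants <- data.table(contig = character(0), pos0 = integer(0),
                           id = character(0), ref = character(0),
                           alt = character(0))
    for (i in snp_idx) {
      m <- mat[mat$id == sprintf("sim-miR-%d-3p", i), ]
      pos0 <- if (m$strand == "+") m$start0 + 2L else m$end0 - 3L
      ref <- if (m$strand == "+") "A" else "T"
      alt <- if (m$strand == "+") "G" else "C"
      variants <- rbind(variants, data.table(
        contig = m$contig, pos0 = pos0, id = sprintf("rsSIM%d", i),
        ref = ref, alt = alt))
    }

    bundle <- structure(list(
      genome = genome, annotation = ann, variants = variants,
      mature_seqs = mature_sequences(genome, ann),
      snp_mirnas = sprintf("sim-miR-%d-3p", snp_idx),
      mito_mirnas = mat$id[mat$mito],
      paths = NULL), class = "mir_reference")

    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(fasta = file.path(outdir, "reference.fa"),
                    gff3 = file.path(outdir, "annotation.gff3"),
                    vcf = file.path(outdir, "known_variants.vcf"))
      Biostrings::writeXStringSet(genome, paths$fasta)
      write_annotation_gff3(ann, paths$gff3)
      write_variants_vcf(variants, paths$vcf,
                         contig_lengths = setNames(Biostrings::width(genome),
                                                   names(genome)))
      bundle$paths <- paths
    }
    bundle
  })
}

# --- sequencing-error machinery -------------------------------------------

OTHER_BASES <- matrix(c("C", "G", "T",
                        "A", "G", "T",
                        "A", "C", "T",
                        "A", "C", "G"),
                      nrow = 4, byrow = TRUE,
                      dimnames = list(DNA_BASES, NULL))

# apply >=1 uniform substitution errors to each sequence (all same length L);
# k errors per read drawn from Binomial(L, e) conditioned on k >= 1
mutate_with_errors <- function(seqs, e) {
  n <- length(seqs)
  if (n == 0L) return(seqs)
  L <- nchar(seqs[1])
  k <- rbinom(n, L, e)
  while (any(zero <- k == 0L)) k[zero] <- rbinom(sum(zero), L, e)
  one <- which(k == 1L)
  if (length(one)) {
    pos <- sample.int(L, length(one), replace = TRUE)
    cur <- substr(seqs[one], pos, pos)
    new <- OTHER_BASES[cbind(match(cur, DNA_BASES),
                             sample.int(3L, length(one), replace = TRUE))]
    substr(seqs[one], pos, pos) <- new
  }
  multi <- which(k >= 2L)
  for (i in multi) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    at <- sample.int(L, k[i])
    ch[at] <- OTHER_BASES[cbind(match(ch[at], DNA_BASES),
                                sample.int(3L, k[i], replace = TRUE))]
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

quality_string <- function(len, low_q_tail) {
  if (low_q_tail > 0L && len > low_q_tail)
    paste0(strrep("?", len - low_q_tail), strrep("+", low_q_tail))  # Q30 / Q10
  else if (low_q_tail >= len) strrep("+", len)
  else strrep("?", len)
}

# translate decoy specs into concrete plants / depth profiles / background
# read sources for one simulated cohort
resolve_decoys <- function(bundle, decoys, design, used_mirnas = character(0)) {
  plants <- list(); depth_profiles <- list(); backgrounds <- list()
  ns <- length(design$stages) * design$samples_per_stage
  mat <- matures(bundle$annotation)
  pool <- setdiff(mat$id, c(bundle$snp_mirnas, bundle$mito_mirnas, used_mirnas))
  take <- function() {
    if (!length(pool)) stopf("reference has too few miRNAs for the requested decoys")
    x <- pool[1]; pool <<- pool[-1]; x
  }
  rising <- rising_fractions(length(design$stages))
  for (d in decoys) {
    switch(d$kind,
      SNP_SITE = {
        id <- d$mirna_id %||% bundle$snp_mirnas[1]
        if (is.null(id) || is.na(id)) stopf("no SNP-overlapping miRNA in bundle")
        plants[[length(plants) + 1L]] <- planted_edit(
          id, d$mature_position %||% 3L, d$fractions %||% rising,
          kind = "SNP_SITE")
      },
      MITO_SITE = {
        id <- d$mirna_id %||% bundle$mito_mirnas[1]
        plants[[length(plants) + 1L]] <- planted_edit(
          id, d$mature_position %||% 3L, d$fractions %||% rising,
          kind = "MITO_SITE")
      },
      OUTSIDE_PREMIRNA = {
        backgrounds[[length(backgrounds) + 1L]] <- list(
          fractions = d$fractions %||% rising, kind = "OUTSIDE_PREMIRNA")
      },
      LOW_EXPRESSION = {
        id <- d$mirna_id %||% take()
        k <- d$expressed_samples %||% 3L
        dep <- d$expressed_depth %||% 40
        prof <- rep(0, ns)
        prof[unique(round(seq(1, ns, length.out = k)))] <- dep
        depth_profiles[[id]] <- prof
        plants[[length(plants) + 1L]] <- planted_edit(
          id, d$mature_position %||% 3L, d$fractions %||% rising,
          kind = "LOW_EXPRESSION")
      },
      NON_SEED = {
        id <- d$mirna_id %||% take()
        plants[[length(plants) + 1L]] <- planted_edit(
          id, d$mature_position %||% 12L, d$fractions %||% rising,
          kind = "NON_SEED")
      },
      FLAT_TREND = {
        id <- d$mirna_id %||% take()
        plants[[length(plants) + 1L]] <- planted_edit(
          id, d$mature_position %||% 3L, d$fractions %||% 0.10,
          trend = FALSE, kind = "FLAT_TREND")
      })
  }
  list(plants = plants, depth_profiles = depth_profiles,
       backgrounds = backgrounds)
}

#' The six standard decoys, one per documented filter
#'
#' @param bundle a [make_reference()] bundle.
#' @return list of [decoy_spec()]s covering all six kinds.
#' @export
default_decoy_set <- function(bundle) {
  lapply(DECOY_KINDS, decoy_spec)
}

# pick an intergenic window on chr1 holding an A at window offset `at`
intergenic_window <- function(bundle, width = 22L, at = 11L) {
  ann <- premirnas(bundle$annotation)
  chr1 <- as.character(bundle$genome[["chr1"]])
  occ <- ann[ann$contig == "chr1", ]
  margin <- 40L
  gaps_start <- c(0L, occ$end0 + margin)
  gaps_end <- c(occ$start0 - margin, nchar(chr1))
  for (g in seq_along(gaps_start)) {
    lo <- gaps_start[g]; hi <- gaps_end[g] - width
    if (hi - lo < 5L) next
    for (s0 in seq(lo, hi)) {
      w <- substr(chr1, s0 + 1L, s0 + width)
      if (substr(w, at, at) == "A") return(list(start0 = s0, seq = w, at = at))
    }
  }
  stopf("no intergenic window with an A found on chr1")
}

#' Simulate a multistage small-RNA sequencing cohort
#'
#' Each read is drawn from a mature miRNA sequence in sense orientation,
#' edited at every planted site with the sample's stage-specific fraction
#' (edited reads carry G at the site, the sequencing image of inosine),
#' extended with the 3' adapter, truncated to the machine read length, and
#' then corrupted with uniform substitution errors at the design error rate.
#' Read counts per miRNA are Poisson around `depth_per_mirna`. Decoys add
#' plants, per-sample depth overrides, or intergenic background reads.
#'
#' @param bundle a [make_reference()] bundle.
#' @param design a [sim_design()].
#' @param plants list of [planted_edit()]s.
#' @param decoys list of [decoy_spec()]s.
#' @param outdir if non-NULL, write one FASTQ per sample plus
#'   `truth_sites.tsv` and `samples.tsv` there.
#' @return a `sim_reads` object: `samples` (sample sheet), `reads` (per-sample
#'   aggregated read tables `seq`/`qual`/`count`), `truth` (true per-site,
#'   per-sample editing fractions), `fastq_paths`.
#' @export
simulate_reads <- function(bundle, design, plants = list(), decoys = list(),
                           outdir = NULL) {
  stopifnot(is(bundle, "mir_reference"), is(design, "sim_design"))
  if (is(plants, "planted_edit")) plants <- list(plants)
  dec <- resolve_decoys(bundle, decoys, design,
                        used_mirnas = vapply(plants, `[[`, "", "mirna_id"))
  plants <- c(plants, dec$plants)

  # validate plants against the reference
  for (p in plants) {
    seq <- bundle$mature_seqs[[p$mirna_id]]
    if (is.null(seq)) stopf("plant references unknown miRNA '%s'", p$mirna_id)
    if (p$mature_position < 1L || p$mature_position > nchar(seq))
      stopf("plant position %d outside mature miRNA '%s'",
            p$mature_position, p$mirna_id)
    base <- substr(seq, p$mature_position, p$mature_position)
    if (base != "A")
      stopf("plant at %s position %d: reference base is %s, expected A",
            p$mirna_id, p$mature_position, base)
  }

  stages <- design$stages
  samples <- data.table(
    sample_id = paste0(rep(stages, each = design$samples_per_stage), "_",
                       rep(seq_len(design$samples_per_stage), length(stages))),
    stage = factor(rep(stages, each = design$samples_per_stage),
                   levels = stages))
  samples[, group := ifelse(stage == stages[1], "normal",
                     ifelse(stage == stages[length(stages)], "tumor", "other"))]

  mat <- matures(bundle$annotation)
  plant_by_mirna <- split(plants, vapply(plants, `[[`, "", "mirna_id"))
  bg <- lapply(dec$backgrounds, function(b) {
    w <- intergenic_window(bundle)
    c(b, w)
  })

  frac_at <- function(fr, stage_i) {
    if (length(fr) == 1L) fr else fr[stage_i]
  }
  genomic_pos0 <- function(m, p) {
    if (m$strand == "+") m$start0 + p - 1L else m$end0 - p
  }

  with_rng(design$rng_seed, {
    reads <- vector("list", nrow(samples))
    truth <- list()
    for (si in seq_len(nrow(samples))) {
      stage_i <- match(as.character(samples$stage[si]), stages)
      tabs <- list()
      emit <- function(insert_variants) {
        # insert_variants: data.table(seq, n); adapterize, mutate, aggregate
        iv <- insert_variants[n > 0L]
        if (!nrow(iv)) return(invisible())
        raw <- if (nzchar(design$adapter))
          substr(paste0(iv$seq, design$adapter), 1L, design$read_length)
        else iv$seq
        L <- nchar(raw[1])
        p0 <- (1 - design$error_rate)^L
        nerr <- rbinom(nrow(iv), iv$n, 1 - p0)
        clean <- data.table(seq = raw, count = iv$n - nerr)
        errs <- mutate_with_errors(rep(raw, nerr), design$error_rate)
        tab <- rbind(clean[count > 0L],
                     if (length(errs)) data.table(seq = errs, count = 1L))
        tabs[[length(tabs) + 1L]] <<- tab
      }
      for (mi in seq_len(nrow(mat))) {
        id <- mat$id[mi]
        prof <- dec$depth_profiles[[id]]
        mu <- if (is.null(prof)) design$depth_per_mirna else prof[si]
        n <- if (mu > 0) rpois(1L, mu) else 0L
        base_seq <- bundle$mature_seqs[[id]]
        pl <- plant_by_mirna[[id]]
        variants <- data.table(seq = base_seq, n = n)
        if (!is.null(pl)) for (p in pl) {
          f <- frac_at(p$stage_fractions, stage_i)
          m <- mat[mi, ]
          truth[[length(truth) + 1L]] <- data.table(
            sample_id = samples$sample_id[si],
            stage = as.character(samples$stage[si]),
            mirna_id = id, contig = m$contig,
            pos0 = genomic_pos0(m, p$mature_position),
            mature_position = p$mature_position,
            kind = p$kind, true_fraction = f)
          if (f > 0 && n > 0L) {
            split_n <- rbinom(nrow(variants), variants$n, f)
            edited <- copy(variants)[, n := split_n]
            substr(edited$seq, p$mature_position, p$mature_position) <- "G"
            variants[, n := n - split_n]
            variants <- rbind(variants, edited)
          }
        }
        if (n > 0L) emit(variants)
      }
      for (b in bg) {
        n <- rpois(1L, design$depth_per_mirna)
        f <- frac_at(b$fractions, stage_i)
        truth[[length(truth) + 1L]] <- data.table(
          sample_id = samples$sample_id[si],
          stage = as.character(samples$stage[si]),
          mirna_id = NA_character_, contig = "chr1",
          pos0 = b$start0 + b$at - 1L, mature_position = NA_integer_,
          kind = b$kind, true_fraction = f)
        if (n > 0L) {
          k <- rbinom(1L, n, f)
          ed <- b$seq
          substr(ed, b$at, b$at) <- "G"
          emit(data.table(seq = c(b$seq, ed), n = c(n - k, k)))
        }
      }
      tab <- rbindlist(tabs)[, .(count = sum(count)), by = seq]
      setorder(tab, seq)
      tab[, qual := quality_string(nchar(seq)[1], design$low_q_tail),
          by = nchar(seq)]
      reads[[si]] <- tab[, .(seq, qual, count)]
    }
    names(reads) <- samples$sample_id
    truth <- rbindlist(truth)

    fastq_paths <- NULL
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      fastq_paths <- file.path(outdir, paste0("reads_", samples$sample_id,
                                              ".fastq"))
      for (si in seq_len(nrow(samples))) {
        tab <- reads[[si]]
        idx <- rep(seq_len(nrow(tab)), tab$count)
        write_fastq(data.table(id = sprintf("%s_r%d", samples$sample_id[si],
                                            seq_along(idx)),
                               seq = tab$seq[idx], qual = tab$qual[idx]),
                    fastq_paths[si])
      }
      write_tsv(truth, file.path(outdir, "truth_sites.tsv"))
      write_tsv(samples, file.path(outdir, "samples.tsv"))
    }
    structure(list(design = design, samples = samples, reads = reads,
                   truth = truth, fastq_paths = fastq_paths),
              class = "sim_reads")
  })
}

#' Simulate a stage-structured gene expression matrix
#'
#' Each cluster follows a distinct stage profile on the log2 scale (monotone
#' up, monotone down, transient peak, with larger amplitudes for additional
#' clusters); genes get log-normal noise around their cluster profile and are
#' reported on the FPKM-like linear scale, so that `log2(x + 1)` recovers the
#' profile. A flat profile is deliberately not used: pattern clustering
#' standardizes each gene to mean 0, sd 1 across stages, under which a flat
#' profile degenerates to pure noise and carries no recoverable label.
#'
#' @param genes number of genes (>= trend_clusters).
#' @param design a [sim_design()] (stage order and samples per stage reused).
#' @param trend_clusters number of clusters (>= 2).
#' @param noise_sd log2-scale noise standard deviation (0 gives identical
#'   within-cluster profiles).
#' @param rng_seed seed (defaults to the design seed).
#' @return a `sim_expression` list: `fpkm` (genes x samples matrix), `samples`
#'   (sample sheet), `labels` (true cluster per gene), `centers_log2`.
#' @export
simulate_expression_matrix <- function(genes, design, trend_clusters,
                                       noise_sd = 0.5,
                                       rng_seed = design$rng_seed) {
  if (trend_clusters < 2L) stopf("trend_clusters must be >= 2")
  if (genes < trend_clusters) stopf("genes must be >= trend_clusters")
  ns <- length(design$stages)
  centers <- matrix(0, trend_clusters, ns,
                    dimnames = list(NULL, design$stages))
  for (j in seq_len(trend_clusters)) {
    amp <- 1.5 * (1 + (j - 1L) %/% 3L)
    shape <- switch(((j - 1L) %% 3L) + 1L,
                    seq(0, amp, length.out = ns),                  # up
                    seq(amp, 0, length.out = ns),                  # down
                    amp * sin(pi * (seq_len(ns) - 1) / (ns - 1)))  # peak
    centers[j, ] <- 3 + shape
  }
  with_rng(rng_seed, {
    labels <- rep_len(seq_len(trend_clusters), genes)
    samples <- data.table(
      sample_id = paste0(rep(design$stages, each = design$samples_per_stage),
                         "_", rep(seq_len(design$samples_per_stage), ns)),
      stage = factor(rep(design$stages, each = design$samples_per_stage),
                     levels = design$stages))
    mu <- centers[labels, match(as.character(samples$stage),
                                design$stages), drop = FALSE]
    noise <- matrix(rnorm(length(mu), sd = noise_sd), nrow(mu), ncol(mu))
    fpkm <- pmax(2^(mu + noise) - 1, 0)
    dimnames(fpkm) <- list(sprintf("gene_%d", seq_len(genes)),
                           samples$sample_id)
    structure(list(fpkm = fpkm, samples = samples, labels = labels,
                   centers_log2 = centers, stages = design$stages),
              class = "sim_expression")
  })
}

#' Simulate 3'UTR sequences with planted seed-match sites
#'
#' Background sequence is rejection-sampled so that it contains no accidental
#' site of any type for either seed; planted sites are embedded at recorded
#' coordinates with flanking bases chosen so that each site has exactly its
#' requested type.
#'
#' @param n_genes number of UTRs; genes without a planted site are
#'   background-only.
#' @param canonical_seed,edited_seed the two 7-mer seeds (miRNA positions
#'   2-8, RNA or DNA alphabet); they must differ.
#' @param planted data.frame with columns `gene` (index in 1..n_genes),
#'   `form` ("canonical"/"edited") and `type` ("8mer", "7mer-m8", "7mer-A1",
#'   "6mer"), or NULL.
#' @param rng_seed integer seed.
#' @param utr_length background UTR length.
#' @param fasta optional path to write the UTRs as FASTA.
#' @return a `sim_utrs` list: `utrs` (named DNA character vector), `truth`
#'   (gene, form, type, start0).
#' @export
simulate_utrs <- function(n_genes, canonical_seed, edited_seed,
                          planted = NULL, rng_seed = 1L, utr_length = 500L,
                          fasta = NULL) {
  canonical_seed <- as_dna(canonical_seed); edited_seed <- as_dna(edited_seed)
  if (nchar(canonical_seed) != 7L || nchar(edited_seed) != 7L)
    stopf("seeds must be 7-mers (miRNA positions 2-8)")
  if (canonical_seed == edited_seed)
    stopf("canonical and edited seeds are identical; they must differ")
  planted <- if (is.null(planted))
    data.table(gene = integer(0), form = character(0), type = character(0))
  else as.data.table(planted)
  stopifnot(all(planted$form %in% c("canonical", "edited")),
            all(planted$type %in% SITE_TYPES),
            all(planted$gene >= 1 & planted$gene <= n_genes))

  seeds <- c(canonical = canonical_seed, edited = edited_seed)
  scan_both <- function(utr) {
    a <- scan_utr(seeds[["canonical"]], utr, is_seed = TRUE)
    a[, form := rep("canonical", .N)]
    b <- scan_utr(seeds[["edited"]], utr, is_seed = TRUE)
    b[, form := rep("edited", .N)]
    rbind(a, b)
  }

  with_rng(rng_seed, {
    utrs <- character(n_genes)
    truth <- list()
    for (g in seq_len(n_genes)) {
      want <- planted[gene == g]
      for (try in seq_len(500L)) {
        utr <- random_dna(utr_length)
        pos0 <- integer(0)
        ok <- TRUE
        if (nrow(want)) {
          # embed sites left to right with >= 12 nt spacing
          slots <- sort(sample.int(utr_length - 60L, nrow(want)) + 20L)
          if (nrow(want) > 1L && any(diff(slots) < 20L)) next
          for (k in seq_len(nrow(want))) {
            emb <- embed_site(utr, slots[k], seeds[[want$form[k]]],
                              want$type[k])
            if (is.null(emb)) { ok <- FALSE; break }
            utr <- emb$utr; pos0 <- c(pos0, emb$start0)
          }
          if (!ok) next
        }
        found <- scan_both(utr)
        expected <- if (nrow(want))
          data.table(form = want$form, type = want$type, start0 = pos0)
        else data.table(form = character(0), type = character(0),
                        start0 = integer(0))
        got <- as.data.table(found)[, .(form, type, start0)]
        setorder(got, form, start0); setorder(expected, form, start0)
        if (isTRUE(all.equal(got, expected, check.attributes = FALSE))) {
          utrs[g] <- utr
          if (nrow(expected))
            truth[[length(truth) + 1L]] <- cbind(gene = g, expected)
          break
        }
        if (try == 500L) stopf("could not place requested sites in gene %d", g)
      }
    }
    names(utrs) <- sprintf("gene_%d", seq_len(n_genes))
    truth <- if (length(truth)) rbindlist(truth)
             else data.table(gene = integer(0), form = character(0),
                             type = character(0), start0 = integer(0))
    if (!is.null(fasta))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(utrs), fasta)
    structure(list(utrs = utrs, truth = truth), class = "sim_utrs")
  })
}

# splice a site of exactly `type` for `seed` into utr at 1-based position pos;
# returns NULL if impossible, else list(utr, start0)
embed_site <- function(utr, pos, seed, type) {
  core6 <- revcomp_chr(substr(seed, 1L, 6L))   # complements positions 2-7
  m8c <- complement_chr(substr(seed, 7L, 7L))  # base pairing miRNA position 8
  non <- function(b) setdiff(c("C", "G"), b)[1]  # a safe base != b and != A
  motif <- switch(type,
    "8mer" = paste0(m8c, core6, "A"),
    "7mer-m8" = paste0(m8c, core6, non("A")),
    "7mer-A1" = paste0(non(m8c), core6, "A"),
    "6mer" = paste0(non(m8c), core6, non("A")))
  substr(utr, pos, pos + nchar(motif) - 1L) <- motif
  # 0-based start of the reported site (the scanner anchors 8mer/7mer-m8 at
  # the m8-pairing base, 7mer-A1/6mer at the core)
  start0 <- if (type %in% c("8mer", "7mer-m8")) pos - 1L else pos
  list(utr = utr, start0 = start0)
}
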