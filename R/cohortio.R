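#' Write a cohort editing matrix as TSV
#'
#' Two files: `<prefix>_editing.tsv` (site metadata columns followed by one
#' editing-level column per sample) and `<prefix>_tpm.tsv` (mature miRNA TPM
#' per sample). The sample sheet is written as `<prefix>_samples.tsv`.
#'
#' @param matrix a [cohort_editing_matrix()].
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
write_cohort_matrix <- function(matrix, prefix) {
  ed <- cbind(matrix$sites, as.data.table(matrix$editing))
  p1 <- paste0(prefix, "_editing.tsv"); write_tsv(ed, p1)
  tpm <- data.table(mirna_id = rownames(matrix$tpm),
                    as.data.table(matrix$tpm))
  p2 <- paste0(prefix, "_tpm.tsv"); write_tsv(tpm, p2)
  p3 <- paste0(prefix, "_samples.tsv"); write_tsv(matrix$samples, p3)
  invisible(c(p1, p2, p3))
}

#' Read a cohort editing matrix written by [write_cohort_matrix()]
#'
#' @param prefix path prefix used at write time.
#' @param stages declared stage order.
#' @return a `cohort_matrix` object.
#' @export
read_cohort_matrix <- function(prefix, stages) {
  samples <- read_sample_sheet(paste0(prefix, "_samples.tsv"), stages)
  ed <- as.data.table(read.delim(paste0(prefix, "_editing.tsv")))
  meta_cols <- c("site_id", "contig", "pos0", "mirna_id", "mature_id",
                 "mature_position", "in_seed", "mito")
  info <- ed[, intersect(meta_cols, names(ed)), with = FALSE]
  # read.delim mangles sample ids into syntactic names; map them back
  samp_cols <- setdiff(names(ed), meta_cols)
  editing <- as.matrix(ed[, samp_cols, with = FALSE])
  colnames(editing) <- samples$sample_id[
    match(samp_cols, make.names(samples$sample_id))]
  rownames(editing) <- info$site_id
  tp <- as.data.table(read.delim(paste0(prefix, "_tpm.tsv")))
  tpm <- as.matrix(tp[, setdiff(names(tp), "mirna_id"), with = FALSE])
  colnames(tpm) <- samples$sample_id[
    match(colnames(tpm), make.names(samples$sample_id))]
  rownames(tpm) <- tp$mirna_id
  structure(list(sites = info, editing = editing[, samples$sample_id,
                                                 drop = FALSE],
                 tpm = tpm[, samples$sample_id, drop = FALSE],
                 samples = samples, stages = stages),
            class = "cohort_matrix")
}
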