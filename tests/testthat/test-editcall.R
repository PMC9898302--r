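# deterministic toy genome for pileup tests: c1 = "ACGT" repeated
toy_genome <- function() Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 50)))
base_at <- function(pos0) c("A", "C", "G", "T")[(pos0 %% 4) + 1]

test_that("pileup tallies bases and orients minus-strand genes", {
  ann <- toy_annotation(); gen <- toy_genome()
  # 10 perfect reads over the plus-strand mature arm
  core <- substr(as.character(gen[[1]]), 21, 40)
  aln <- toy_alignment("c1", 20L, core, count = 10L)
  pu <- pileup(aln, ann, gen)
  a_sites <- pu[pu$ref_base == "A", ]
  expect_true(all(a_sites$A == 10L & a_sites$C == 0L & a_sites$G == 0L &
                    a_sites$T == 0L))
  expect_true(all(pu$coverage == 10L))
  expect_equal(pu$mature_position[pu$pos0 == 22], 3L)
  expect_true(pu$in_seed[pu$pos0 == 22])

  # minus-strand gene: genomic T -> C variant reads report as A -> G on the
  # miRNA strand
  tpos <- 115L                      # base_at(115) == "T", inside [110, 132)
  expect_identical(base_at(tpos), "T")
  ref_core <- substr(as.character(gen[[1]]), 111, 130)
  var_core <- ref_core
  substr(var_core, tpos - 110L + 1L, tpos - 110L + 1L) <- "C"
  aln2 <- rbind(toy_alignment("c1", 110L, ref_core, count = 6L),
                toy_alignment("c1", 110L, var_core, count = 4L))
  pu2 <- pileup(aln2, ann, gen)
  row <- pu2[pu2$pos0 == tpos, ]
  expect_identical(row$ref_base, "A")
  expect_equal(row$A, 6L)
  expect_equal(row$G, 4L)
  expect_identical(row$strand, "-")
  expect_equal(row$mature_position, 132L - tpos)

  # restrict drops positions outside any pre-miRNA
  stray <- toy_alignment("c1", 180L, "ACGTACGTAC")
  expect_equal(nrow(pileup(stray, ann, gen)), 0L)
  expect_equal(nrow(pileup(stray, ann, gen, restrict = FALSE)), 10L)
  expect_error(pileup(toy_alignment("cZ", 5L, "ACGT"), ann, gen), "cZ")
})

test_that("pileup equals a brute-force per-read per-base tally", {
  ann <- toy_annotation(); gen <- toy_genome()
  set.seed(12)
  cores <- vapply(1:5, function(i) {
    s <- substr(as.character(gen[[1]]), 21 + i, 40 + i)
    p <- sample(20, 1)
    substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
    s
  }, "")
  aln <- toy_alignment("c1", 20L + 1:5, cores, count = sample(1:3, 5, TRUE))
  pu <- pileup(aln, ann, gen)
  tally <- oracle_pileup_tally(aln)
  for (i in seq_len(nrow(pu))) {
    r <- pu[i, ]
    for (b in c("A", "C", "G", "T")) {
      fwd_b <- if (r$strand == "-") chartr("ACGT", "TGCA", b) else b
      expect_equal(r[[b]],
                   tally[[paste(r$contig, r$pos0, fwd_b)]] %||% 0L,
                   label = sprintf("pos %d base %s", r$pos0, b))
    }
  }
})

test_that("estimate_error_rate pools non-A-to-G mismatches", {
  mk <- function(ref, A, C, G, T) data.table::data.table(
    ref_base = ref, A = A, C = C, G = G, T = T, coverage = A + C + G + T)
  # error-free: floor
  expect_equal(estimate_error_rate(mk("C", 0, 100, 0, 0)), 1e-6)
  # exactly 3 non-A->G mismatches over 300 eligible bases -> 0.01
  p <- rbind(mk("C", 1, 99, 0, 0), mk("G", 0, 1, 99, 0),
             mk("T", 0, 0, 1, 99))
  expect_equal(estimate_error_rate(p), 3 / 300)
  # A->G mismatches are excluded entirely
  expect_equal(estimate_error_rate(mk("A", 95, 0, 5, 0)), 1e-6)
  expect_error(estimate_error_rate(mk("A", 3, 0, 0, 0)), "error_rate")
})

test_that("binomial editing test matches exact arbitrary-precision values", {
  mk_site <- function(A, G, cov = A + G) data.table::data.table(
    contig = "c1", pos0 = 22L, ref_base = "A", A = A, C = 0L, G = G, T = 0L,
    coverage = cov, mirna_id = "toy-mir-1", mature_id = "toy-miR-1-3p",
    mature_position = 3L, in_seed = TRUE, mito = FALSE, strand = "+")
  # A=100, G=0: level 0, p_raw 1
  s <- call_editing_sites(mk_site(100L, 0L),
                          call_config(error_rate = 0.01))
  expect_equal(s$editing_level, 0)
  expect_equal(s$p_raw, 1)

  # frozen exact tail sums (independent arbitrary-precision oracle)
  cases <- list(
    list(A = 950L, G = 50L, er = 0.01, exact = 5.8909257609344181e-41),
    list(A = 490L, G = 10L, er = 0.005, exact = 1.9384134558772338e-8),
    list(A = 1997L, G = 3L, er = 0.02, exact = 0.99983819774649403),
    list(A = 95L, G = 5L, er = 0.01, exact = 2.3811630652817266e-5))
  for (cs in cases) {
    s <- call_editing_sites(mk_site(cs$A, cs$G),
                            call_config(error_rate = cs$er))
    expect_lt(abs(s$p_raw - cs$exact) / cs$exact, 1e-9)
    expect_equal(s$editing_level, cs$G / (cs$A + cs$G))
  }

  # Bonferroni arithmetic: p_raw 0.002 with 100 tests -> 0.2, not significant
  expect_equal(min(1, 0.002 * 100), 0.2)
  many <- data.table::rbindlist(lapply(0:99, function(i) {
    x <- mk_site(500L, if (i == 0) 8L else 0L)
    x$pos0 <- 22L + i * 2L
    x
  }))
  called <- call_editing_sites(many, call_config(error_rate = 0.01))
  expect_equal(unique(called$n_tests), 100L)
  expect_equal(called$p_bonferroni, pmin(1, called$p_raw * 100))
  expect_true(all(called$p_bonferroni >= called$p_raw))

  # monotonicity: p_raw nonincreasing in G at fixed A+G
  ps <- vapply(c(0L, 2L, 5L, 10L, 20L, 50L), function(g)
    call_editing_sites(mk_site(300L - g, g),
                       call_config(error_rate = 0.01))$p_raw, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("filter_sites drops SNP, mitochondrial and outside sites", {
  ann <- toy_annotation()
  sites <- data.table::data.table(
    contig = c("c1", "cM", "c1", "c1"), pos0 = c(22L, 5L, 180L, 30L),
    mirna_id = c("toy-mir-1", "toy-mir-m", NA, "toy-mir-1"),
    mito = c(FALSE, TRUE, FALSE, FALSE))
  vars <- data.table::data.table(contig = "c1", pos0 = 22L, id = "rs1",
                                 ref = "A", alt = "C")  # different alt allele
  res <- filter_sites(sites, ann, vars)
  expect_identical(res$sites$filter_flags,
                   c("KNOWN_SNP", "MITOCHONDRIAL", "NOT_PREMIRNA", ""))
  expect_equal(nrow(res$retained), 1L)
  expect_equal(res$retained$pos0, 30L)
})

test_that("quantify_expression computes length-normalized TPM", {
  ann3 <- mir_annotation(
    contig = "c1", start0 = c(0L, 0L, 100L, 100L, 200L, 200L),
    end0 = c(40L, 20L, 140L, 122L, 240L, 222L), strand = "+",
    type = rep(c("pre_mirna", "mature"), 3),
    id = c("p1", "m1", "p2", "m2", "p3", "m3"),
    derives_from = c(NA, "p1", NA, "p2", NA, "p3"))
  mk_aln <- function(start0, n) toy_alignment("c1", rep(start0, n),
                                              strrep("A", 10))
  # single expressed miRNA: TPM = 1e6
  q1 <- quantify_expression(mk_aln(2L, 1), ann3)
  expect_equal(q1$tpm[q1$mirna_id == "m1"], 1e6)
  # counts 10/20/70 with lengths 20/22/22: independent closed form
  aln <- rbind(mk_aln(2L, 10), mk_aln(102L, 20), mk_aln(202L, 70))
  q <- quantify_expression(aln, ann3)
  rate <- c(10 / 0.020, 20 / 0.022, 70 / 0.022)
  expect_equal(q$tpm, rate / sum(rate) * 1e6)
  expect_equal(sum(q$tpm), 1e6)
  # equal counts, equal lengths: split evenly
  q2 <- quantify_expression(rbind(mk_aln(102L, 5), mk_aln(202L, 5)), ann3)
  expect_equal(q2$tpm[q2$mirna_id %in% c("m2", "m3")], c(5e5, 5e5))
  expect_warning(
    q0 <- quantify_expression(mk_aln(2L, 1)[0], ann3), "zero total")
  expect_true(all(q0$tpm == 0))
})

test_that("cohort filters enforce the documented boundaries", {
  mk_matrix <- function(editing, tpm_val, stages = c("N", "T")) {
    ns <- ncol(editing)
    samples <- data.table::data.table(
      sample_id = paste0("s", seq_len(ns)),
      stage = factor(rep(stages, length.out = ns), levels = stages),
      group = "other")
    colnames(editing) <- samples$sample_id
    tpm <- matrix(tpm_val, 1, ns,
                  dimnames = list("m1", samples$sample_id))
    structure(list(
      sites = data.table::data.table(
        site_id = rownames(editing), contig = "c1",
        pos0 = seq_len(nrow(editing)), mirna_id = "p1", mature_id = "m1",
        mature_position = 3L, in_seed = TRUE, mito = FALSE),
      editing = editing, tpm = tpm, samples = samples, stages = stages),
      class = "cohort_matrix")
  }
  # mean editing 0.049 dropped, 0.05 kept under MEAN_AND_TPM
  ed <- matrix(c(rep(0.049, 12), rep(0.050, 12)), 2, 12, byrow = TRUE,
               dimnames = list(c("s_low", "s_ok"), NULL))
  cm <- mk_matrix(ed, tpm_val = 5)
  res <- apply_cohort_filters(cm, "MEAN_AND_TPM")
  expect_identical(res$retained, "s_ok")
  expect_identical(res$detail[site_id == "s_low", reason],
                   "LOW_MEAN_EDITING")
  # TPM below 1 drops an otherwise-passing site
  cm_lowtpm <- mk_matrix(ed, tpm_val = 0.5)
  expect_identical(apply_cohort_filters(cm_lowtpm, "MEAN_AND_TPM")$retained,
                   character(0))
  # editing >= 5% in exactly 9 samples dropped, in 10 kept under N_SAMPLES
  ed9 <- matrix(c(rep(0.2, 9), rep(0, 3)), 1, 12,
                dimnames = list("nine", NULL))
  ed10 <- matrix(c(rep(0.2, 10), rep(0, 2)), 1, 12,
                 dimnames = list("ten", NULL))
  expect_identical(apply_cohort_filters(mk_matrix(ed9, 5),
                                        "N_SAMPLES")$retained, character(0))
  expect_identical(apply_cohort_filters(mk_matrix(ed10, 5),
                                        "N_SAMPLES")$retained, "ten")
  # all-zero matrix: empty result
  edz <- matrix(0, 1, 12, dimnames = list("z", NULL))
  expect_identical(apply_cohort_filters(mk_matrix(edz, 5),
                                        "MEAN_AND_TPM")$retained,
                   character(0))
  expect_error(apply_cohort_filters(mk_matrix(edz, 5), "BOGUS"))
})
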