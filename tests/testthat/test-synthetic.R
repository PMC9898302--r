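test_that("make_reference is byte-identical under a fixed seed", {
  for (n in c(1L, 10L)) {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    make_reference(n, rng_seed = 7, outdir = d1)
    make_reference(n, rng_seed = 7, outdir = d2)
    for (f in c("reference.fa", "annotation.gff3", "known_variants.vcf"))
      expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                       readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
})

test_that("make_reference postconditions hold", {
  b <- make_reference(10, rng_seed = 1)
  pre <- b$annotation[b$annotation$type == "pre_mirna", ]
  mat <- b$annotation[b$annotation$type == "mature", ]
  expect_equal(nrow(pre), 10L)
  expect_true(all(pre$end0 - pre$start0 >= 60 & pre$end0 - pre$start0 <= 110))
  expect_true(all(mat$end0 - mat$start0 >= 20 & mat$end0 - mat$start0 <= 24))
  # exhaustive interval containment of each mature arm in its hairpin
  for (i in seq_len(nrow(mat))) {
    p <- pre[pre$id == mat$derives_from[i], ]
    expect_true(mat$contig[i] == p$contig && mat$start0[i] >= p$start0 &&
                  mat$end0[i] <= p$end0)
  }
  expect_true(any(pre$strand == "-"))
  expect_true(any(pre$mito))
  # VCF records overlap declared adenosines of the mature arm (miRNA strand)
  expect_gt(nrow(b$variants), 0L)
  for (i in seq_len(nrow(b$variants))) {
    v <- b$variants[i, ]
    gbase <- substr(as.character(b$genome[[v$contig]]), v$pos0 + 1, v$pos0 + 1)
    expect_identical(gbase, v$ref)
    expect_true(v$ref %in% c("A", "T"))  # A on the miRNA strand
  }
  # round trip through GFF3 preserves the annotation
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(b$annotation, gff)
  back <- read_annotation_gff3(gff)
  expect_equal(as.data.frame(back[order(id)]),
               as.data.frame(b$annotation[order(id)]))
  expect_error(make_reference(0), "n_mirnas")
})

test_that("simulate_reads honors degenerate fractions and converges", {
  b <- shared_bundle()
  # fraction 1, no errors: every read covering the site carries G
  d <- sim_design(stages = "S", samples_per_stage = 1, depth_per_mirna = 200,
                  error_rate = 0, rng_seed = 3, adapter = "")
  sr <- simulate_reads(b, d, plants = planted_edit("sim-miR-1-3p", 3, 1.0))
  tab <- sr$reads[[1]]
  m1 <- tab[startsWith(seq, substr(b$mature_seqs[["sim-miR-1-3p"]], 1, 2))]
  target <- b$mature_seqs[["sim-miR-1-3p"]]
  covering <- tab[seq %in% c(target, `substr<-`(target, 3, 3, "G"))]
  expect_true(all(substr(covering$seq, 3, 3) == "G"))

  # fraction 0.3 at depth 10000: empirical G fraction within +/- 0.02
  d2 <- sim_design(stages = "S", samples_per_stage = 1,
                   depth_per_mirna = 10000, error_rate = 0, rng_seed = 4,
                   adapter = "")
  sr2 <- simulate_reads(b, d2, plants = planted_edit("sim-miR-1-3p", 3, 0.3))
  tab2 <- sr2$reads[[1]]
  edited <- `substr<-`(target, 3, 3, "G")
  g <- sum(tab2[seq == edited, count]); a <- sum(tab2[seq == target, count])
  expect_lt(abs(g / (a + g) - 0.3), 0.02)
})

test_that("simulate_reads validates plants and is deterministic", {
  b <- shared_bundle()
  d <- sim_design(stages = "S", samples_per_stage = 1, depth_per_mirna = 50,
                  rng_seed = 9)
  seqs <- b$mature_seqs[["sim-miR-1-3p"]]
  pos_c <- regexpr("C", seqs)[1]
  expect_error(
    simulate_reads(b, d, plants = planted_edit("sim-miR-1-3p", pos_c, 0.5)),
    "expected A")
  expect_error(planted_edit("x", 3, c(0.3, 0.1)), "nondecreasing")
  expect_error(planted_edit("x", 3, 1.2), "\\[0, 1\\]")
  s1 <- simulate_reads(b, d, plants = planted_edit("sim-miR-1-3p", 3, 0.2))
  s2 <- simulate_reads(b, d, plants = planted_edit("sim-miR-1-3p", 3, 0.2))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("truth table rows match emitted samples", {
  b <- shared_bundle()
  d <- sim_design(stages = c("A", "B"), samples_per_stage = 2,
                  depth_per_mirna = 30, rng_seed = 2)
  sr <- simulate_reads(b, d, plants = planted_edit("sim-miR-1-3p", 3,
                                                   c(0.1, 0.4)))
  expect_setequal(unique(sr$truth$sample_id), sr$samples$sample_id)
  expect_equal(sr$truth[sample_id == "B_1", true_fraction], 0.4)
  expect_equal(nrow(sr$truth), nrow(sr$samples))
})

test_that("simulate_expression_matrix has the promised structure", {
  d <- sim_design(stages = c("N", "C", "H"), samples_per_stage = 4,
                  rng_seed = 5)
  e <- simulate_expression_matrix(60, d, 3)
  expect_equal(dim(e$fpkm), c(60L, 12L))
  expect_equal(sort(unique(e$labels)), 1:3)
  expect_equal(tabulate(e$labels), rep(20L, 3))
  # zero noise: within-cluster profiles identical
  e0 <- simulate_expression_matrix(12, d, 3, noise_sd = 0)
  for (k in 1:3) {
    rows <- e0$fpkm[e0$labels == k, , drop = FALSE]
    expect_true(all(abs(sweep(rows, 2, rows[1, ])) < 1e-12))
  }
  expect_error(simulate_expression_matrix(2, d, 3), "genes")
  expect_error(simulate_expression_matrix(10, d, 1), "trend_clusters")
})

test_that("expression clusters are separated relative to noise", {
  d <- sim_design(stages = c("N", "C", "D", "H"), samples_per_stage = 8,
                  rng_seed = 5)
  e <- simulate_expression_matrix(300, d, 3)
  prof <- prepare_expression(e$fpkm, e$samples)
  cent <- sapply(1:3, function(k) colMeans(prof[e$labels == k, ]))
  within <- mean(vapply(seq_len(nrow(prof)), function(i)
    sqrt(sum((prof[i, ] - cent[, e$labels[i]])^2)), numeric(1)))
  between <- min(dist(t(cent)))
  expect_gt(between, within)
})

test_that("simulate_utrs plants exactly the requested sites", {
  ed <- apply_edit("TTACGCCTAGGCTAACCTGAAT", 3)
  pl <- data.frame(gene = c(1, 2), form = c("edited", "canonical"),
                   type = c("8mer", "7mer-m8"))
  su <- simulate_utrs(4, ed$canonical_seed, ed$edited_seed, planted = pl,
                      rng_seed = 8)
  expect_equal(nrow(su$truth), 2L)
  expect_identical(su$truth[su$truth$gene == 1, ]$form, "edited")
  expect_identical(su$truth[su$truth$gene == 1, ]$type, "8mer")
  # background-only genes: zero sites for both seeds by exhaustive scan
  for (g in 3:4) for (sd in c(ed$canonical_seed, ed$edited_seed))
    expect_equal(nrow(oracle_scan_utr(sd, su$utrs[[g]])), 0L)
  # planted coordinates verified by the exhaustive scanner
  o <- oracle_scan_utr(ed$edited_seed, su$utrs[[1]])
  expect_equal(o$start0, su$truth$start0[su$truth$gene == 1])
  expect_equal(o$type, "8mer")
  expect_error(simulate_utrs(2, ed$canonical_seed, ed$canonical_seed),
               "identical")
})
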