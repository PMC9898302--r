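# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

shared_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- make_reference(8, rng_seed = 11)
  .fixtures$bundle
}

# a minimal alignment-record table for hand-built pileup tests
toy_alignment <- function(contig, start0, core_fwd, count = 1L,
                          strand = "+") {
  data.table::data.table(
    id = sprintf("t%d", seq_along(start0)), seq = core_fwd,
    qual = strrep("I", nchar(core_fwd)), count = as.integer(count),
    contig = contig, start0 = as.integer(start0), strand = strand,
    core_fwd = core_fwd, clip3 = "", nm = 0L, mapped = TRUE,
    reason = NA_character_)
}

rc <- function(x) mirED:::revcomp_chr(x)

# tiny deterministic single-arm annotation for unit tests:
# one plus-strand and one minus-strand gene on "c1"
toy_annotation <- function() {
  mir_annotation(
    contig = c("c1", "c1", "c1", "c1"),
    start0 = c(10L, 20L, 100L, 110L),
    end0 = c(70L, 42L, 170L, 132L),
    strand = c("+", "+", "-", "-"),
    type = c("pre_mirna", "mature", "pre_mirna", "mature"),
    id = c("toy-mir-1", "toy-miR-1-3p", "toy-mir-2", "toy-miR-2-3p"),
    derives_from = c(NA, "toy-mir-1", NA, "toy-mir-2"),
    mito = FALSE)
}
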