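#' @import data.table
#' @importFrom methods is
#' @importFrom stats cor pbinom pchisq pnorm pt qnorm rbinom rnorm rpois
#'   runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic operations in the
# package go through this so results are reproducible and side-effect free.
with_rng <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# complement/reverse-complement on plain character vectors (DNA, T alphabet)
complement_chr <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

revcomp_chr <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# normalize RNA to DNA alphabet (U -> T), uppercased
as_dna <- function(x) chartr("uU", "tT", toupper(x))

# DNA -> RNA alphabet
as_rna <- function(x) chartr("tT", "uU", toupper(x))

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

phred_char <- function(q) intToUtf8(q + 33L, multiple = FALSE)

phred_ints <- function(qualstr) utf8ToInt(qualstr) - 33L

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
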