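# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive: direct enumeration and summation, no shared code paths
# with the implementation.

# exact binomial upper tail P(X >= g), X ~ Binomial(n, p), by log-space term
# summation (terms added smallest-first for accuracy)
oracle_binom_tail <- function(n, g, p) {
  if (g <= 0) return(1)
  if (g > n) return(0)
  k <- g:n
  lt <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  sum(exp(sort(lt)))
}

# brute-force all-offset ungapped mapper: scans every offset of every contig
# on both strands counting mismatches of the read core (last `trim3` bases
# ignored); unique-in-best-stratum reporting
oracle_map_read <- function(read, ref_chars, trim3 = 2L, max_mm = 1L) {
  core <- substr(read, 1L, nchar(read) - trim3)
  L <- nchar(core)
  hits <- list()
  for (cg in names(ref_chars)) {
    rchr <- ref_chars[[cg]]
    n <- length(rchr)
    if (n < L) next
    for (st in c("+", "-")) {
      pat <- strsplit(if (st == "+") core else rc(core), "")[[1]]
      noff <- n - L + 1L
      mm <- integer(noff)
      for (j in seq_len(L))
        mm <- mm + (rchr[j:(j + noff - 1L)] != pat[j])
      ok <- which(mm <= max_mm)
      if (length(ok))
        hits[[length(hits) + 1L]] <- data.frame(
          contig = cg, start0 = ok - 1L, strand = st, nm = mm[ok])
    }
  }
  h <- if (length(hits)) do.call(rbind, hits) else NULL
  if (is.null(h) || !nrow(h))
    return(list(mapped = FALSE, reason = "no_alignment"))
  hb <- h[h$nm == min(h$nm), , drop = FALSE]
  if (nrow(hb) == 1L)
    list(mapped = TRUE, contig = hb$contig, start0 = hb$start0,
         strand = hb$strand, nm = hb$nm)
  else list(mapped = FALSE, reason = "multimapper")
}

# exhaustive sliding-window seed-site scanner: tests every window against
# every site-type definition, assigns the highest-priority type per 6mer-core
# occurrence
oracle_scan_utr <- function(seed7, utr) {
  seed7 <- chartr("uU", "tT", toupper(seed7)); utr <- toupper(utr)
  core6 <- rc(substr(seed7, 1, 6))
  m8c <- chartr("ACGT", "TGCA", substr(seed7, 7, 7))
  L <- nchar(utr)
  out <- NULL
  for (p in seq_len(L - 5L)) {
    if (substr(utr, p, p + 5L) != core6) next
    m8 <- p > 1L && substr(utr, p - 1L, p - 1L) == m8c
    a1 <- p + 6L <= L && substr(utr, p + 6L, p + 6L) == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
            else if (a1) "7mer-A1" else "6mer"
    start0 <- if (m8) p - 2L else p - 1L
    out <- rbind(out, data.frame(start0 = start0, type = type))
  }
  if (is.null(out)) data.frame(start0 = integer(0), type = character(0))
  else out
}

# per-read, per-base tally oracle for pileup (forward-oriented records)
oracle_pileup_tally <- function(alignments) {
  counts <- list()
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    bases <- strsplit(a$core_fwd, "")[[1]]
    for (j in seq_along(bases)) {
      key <- paste(a$contig, a$start0 + j - 1L, bases[j])
      counts[[key]] <- (counts[[key]] %||% 0L) + a$count
    }
  }
  counts
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# best-permutation label-recovery accuracy for k-cluster assignments
oracle_label_accuracy <- function(assigned, truth, k) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(p[assigned] == truth))
  best
}

# exact permutation p-value for the two-sided rank-sum test statistic
# |mean rank difference|; small n only
oracle_rank_perm_p <- function(x, y) {
  all_v <- c(x, y); nx <- length(x)
  r <- rank(all_v)
  stat <- function(idx) abs(mean(r[idx]) - mean(r[-idx]))
  obs <- stat(seq_len(nx))
  combs <- utils::combn(length(all_v), nx)
  mean(apply(combs, 2L, function(idx) stat(idx) >= obs - 1e-12))
}
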