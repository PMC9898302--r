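SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
SITE_PRIORITY <- setNames(seq_along(SITE_TYPES), SITE_TYPES)  # 1 = best

#' Derive the edited miRNA from an A-to-G edit call
#'
#' Replaces the adenosine at `position` of the mature sequence with guanosine
#' (the sequencing image of inosine) and extracts both seeds (positions 2-8).
#'
#' @param mature_sequence canonical mature miRNA (RNA or DNA alphabet).
#' @param position 1-based edit position within the mature sequence.
#' @param mirna_id optional identifier carried through.
#' @param from_base,to_base the substitution (A -> G for A-to-I editing).
#' @return an `edited_mirna` list with RNA-alphabet `canonical`, `edited`,
#'   `canonical_seed`, `edited_seed`, `edit_position`.
#' @export
apply_edit <- function(mature_sequence, position, mirna_id = NA_character_,
                       from_base = "A", to_base = "G") {
  rna <- as_rna(mature_sequence)
  if (position < 1L || position > nchar(rna))
    stopf("edit position %d outside mature sequence of length %d",
          position, nchar(rna))
  found <- substr(rna, position, position)
  if (found != as_rna(from_base))
    stopf("base at position %d is %s, expected %s", position, found,
          as_rna(from_base))
  edited <- rna
  substr(edited, position, position) <- as_rna(to_base)
  structure(list(mirna_id = mirna_id, canonical = rna, edited = edited,
                 edit_position = as.integer(position),
                 canonical_seed = substr(rna, 2L, 8L),
                 edited_seed = substr(edited, 2L, 8L)),
            class = "edited_mirna")
}

#' Scan a 3'UTR for canonical seed-match target sites
#'
#' Site typing follows the canonical TargetScan classes. With the UTR written
#' 5'->3', a site is anchored on a perfect Watson-Crick match to the reverse
#' complement of miRNA positions 2-7 (the 6mer core); pairing of miRNA
#' position 8 extends the match 5' on the UTR, and an adenosine opposite
#' miRNA position 1 extends it 3'. Each core occurrence (overlaps included)
#' is reported once with its single highest-priority type:
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer.
#'
#' @param mirna mature miRNA sequence (>= 8 nt, RNA or DNA), or a 7-mer seed
#'   when `is_seed = TRUE`.
#' @param utr_sequence the UTR (RNA or DNA alphabet; `N` never matches).
#' @param is_seed treat `mirna` as the seed (positions 2-8) directly.
#' @return data.table with `start0` (0-based site start on the UTR), `type`,
#'   `core_start0` (start of the 6mer core).
#' @export
scan_utr <- function(mirna, utr_sequence, is_seed = FALSE) {
  utr <- as_dna(utr_sequence)
  if (grepl("[^ACGTN]", utr))
    stopf("UTR contains characters outside {A,C,G,T,U,N}")
  seed <- as_dna(mirna)
  if (!is_seed) {
    if (nchar(seed) < 8L) stopf("mature miRNA must be >= 8 nt")
    seed <- substr(seed, 2L, 8L)
  } else if (nchar(seed) != 7L) stopf("seed must be a 7-mer")
  if (grepl("N", seed, fixed = TRUE))
    stopf("seed contains N")
  empty <- data.table(start0 = integer(0), type = character(0),
                      core_start0 = integer(0))
  core6 <- revcomp_chr(substr(seed, 1L, 6L))
  m8c <- complement_chr(substr(seed, 7L, 7L))
  L <- nchar(utr)
  if (L < 6L) return(empty)
  hits <- gregexpr(paste0("(?=", core6, ")"), utr, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(empty)
  p <- as.integer(hits)
  has_m8 <- p > 1L & substring(utr, p - 1L, p - 1L) == m8c
  has_a1 <- p + 6L <= L & substring(utr, p + 6L, p + 6L) == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", "6mer")))
  start0 <- ifelse(has_m8, p - 2L, p - 1L)
  data.table(start0 = as.integer(start0), type = type,
             core_start0 = p - 1L)
}

#' Predict seed-match sites for the canonical and edited miRNA forms
#'
#' @param edited an [apply_edit()] object.
#' @param utrs named character vector (or DNAStringSet) of 3'UTR sequences.
#' @return data.table with `gene`, `form` ("canonical"/"edited"), `start0`,
#'   `type`.
#' @export
predict_targets <- function(edited, utrs) {
  stopifnot(is(edited, "edited_mirna"))
  if (is(utrs, "DNAStringSet")) utrs <- as.character(utrs)
  res <- list()
  for (g in names(utrs)) {
    for (form in c("canonical", "edited")) {
      seed <- if (form == "canonical") edited$canonical_seed
              else edited$edited_seed
      s <- scan_utr(seed, utrs[[g]], is_seed = TRUE)
      if (nrow(s))
        res[[length(res) + 1L]] <- data.table(gene = g, form = form,
                                              start0 = s$start0,
                                              type = s$type)
    }
  }
  if (!length(res))
    return(data.table(gene = character(0), form = character(0),
                      start0 = integer(0), type = character(0)))
  rbindlist(res)
}

#' Partition genes into lost, gained and shared target sets
#'
#' A gene is *lost* if it has at least one site for the canonical miRNA and
#' none for the edited form, *gained* in the converse case, and *shared* when
#' both forms have sites. Within each set genes are ranked by best site-type
#' priority (8mer first), then by site count.
#'
#' @param canonical_sites,edited_sites data.tables with `gene` and `type`
#'   columns (e.g. the two halves of [predict_targets()] output).
#' @return a `target_delta` list with `lost`, `gained`, `shared` data.tables
#'   (`gene`, `best_type`, `n_sites`).
#' @export
target_delta <- function(canonical_sites, edited_sites) {
  summarize <- function(x) {
    x <- as.data.table(x)
    if (!nrow(x)) return(data.table(gene = character(0),
                                    best_type = character(0),
                                    n_sites = integer(0)))
    s <- x[, .(best_prio = min(SITE_PRIORITY[type]), n_sites = .N), by = gene]
    s[, best_type := SITE_TYPES[best_prio]]
    setorder(s, best_prio, -n_sites, gene)
    s[, .(gene, best_type, n_sites)]
  }
  can <- summarize(canonical_sites); edi <- summarize(edited_sites)
  structure(list(
    lost = can[!gene %in% edi$gene],
    gained = edi[!gene %in% can$gene],
    shared = can[gene %in% edi$gene]), class = "target_delta")
}

#' Fuzzy c-means clustering
#'
#' Standard alternating optimization: memberships
#' \eqn{u_{ij} = 1 / \sum_k (d_{ij}/d_{ik})^{2/(m-1)}} and centers as
#' \eqn{u^m}-weighted means, iterated until the maximum center shift drops
#' below `tol` or `max_iter` is reached. Centers are initialized by a seeded
#' random selection of distinct data rows. Rows with zero distance to a
#' center receive crisp membership there.
#'
#' @param x numeric matrix (observations x features), typically the
#'   standardized stage-profile matrix from [prepare_expression()].
#' @param c number of clusters (>= 2, <= distinct rows).
#' @param m fuzzifier (> 1; 2 is the common default).
#' @param tol convergence tolerance on the maximum center coordinate shift.
#' @param max_iter iteration cap.
#' @param rng_seed seed for center initialization.
#' @return a `fuzzy_clustering` list: `membership` (rows sum to 1),
#'   `centers`, `objective` (per-iteration \eqn{\sum u^m d^2},
#'   nonincreasing), `iterations`, `m`.
#' @export
fuzzy_cmeans <- function(x, c, m = 2, tol = 1e-6, max_iter = 200L,
                         rng_seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (c < 2L) stopf("c must be >= 2")
  if (m <= 1) stopf("fuzzifier m must be > 1")
  if (c > n) stopf("more clusters (%d) than observations (%d)", c, n)
  with_rng(rng_seed, {
    uniq <- which(!duplicated(x))
    if (length(uniq) < c)
      stopf("fewer than c distinct rows; cannot initialize %d centers", c)
    centers <- x[sample(uniq, c), , drop = FALSE]
    sqdist <- function(ctr) {
      # n x c matrix of squared Euclidean distances
      d2 <- outer(rowSums(x^2), rep(1, nrow(ctr))) +
        outer(rep(1, n), rowSums(ctr^2)) - 2 * x %*% t(ctr)
      pmax(d2, 0)
    }
    memberships <- function(d2) {
      u <- matrix(0, n, c)
      zero <- d2 < 1e-300
      anyzero <- rowSums(zero) > 0L
      if (any(anyzero))
        u[anyzero, ] <- zero[anyzero, , drop = FALSE] /
          rowSums(zero[anyzero, , drop = FALSE])
      if (any(!anyzero)) {
        r <- d2[!anyzero, , drop = FALSE]^(-1 / (m - 1))
        u[!anyzero, ] <- r / rowSums(r)
      }
      u
    }
    obj <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- sqdist(centers)
      u <- memberships(d2)
      obj <- c(obj, sum(u^m * d2))
      um <- u^m
      new_centers <- (t(um) %*% x) / colSums(um)
      shift <- max(abs(new_centers - centers))
      centers <- new_centers
      if (shift < tol) break
    }
    d2 <- sqdist(centers)
    u <- memberships(d2)
    rownames(u) <- rownames(x)
    colnames(centers) <- colnames(x)
    structure(list(membership = u, centers = centers, objective = obj,
                   iterations = it, m = m),
              class = "fuzzy_clustering")
  })
}

#' Prepare an expression matrix for pattern clustering
#'
#' Applies the log2(x + 1) transform, collapses samples to per-stage means,
#' and standardizes each gene to mean 0, sd 1 across stages. Genes with zero
#' variance across stages are excluded with a warning.
#'
#' @param fpkm genes x samples matrix on the linear (FPKM-like) scale.
#' @param samples sample sheet with `sample_id` and `stage` (factor ordered
#'   as the stage sequence).
#' @return genes x stages standardized matrix.
#' @export
prepare_expression <- function(fpkm, samples) {
  stopifnot(all(colnames(fpkm) %in% samples$sample_id))
  lg <- log2(fpkm + 1)
  stages <- levels(samples$stage)
  prof <- sapply(stages, function(st) {
    ids <- samples$sample_id[samples$stage == st]
    rowMeans(lg[, colnames(lg) %in% ids, drop = FALSE])
  })
  sds <- apply(prof, 1L, sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warnf("%d gene(s) with zero variance across stages excluded from standardization",
          sum(flat))
    prof <- prof[!flat, , drop = FALSE]; sds <- sds[!flat]
  }
  (prof - rowMeans(prof)) / sds
}

is_monotone <- function(v, direction, min_change, tol = 1e-8) {
  if (direction == "up") all(diff(v) >= -tol) && (v[length(v)] - v[1]) >= min_change
  else all(diff(v) <= tol) && (v[1] - v[length(v)]) >= min_change
}

#' Shortlist lost/gained targets by stage-wise expression pattern
#'
#' A lost target (released from canonical repression) is expected to rise
#' with disease stage; a gained target (newly repressed by the edited miRNA)
#' is expected to fall. A gene is shortlisted when its dominant cluster
#' (argmax membership, membership >= `dominance`) has a stage-monotone center
#' in the expected direction with a total change of at least `min_change`
#' standardized units.
#'
#' @param delta a [target_delta()] object.
#' @param clustering a [fuzzy_cmeans()] result on the same gene universe.
#' @param direction_for_lost,direction_for_gained expected center direction.
#' @param dominance minimum membership in the dominant cluster.
#' @param min_change minimum |last - first| center change (standardized
#'   units) for a cluster to count as monotone.
#' @return list with `lost` and `gained` character vectors of shortlisted
#'   genes.
#' @export
shortlist_by_pattern <- function(delta, clustering,
                                 direction_for_lost = "up",
                                 direction_for_gained = "down",
                                 dominance = 0.5, min_change = 0.25) {
  stopifnot(is(delta, "target_delta"), is(clustering, "fuzzy_clustering"))
  u <- clustering$membership
  ctr <- clustering$centers
  mono <- function(j, direction) is_monotone(ctr[j, ], direction, min_change)
  pick <- function(genes, direction) {
    keep <- character(0)
    for (g in genes) {
      if (!g %in% rownames(u)) {
        warnf("gene '%s' absent from clustering; skipped", g)
        next
      }
      j <- which.max(u[g, ])
      if (u[g, j] >= dominance && mono(j, direction)) keep <- c(keep, g)
    }
    keep
  }
  list(lost = pick(delta$lost$gene, direction_for_lost),
       gained = pick(delta$gained$gene, direction_for_gained))
}
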