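#' Restrict sites to the miRNA seed region
#'
#' Keeps sites with a mature-arm mapping at positions 2-8 (the seed). Sites
#' lacking a mature mapping are excluded with a warning, not an error. The
#' operation is a projection: applying it twice equals applying it once.
#'
#' @param sites a site table carrying a `mature_position` column (e.g. the
#'   `sites` slot of a [cohort_editing_matrix()]).
#' @return the subset with `mature_position` in 2..8.
#' @export
annotate_seed_sites <- function(sites) {
  s <- as.data.table(sites)
  missing_map <- is.na(s$mature_position)
  if (any(missing_map))
    warnf("%d site(s) lack a mature-arm mapping and were excluded",
          sum(missing_map))
  s[!missing_map & mature_position >= 2L & mature_position <= 8L]
}

# Spearman rho with midranks plus t-approximation p-value (shared by
# stage_trend and rank_correlation)
spearman_midrank <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (sd(x) == 0 || sd(y) == 0) {
    warnf("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

# Wilcoxon rank-sum, two-sided, normal approximation with tie correction
wilcoxon_rank_sum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stopf("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  N <- nx + ny
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1))
  z <- (U - nx * ny / 2) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))))
}

#' Stage-trend report for one editing site
#'
#' "Editing rises with disease progression" is operationalized as
#' nondecreasing per-stage mean editing along the declared stage order with a
#' total rise of at least `delta`, plus a Spearman rank correlation of
#' editing against the ordinal stage (midranks for ties). Uncovered samples
#' (NA) are excluded, never imputed.
#'
#' @param matrix a [cohort_editing_matrix()].
#' @param site_id row of the editing matrix to analyse.
#' @param delta minimum rise from first- to last-stage mean.
#' @return list with `stage_means`, `rho`, `p`, `monotone`.
#' @export
stage_trend <- function(matrix, site_id, delta = 0.01) {
  vals <- matrix$editing[site_id, ]
  stage <- factor(as.character(matrix$samples$stage), levels = matrix$stages)
  covered_stages <- unique(stage[!is.na(vals)])
  if (length(matrix$stages) < 2L)
    stopf("stage trend needs at least two stages")
  stage_means <- setNames(as.numeric(tapply(vals, stage, mean, na.rm = TRUE)),
                          matrix$stages)
  stage_means[is.nan(stage_means)] <- NA_real_
  obs <- stage_means[!is.na(stage_means)]
  monotone <- length(obs) >= 2L && all(diff(obs) >= 0) &&
    (obs[length(obs)] - obs[1]) >= delta
  sp <- spearman_midrank(as.integer(stage), vals)
  list(stage_means = stage_means, rho = sp$rho, p = sp$p,
       monotone = monotone)
}

#' Tumor-versus-normal report for one editing site
#'
#' @param matrix a [cohort_editing_matrix()]; its sample sheet's `group`
#'   column supplies the two groups.
#' @param site_id row of the editing matrix.
#' @param alpha significance level for calling the direction "increased".
#' @return list with `mean_tumor`, `mean_normal`, `p` (two-sided Wilcoxon
#'   rank-sum, normal approximation with tie correction), `direction` in
#'   "increased"/"decreased"/"none".
#' @export
tumor_vs_normal <- function(matrix, site_id, alpha = 0.05) {
  vals <- matrix$editing[site_id, ]
  grp <- matrix$samples$group
  tum <- vals[grp == "tumor" & !is.na(vals)]
  nor <- vals[grp == "normal" & !is.na(vals)]
  if (!length(tum) || !length(nor))
    stopf("both tumor and normal groups must be non-empty")
  w <- wilcoxon_rank_sum(tum, nor)
  direction <- if (w$p < alpha && mean(tum) > mean(nor)) "increased"
  else if (w$p < alpha && mean(tum) < mean(nor)) "decreased"
  else "none"
  list(mean_tumor = mean(tum), mean_normal = mean(nor), p = w$p,
       direction = direction)
}

#' Select seed-region editing hotspots from a cohort
#'
#' Applies, in order: the seed-region restriction, the cohort retention rule
#' (`"catholic"` = mean editing and TPM floors; `"tcga"` = editing above
#' threshold in enough samples), and the stage rule (`"catholic"` =
#' nondecreasing stage trend; `"tcga"` = increased in tumors vs normals).
#' Every excluded site is logged with the single filter that removed it.
#'
#' @param matrix a [cohort_editing_matrix()].
#' @param rule `"catholic"` (multistage trend cohort) or `"tcga"`
#'   (tumor/normal cohort).
#' @param config a [call_config()].
#' @param delta stage-trend minimum rise.
#' @param alpha two-group significance level.
#' @return list with `candidates` (data.table keyed by `mirna_id`,
#'   `mature_position` with per-stage means and statistics) and `log`
#'   (site_id, removed_by).
#' @export
select_candidates <- function(matrix, rule = c("catholic", "tcga"),
                              config = call_config(), delta = 0.01,
                              alpha = 0.05) {
  rule <- match.arg(rule)
  info <- matrix$sites
  log <- data.table(site_id = info$site_id, removed_by = "")
  seed_ok <- !is.na(info$mature_position) & info$mature_position >= 2L &
    info$mature_position <= 8L
  log[!seed_ok, removed_by := "NOT_SEED_REGION"]

  cohort <- apply_cohort_filters(matrix,
                                 if (rule == "catholic") "MEAN_AND_TPM"
                                 else "N_SAMPLES", config)
  drop_cohort <- setNames(cohort$detail$reason, cohort$detail$site_id)
  idx <- log$removed_by == "" & drop_cohort[log$site_id] != ""
  log[idx, removed_by := drop_cohort[site_id]]

  cands <- list()
  for (sid in log[removed_by == "", site_id]) {
    row <- info[site_id == sid]
    if (rule == "catholic") {
      tr <- stage_trend(matrix, sid, delta = delta)
      if (!tr$monotone) {
        log[site_id == sid, removed_by := "NO_STAGE_TREND"]
        next
      }
      cands[[length(cands) + 1L]] <- data.table(
        mirna_id = row$mature_id, mature_position = row$mature_position,
        site_id = sid, rho = tr$rho, p_trend = tr$p,
        t(setNames(as.numeric(tr$stage_means),
                   paste0("mean_", names(tr$stage_means)))),
        cohort_rule = rule)
    } else {
      tv <- tumor_vs_normal(matrix, sid, alpha = alpha)
      if (tv$direction != "increased") {
        log[site_id == sid, removed_by := "NOT_INCREASED_IN_TUMOR"]
        next
      }
      cands[[length(cands) + 1L]] <- data.table(
        mirna_id = row$mature_id, mature_position = row$mature_position,
        site_id = sid, mean_tumor = tv$mean_tumor,
        mean_normal = tv$mean_normal, p_group = tv$p, cohort_rule = rule)
    }
  }
  candidates <- if (length(cands)) rbindlist(cands, fill = TRUE)
  else data.table(mirna_id = character(0), mature_position = integer(0),
                  site_id = character(0), cohort_rule = character(0))
  list(candidates = candidates, log = log)
}

#' Intersect candidate lists from two cohorts
#'
#' Set intersection keyed by (mirna_id, mature_position); the result carries
#' both cohorts' statistics, suffixed `_a` and `_b`.
#'
#' @param candidates_a,candidates_b candidate tables from
#'   [select_candidates()].
#' @return the common candidates (possibly empty).
#' @export
intersect_cohorts <- function(candidates_a, candidates_b) {
  a <- as.data.table(candidates_a); b <- as.data.table(candidates_b)
  if (!nrow(a) || !nrow(b))
    return(data.table(mirna_id = character(0), mature_position = integer(0)))
  merge(a, b, by = c("mirna_id", "mature_position"),
        suffixes = c("_a", "_b"))
}
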