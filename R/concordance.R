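#' Per-sample global protein-mRNA concordance
#'
#' The headline statistic: for each sample, the Spearman correlation between
#' its protein and mRNA abundances over the matched pair set. Tumor and
#' control pair universes are built separately (a pair belongs to a scope's
#' universe when its protein value is observed in at least `min_obs_frac` of
#' that scope's samples), so the two scopes may use different pair counts.
#' Within the tumor arm, samples are split at the median rho into high/low
#' groups (ties at the median go to the low group).
#'
#' @param cohort a `paired_cohort`.
#' @param min_pairs minimum matched pairs per sample (samples below are
#'   excluded with a warning; default 100).
#' @param min_obs_frac minimum observed fraction defining a scope's universe.
#' @return data.frame of class `concordance_profile`: `sample`, `group`,
#'   `rho`, `n_pairs`, `rho_group` (tumor samples only). Scope pair counts in
#'   attribute `"pair_counts"`.
#' @export
compute_concordance <- function(cohort, min_pairs = 100, min_obs_frac = 0.8) {
  stopifnot(inherits(cohort, "paired_cohort"))
  grp <- cohort$meta$group
  scope <- ifelse(grp == "tumor", "tumor", "control")
  universes <- lapply(c(tumor = "tumor", control = "control"), function(sc) {
    cols <- which(scope == sc)
    obs <- rowMeans(!is.na(cohort$protein[, cols, drop = FALSE]))
    which(obs >= min_obs_frac)
  })
  rho <- n_pairs <- numeric(length(cohort$samples))
  for (j in seq_along(cohort$samples)) {
    u <- universes[[scope[j]]]
    x <- cohort$protein[u, j]
    y <- cohort$mrna[u, j]
    ok <- is.finite(x) & is.finite(y)
    n_pairs[j] <- sum(ok)
    rho[j] <- if (sum(ok) >= 3)
      suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
    else NA_real_
  }
  keep <- n_pairs >= min_pairs
  if (!all(keep))
    warnf("excluded %d sample(s) with < %d matched pairs", sum(!keep),
          min_pairs)
  out <- data.frame(sample = cohort$samples, group = grp, rho = rho,
                    n_pairs = as.integer(n_pairs),
                    stringsAsFactors = FALSE)[keep, ]
  out$rho_group <- NA_character_
  tum <- out$group == "tumor"
  if (sum(tum) >= 2) {
    med <- stats::median(out$rho[tum])
    out$rho_group[tum] <- ifelse(out$rho[tum] > med, "high", "low")
  }
  attr(out, "pair_counts") <- vapply(universes, length, 1L)
  class(out) <- c("concordance_profile", "data.frame")
  out
}

#' @export
print.concordance_profile <- function(x, ...) {
  cat(sprintf("concordance_profile: %d samples\n", nrow(x)))
  med <- tapply(x$rho, x$group, stats::median)
  for (g in names(med)) cat(sprintf("  median rho [%s] = %.3f\n", g, med[g]))
  pc <- attr(x, "pair_counts")
  if (!is.null(pc))
    cat(sprintf("  pair universes: tumor %d, control %d\n",
                pc["tumor"], pc["control"]))
  invisible(x)
}

#' Compare concordance between two sample groups
#'
#' Mann-Whitney U test on per-sample rho; `grouping` may be a metadata-like
#' factor/vector aligned with the profile rows or a logical vector.
#'
#' @param profiles a [compute_concordance] result.
#' @param grouping two-level grouping over the profile rows.
#' @return a [test_result].
#' @export
compare_groups <- function(profiles, grouping) {
  g <- factor(grouping)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stopf("compare_groups needs two nonempty groups")
  lv <- levels(g)
  mann_whitney_u(profiles$rho[g == lv[2]], profiles$rho[g == lv[1]])
}

#' Correlate concordance with a numeric covariate
#'
#' Pearson correlation of per-sample rho with a covariate (e.g. MKI67 protein
#' abundance or a per-sample gene-set score), computed within one group at a
#' time.
#'
#' @param profiles a [compute_concordance] result.
#' @param covariate numeric vector aligned with the profile rows.
#' @param group optional group label to subset to (e.g. `"tumor"`).
#' @return a [test_result].
#' @export
correlate_with <- function(profiles, covariate, group = NULL) {
  stopifnot(length(covariate) == nrow(profiles))
  keep <- if (is.null(group)) rep(TRUE, nrow(profiles))
          else profiles$group == group
  pearson_r(profiles$rho[keep], covariate[keep])
}

#' Concordance and survival: median split + continuous Cox
#'
#' Splits tumor samples at the median rho (ties to the low group), compares
#' the two Kaplan-Meier curves by log-rank, and additionally fits a
#' univariate Cox model on continuous rho.
#'
#' @param profiles a [compute_concordance] result.
#' @param meta cohort metadata containing `<endpoint>_time` / `_event`.
#' @param endpoint one of PFS, OS, RFS, LRFS, DRFS.
#' @return list with `km` (per-group KM curves), `logrank` and `cox`
#'   [test_result]s, and the split labels.
#' @export
concordance_survival <- function(profiles, meta,
                                 endpoint = c("PFS", "OS", "RFS", "LRFS",
                                              "DRFS")) {
  endpoint <- match.arg(endpoint)
  tum <- profiles[profiles$group == "tumor", ]
  mm <- meta[match(tum$sample, meta$sample), ]
  tt <- mm[[paste0(endpoint, "_time")]]
  evt <- mm[[paste0(endpoint, "_event")]]
  ok <- !is.na(tt) & !is.na(evt)
  tum <- tum[ok, ]; tt <- tt[ok]; evt <- evt[ok]
  if (length(unique(tum$rho_group)) < 2)
    stopf("median split degenerate (constant rho?)")
  if (sum(evt) == 0)
    return(list(km = NULL,
                logrank = test_result(NA, NA, n_used = length(tt),
                                      method = "log-rank", note = "no events"),
                cox = NULL, split = tum$rho_group))
  km <- lapply(split(seq_along(tt), tum$rho_group),
               function(i) km_curve(tt[i], evt[i]))
  lr <- logrank_test(tt, evt, tum$rho_group)
  cx <- cox_fit(tum$rho, tt, evt)
  list(km = km, logrank = lr, cox = cx, split = tum$rho_group)
}

#' Rank gene sets by correlation of per-sample scores with concordance
#'
#' @param profiles a [compute_concordance] result.
#' @param set_scores sets x samples score matrix ([ssgsea_matrix]); columns
#'   must cover the profile samples.
#' @param top_k how many sets to flag as top (capped at the number of sets).
#' @return data.frame ranked by Pearson r (descending) with `set`, `r`, `p`,
#'   `top` flag.
#' @export
concordance_geneset_ranking <- function(profiles, set_scores, top_k = 20) {
  if (!all(profiles$sample %in% colnames(set_scores)))
    stopf("score matrix does not cover the profile samples")
  sc <- set_scores[, profiles$sample, drop = FALSE]
  res <- t(apply(sc, 1, function(s) {
    tr <- pearson_r(s, profiles$rho)
    c(r = tr$estimate, p = tr$p_value)
  }))
  out <- data.frame(set = rownames(sc), r = res[, "r"], p = res[, "p"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$r), ]
  out$top <- seq_len(nrow(out)) <= min(top_k, nrow(out))
  out
}
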