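#' Classify each protein's trend across normal -> inflammation -> tumor
#'
#' Three pairwise Welch t-tests per gene (N-I, I-T, N-T). A step is called
#' `up`/`down` when its test has p < 0.05 and |log2 delta| > log2(1.2) (the
#' proteome fold-change gate), otherwise `flat`; the pattern is the ordered
#' pair (step1, step2), one of nine.
#'
#' @param mat log2-scale proteins x samples matrix (no missing values).
#' @param groups per-sample labels containing `normal`, `inflammation`,
#'   `tumor` (each with >= 2 samples).
#' @param p_max,effect_min step significance and effect gates.
#' @return data.frame of class `trend_patterns`: per gene the step calls,
#'   pattern, and the three tests' deltas and p-values (`delta_ni` etc. are
#'   later-group minus earlier-group).
#' @export
call_trend_patterns <- function(mat, groups, p_max = 0.05,
                                effect_min = log2(1.2)) {
  groups <- as.character(groups)
  for (g in group_levels)
    if (sum(groups == g) < 2) stopf("group '%s' needs >= 2 samples", g)
  if (anyNA(mat)) stopf("call_trend_patterns: impute missing values first")
  mN <- mat[, groups == "normal", drop = FALSE]
  mI <- mat[, groups == "inflammation", drop = FALSE]
  mT <- mat[, groups == "tumor", drop = FALSE]
  ni <- row_welch(mI, mN)   # inflammation - normal
  it <- row_welch(mT, mI)   # tumor - inflammation
  nt <- row_welch(mT, mN)   # tumor - normal
  call_step <- function(w)
    ifelse(w$p < p_max & abs(w$delta) > effect_min,
           ifelse(w$delta > 0, "up", "down"), "flat")
  step1 <- call_step(ni)
  step2 <- call_step(it)
  nt_call <- call_step(nt)
  out <- data.frame(gene = rownames(mat), step1 = step1, step2 = step2,
                    pattern = paste(step1, step2, sep = "-"),
                    nt_call = nt_call,
                    delta_ni = ni$delta, p_ni = ni$p,
                    delta_it = it$delta, p_it = it$p,
                    delta_nt = nt$delta, p_nt = nt$p,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("trend_patterns", "data.frame")
  out
}

#' Cluster highly variable proteins by k-means on z-scored profiles
#'
#' HVGs = genes whose MAD across samples exceeds the (1 - `mad_quantile`)
#' quantile; their per-gene z-scored profiles are clustered with k-means.
#' Each cluster's trajectory is the per-group mean of per-sample median
#' z-scores, with segmented-regression slopes between adjacent groups and an
#' overall normal -> tumor slope; a cluster is `up`/`down`-trending when the
#' overall tumor-minus-normal trajectory change exceeds `trend_min` in
#' absolute value, else `flat`. An inertia elbow curve over k = 2..10 is
#' attached.
#'
#' @param mat log2-scale proteins x samples matrix.
#' @param groups per-sample group labels (normal/inflammation/tumor).
#' @param mad_quantile fraction of genes retained as HVGs (0.5 = top 50% MAD;
#'   1 keeps all genes).
#' @param k number of clusters.
#' @param seed integer seed for k-means restarts.
#' @param trend_min minimum |tumor - normal| trajectory change (z units)
#'   for a cluster to count as trending.
#' @return list with `labels` (per HVG), `trajectories` (k x 3 matrix of
#'   group medians), `slopes` (k x 2 adjacent-segment slopes), `overall`
#'   (k-vector of overall slopes), `direction` (up/down/flat per cluster),
#'   `elbow` (data.frame k, inertia), `hvgs`.
#' @export
cluster_hvgs <- function(mat, groups, mad_quantile = 0.5, k = 4, seed = 1,
                         trend_min = 0.1) {
  groups <- factor(as.character(groups), levels = group_levels)
  mads <- apply(mat, 1, stats::mad)
  cut <- stats::quantile(mads, 1 - mad_quantile)
  hvgs <- rownames(mat)[mads >= cut]
  if (length(hvgs) < k) stopf("fewer HVGs (%d) than k (%d)", length(hvgs), k)
  z <- t(scale(t(mat[hvgs, , drop = FALSE])))
  z[!is.finite(z)] <- 0
  fit <- kmeans_fit(z, k, seed = seed)
  labels <- stats::setNames(fit$labels, hvgs)

  gidx <- as.integer(groups)   # 1 = normal, 2 = inflammation, 3 = tumor
  traj <- matrix(NA_real_, k, 3,
                 dimnames = list(paste0("cluster", seq_len(k)), group_levels))
  slopes <- matrix(NA_real_, k, 2,
                   dimnames = list(rownames(traj),
                                   c("normal_inflammation",
                                     "inflammation_tumor")))
  overall <- numeric(k)
  for (cl in seq_len(k)) {
    zz <- z[labels == cl, , drop = FALSE]
    med_s <- apply(zz, 2, stats::median)      # per-sample cluster median z
    gm <- tapply(med_s, groups, mean)
    traj[cl, ] <- gm[group_levels]
    # segmented regression between adjacent groups over samples
    for (seg in 1:2) {
      sel <- gidx %in% c(seg, seg + 1)
      slopes[cl, seg] <- stats::coef(
        stats::lm(med_s[sel] ~ gidx[sel]))[2]
    }
    overall[cl] <- stats::coef(stats::lm(med_s ~ gidx))[2]
  }
  direction <- ifelse(traj[, "tumor"] - traj[, "normal"] > trend_min, "up",
                ifelse(traj[, "tumor"] - traj[, "normal"] < -trend_min,
                       "down", "flat"))
  elbow <- data.frame(k = 2:10, inertia = vapply(2:10, function(kk) {
    if (kk > nrow(z)) NA_real_ else kmeans_fit(z, kk, seed = seed)$inertia
  }, numeric(1)))
  list(labels = labels, trajectories = traj, slopes = slopes,
       overall = overall, direction = direction, elbow = elbow, hvgs = hvgs)
}

#' Merge trend patterns and cluster trends into the five-class signature
#'
#' Mapping (all classes additionally require membership in a cluster trending
#' in the matching direction):
#' * `MIMIC-UP` — pattern (up, flat) with a significant overall N -> T
#'   increase: the gene rises with inflammation and tumors cannot be
#'   discriminated from inflammation.
#' * `SPECIFIC-UP` — pattern (flat, up): tumor-specific increase.
#' * `VAGUE-UP` — overall N -> T increase with steps (up, up) or two
#'   sub-threshold steps (flat, flat).
#' * `MIMIC-DOWN` / `SPECIFIC-DOWN` mirror the up cases.
#' * everything else (including opposing steps such as up-down) — `NONE`.
#'
#' @param patterns a [call_trend_patterns] result.
#' @param clusters a [cluster_hvgs] result.
#' @return list with `table` (gene, pattern, cluster, cluster_trend,
#'   final_class) over the HVG set and `counts` per class.
#' @export
build_signature <- function(patterns, clusters) {
  genes <- clusters$hvgs
  missing <- setdiff(genes, patterns$gene)
  if (length(missing)) {
    warnf("%d HVGs absent from the pattern table -> NONE", length(missing))
    genes <- setdiff(genes, missing)
  }
  pp <- patterns[match(genes, patterns$gene), ]
  cl <- clusters$labels[genes]
  cdir <- clusters$direction[cl]

  classify <- function(s1, s2, ntc, cd) {
    if (cd == "up" && ntc == "up") {
      if (s1 == "up" && s2 == "flat") return("MIMIC-UP")
      if (s1 == "flat" && s2 == "up") return("SPECIFIC-UP")
      if ((s1 == "up" && s2 == "up") || (s1 == "flat" && s2 == "flat"))
        return("VAGUE-UP")
    }
    if (cd == "up" && s1 == "flat" && s2 == "up") return("SPECIFIC-UP")
    if (cd == "down" && ntc == "down") {
      if (s1 == "down" && s2 == "flat") return("MIMIC-DOWN")
      if (s1 == "flat" && s2 == "down") return("SPECIFIC-DOWN")
    }
    if (cd == "down" && s1 == "flat" && s2 == "down") return("SPECIFIC-DOWN")
    "NONE"
  }
  final <- mapply(classify, pp$step1, pp$step2, pp$nt_call, cdir)
  tab <- data.frame(gene = genes, pattern = pp$pattern,
                    kmeans_cluster = unname(cl),
                    cluster_trend = unname(cdir),
                    final_class = unname(final),
                    stringsAsFactors = FALSE)
  counts <- table(factor(final, levels = c("MIMIC-UP", "VAGUE-UP",
                                           "SPECIFIC-UP", "MIMIC-DOWN",
                                           "SPECIFIC-DOWN", "NONE")))
  list(table = tab, counts = c(counts))
}
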