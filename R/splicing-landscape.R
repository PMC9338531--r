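#' Call aberrant alternative-splicing events
#'
#' Per event, a two-sided Mann-Whitney test of tumor vs control inclusion
#' levels; BH adjustment is applied once across all tested events of all five
#' types jointly. An event passes when |delta IncLevel| (tumor mean minus
#' control mean) exceeds `delta_min` AND the adjusted p falls below `q_max`
#' (defaults: 0.05 and 0.01). Events with fewer than 3 non-missing inclusion
#' levels in either group are skipped with a reason. When the table was read
#' from rMATS output, `use_table_stats = TRUE` takes the file's PValue/FDR
#' columns instead of re-testing.
#'
#' @param events a `splice_event_table`.
#' @param delta_min minimum |delta IncLevel| (default 0.05).
#' @param q_max maximum adjusted p (default 0.01).
#' @param use_table_stats reuse PValue/FDR columns parsed from rMATS files.
#' @return data.frame of class `aase_calls`: `event_id`, `type`, `gene`,
#'   `delta_inclevel`, `p`, `adj_p`, `passes`, `skipped`, `skip_reason`.
#' @export
call_aase <- function(events, delta_min = 0.05, q_max = 0.01,
                      use_table_stats = FALSE) {
  stopifnot(inherits(events, "splice_event_table"))
  grp <- as_group2(events$groups)
  if (!any(grp == "control")) stopf("call_aase: no control samples")
  if (!any(grp == "tumor")) stopf("call_aase: no tumor samples")
  it <- which(grp == "tumor"); ic <- which(grp == "control")
  E <- nrow(events$info)
  delta <- p <- rep(NA_real_, E)
  skip <- rep(FALSE, E)
  reason <- rep(NA_character_, E)
  for (e in seq_len(E)) {
    a <- events$psi[e, it]; b <- events$psi[e, ic]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3 || length(b) < 3) {
      skip[e] <- TRUE
      reason[e] <- sprintf("<3 non-missing IncLevels (tumor %d, control %d)",
                           length(a), length(b))
      next
    }
    delta[e] <- mean(a) - mean(b)
    p[e] <- if (use_table_stats) events$info$PValue[e]
            else mann_whitney_u(a, b)$p_value
  }
  adj_p <- rep(NA_real_, E)
  if (use_table_stats) adj_p[!skip] <- events$info$FDR[!skip]
  else adj_p[!skip] <- bh_adjust(p[!skip])
  passes <- !skip & abs(delta) > delta_min & adj_p < q_max
  out <- data.frame(event_id = events$info$event_id,
                    type = events$info$type, gene = events$info$gene,
                    delta_inclevel = delta, p = p, adj_p = adj_p,
                    passes = passes, skipped = skip, skip_reason = reason,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "thresholds") <- c(delta_min = delta_min, q_max = q_max)
  class(out) <- c("aase_calls", "data.frame")
  out
}

#' @export
print.aase_calls <- function(x, ...) {
  cat(sprintf("aase_calls: %d events tested, %d aberrant (%d skipped)\n",
              sum(!x$skipped), sum(x$passes), sum(x$skipped)))
  if (any(x$passes)) print(table(x$type[x$passes]))
  invisible(x)
}

#' Summarize the aberrant-splicing landscape
#'
#' Pure bookkeeping over passing calls: events per type, genes affected
#' (total, and by exactly one type), and the pairwise type-intersection
#' matrix of affected gene sets.
#'
#' @param calls a [call_aase] result.
#' @return list with `events_per_type`, `n_genes`, `genes_single_type`,
#'   `genes_per_type`, `type_intersections` (5 x 5 gene-count matrix),
#'   `gene_types` (list gene -> types).
#' @export
landscape_summary <- function(calls) {
  hits <- calls[calls$passes, ]
  events_per_type <- table(factor(hits$type, levels = ase_types))
  gene_types <- lapply(split(hits$type, hits$gene), unique)
  genes_per_type <- vapply(ase_types, function(tp)
    sum(vapply(gene_types, function(ts) tp %in% ts, TRUE)), 1L)
  inter <- matrix(0L, 5, 5, dimnames = list(ase_types, ase_types))
  for (i in seq_along(ase_types)) for (j in seq_along(ase_types)) {
    inter[i, j] <- sum(vapply(gene_types, function(ts)
      all(ase_types[c(i, j)] %in% ts), TRUE))
  }
  list(events_per_type = c(events_per_type),
       n_genes = length(gene_types),
       genes_single_type = sum(lengths(gene_types) == 1L),
       genes_per_type = genes_per_type,
       type_intersections = inter,
       gene_types = gene_types)
}

#' Univariate Cox screen of passing events against a survival endpoint
#'
#' For each aberrant event, a univariate Cox model with its inclusion level
#' as continuous covariate over tumor samples with a known endpoint.
#' Constant-inclusion events are reported as rejected. Raw p < 0.05 flags an
#' event progression-related; BH-adjusted values are reported alongside
#' (`use_adjusted = TRUE` gates on them instead).
#'
#' @param calls a [call_aase] result.
#' @param events the `splice_event_table` the calls came from.
#' @param meta metadata with `<endpoint>_time` / `_event` columns.
#' @param endpoint survival endpoint (default PFS).
#' @param p_max significance gate (default 0.05).
#' @param use_adjusted gate on BH-adjusted p instead of raw p.
#' @return data.frame: per passing event `beta`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `adj_p`, `significant`, `note`.
#' @export
progression_aase <- function(calls, events, meta,
                             endpoint = c("PFS", "OS", "RFS", "LRFS", "DRFS"),
                             p_max = 0.05, use_adjusted = FALSE) {
  endpoint <- match.arg(endpoint)
  grp <- as_group2(events$groups)
  tum <- names(events$groups)[grp == "tumor"]
  mm <- meta[match(tum, meta$sample), ]
  tt <- mm[[paste0(endpoint, "_time")]]
  evt <- mm[[paste0(endpoint, "_event")]]
  ok <- !is.na(tt) & !is.na(evt)
  if (sum(evt[ok]) == 0) stopf("no events observed at endpoint %s", endpoint)
  sel <- which(calls$passes)
  rows <- lapply(sel, function(e) {
    x <- events$psi[calls$event_id[e] == rownames(events$psi), tum][ok]
    base <- data.frame(event_id = calls$event_id[e], type = calls$type[e],
                       gene = calls$gene[e], stringsAsFactors = FALSE)
    if (anyNA(x) || stats::sd(x) == 0)
      return(cbind(base, beta = NA, hr = NA, ci_low = NA, ci_high = NA,
                   p = NA, note = if (anyNA(x)) "missing IncLevels"
                                  else "constant covariate"))
    tr <- cox_fit(x, tt[ok], evt[ok])
    cbind(base, beta = tr$estimate, hr = exp(tr$estimate),
          ci_low = exp(tr$ci_low), ci_high = exp(tr$ci_high),
          p = tr$p_value, note = tr$note %||% "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adj_p <- bh_adjust(out$p)
  gate <- if (use_adjusted) out$adj_p else out$p
  out$significant <- !is.na(gate) & gate < p_max
  out
}

#' Rank splicing factors by correlation with aberrant-event inclusion
#'
#' Pearson correlation of each splicing factor's protein abundance with each
#' passing event's inclusion level across tumor samples. Per factor: the
#' count of strong correlations (|r| > `strong_min`) and mean |r|; factors
#' are ranked by strong count with mean |r| as tiebreak. Two rankings are
#' built (all aberrant events; progression-related events) and the recurrent
#' set is the intersection of their top-k.
#'
#' @param sf_list splicing-factor gene IDs (absent ones skipped, warned).
#' @param protein_matrix log2 proteins x samples matrix (cohort samples).
#' @param events the `splice_event_table`.
#' @param calls a [call_aase] result.
#' @param progression a [progression_aase] result (or NULL to skip the second
#'   ranking).
#' @param top_k ranking depth for the recurrent set (default 20).
#' @param strong_min threshold defining a strong correlation (default 0.6).
#' @return list with `correlations` (SF x event r matrix), `ranking_all`,
#'   `ranking_progression` (data.frames sorted by rank), `recurrent`
#'   (character vector), `strong_genes` (list SF -> genes of its strong
#'   events).
#' @export
sf_correlation_ranking <- function(sf_list, protein_matrix, events, calls,
                                   progression = NULL, top_k = 20,
                                   strong_min = 0.6) {
  grp <- as_group2(events$groups)
  tum <- intersect(names(events$groups)[grp == "tumor"],
                   colnames(protein_matrix))
  sfs <- sf_list[sf_list %in% rownames(protein_matrix)]
  if (length(sfs) < length(sf_list))
    warnf("%d splicing factor(s) absent from the protein matrix, skipped",
          length(sf_list) - length(sfs))
  if (!length(sfs)) stopf("no splicing factor present in the protein matrix")
  pass_ids <- calls$event_id[calls$passes]
  if (!length(pass_ids)) stopf("no passing events to correlate")
  P <- events$psi[pass_ids, tum, drop = FALSE]
  X <- protein_matrix[sfs, tum, drop = FALSE]
  r <- matrix(NA_real_, length(sfs), length(pass_ids),
              dimnames = list(sfs, pass_ids))
  for (i in seq_along(sfs)) {
    r[i, ] <- suppressWarnings(
      stats::cor(X[i, ], t(P), use = "pairwise.complete.obs"))
  }
  rank_over <- function(event_ids) {
    rr <- r[, event_ids, drop = FALSE]
    strong <- rowSums(abs(rr) > strong_min, na.rm = TRUE)
    meanr <- rowMeans(abs(rr), na.rm = TRUE)
    df <- data.frame(sf = sfs, n_strong = strong, mean_abs_r = meanr,
                     stringsAsFactors = FALSE, row.names = NULL)
    df <- df[order(-df$n_strong, -df$mean_abs_r), ]
    df$rank <- seq_len(nrow(df))
    df
  }
  ranking_all <- rank_over(pass_ids)
  ranking_prog <- NULL
  recurrent <- ranking_all$sf[seq_len(min(top_k, nrow(ranking_all)))]
  if (!is.null(progression)) {
    prog_ids <- intersect(progression$event_id[progression$significant],
                          pass_ids)
    if (length(prog_ids)) {
      ranking_prog <- rank_over(prog_ids)
      recurrent <- intersect(
        ranking_all$sf[seq_len(min(top_k, nrow(ranking_all)))],
        ranking_prog$sf[seq_len(min(top_k, nrow(ranking_prog)))])
    }
  }
  ev_gene <- stats::setNames(calls$gene[calls$passes], pass_ids)
  strong_genes <- lapply(stats::setNames(sfs, sfs), function(sf)
    unique(unname(ev_gene[which(abs(r[sf, ]) > strong_min)])))
  list(correlations = r, ranking_all = ranking_all,
       ranking_progression = ranking_prog, recurrent = recurrent,
       strong_genes = strong_genes)
}
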