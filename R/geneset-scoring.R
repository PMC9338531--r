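#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value on the 2x2 membership table of a hit
#' list against a gene set within a finite universe.
#'
#' @param hit_genes character vector of hits (must lie in `universe`).
#' @param gene_set character vector of set members.
#' @param universe background gene universe (nonempty).
#' @return list with `overlap`, `expected`, `fold_enrichment`, `p_value`.
#' @export
ora <- function(hit_genes, gene_set, universe) {
  if (!length(universe)) stopf("ora: empty universe")
  universe <- unique(universe)
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% universe)) stopf("ora: hits must lie in universe")
  set_in <- intersect(unique(gene_set), universe)
  if (!length(set_in)) stopf("ora: gene set does not intersect universe")
  N <- length(universe); K <- length(set_in); n <- length(hit_genes)
  k <- length(intersect(hit_genes, set_in))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  list(overlap = k, expected = expected,
       fold_enrichment = if (expected > 0) k / expected else NA_real_,
       p_value = p)
}

#' ORA across a gene-set collection with BH adjustment
#'
#' @inheritParams ora
#' @param gene_sets named list of sets (e.g. from [read_gmt]).
#' @return data.frame with one row per set, BH q-values, sorted by p.
#' @export
ora_collection <- function(hit_genes, gene_sets, universe) {
  rows <- lapply(names(gene_sets), function(nm) {
    r <- ora(hit_genes, gene_sets[[nm]], universe)
    data.frame(set = nm, overlap = r$overlap, expected = r$expected,
               fold_enrichment = r$fold_enrichment, p = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), ]
}

#' Preranked gene-set enrichment (weighted Kolmogorov-Smirnov)
#'
#' Walks the ranking from top to bottom accumulating |score|^1 weight inside
#' the set against a uniform penalty outside it; ES is the maximum deviation
#' of the running sum. Significance by gene-label permutation: NES = ES
#' normalized by the mean |permutation ES| of matching sign, nominal p the
#' matching-sign permutation tail.
#'
#' @param scores named numeric vector (unique gene names), will be sorted
#'   decreasing.
#' @param gene_set character vector; needs >= `min_size` members in the
#'   ranking.
#' @param n_perm number of gene-label permutations.
#' @param seed integer seed for the permutations.
#' @param min_size minimum set size after intersection (default 5).
#' @return list with `es`, `nes`, `p_value`, `leading_edge`.
#' @export
gsea_preranked <- function(scores, gene_set, n_perm = 1000, seed = 1,
                           min_size = 5) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stopf("scores must be uniquely named by gene")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  K <- sum(hit)
  if (K < min_size)
    stopf("gene set too small after intersection (%d < %d)", K, min_size)
  es_stat <- function(hit) {
    w <- abs(s) * hit
    p_hit <- cumsum(w) / sum(w)
    p_miss <- cumsum(!hit) / (length(s) - sum(hit))
    dev <- p_hit - p_miss
    dev[which.max(abs(dev))]
  }
  es <- es_stat(hit)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    es_stat(sample(hit))
  }, numeric(1))
  same <- perm[sign(perm) == sign(es)]
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  w <- abs(s) * hit
  dev <- cumsum(w) / sum(w) - cumsum(!hit) / (length(s) - K)
  peak <- which.max(abs(dev))
  le <- if (es >= 0) names(s)[seq_len(peak)][hit[seq_len(peak)]]
        else names(s)[peak:length(s)][hit[peak:length(s)]]
  list(es = unname(es), nes = unname(nes), p_value = p, leading_edge = le)
}

#' Preranked enrichment over a collection, with permutation-based FDR
#'
#' @inheritParams gsea_preranked
#' @param gene_sets named list of sets.
#' @return data.frame per set with ES, NES, nominal p and BH FDR across the
#'   collection's permutation p-values.
#' @export
gsea_collection <- function(scores, gene_sets, n_perm = 1000, seed = 1,
                            min_size = 5) {
  rows <- lapply(names(gene_sets), function(nm) {
    r <- tryCatch(gsea_preranked(scores, gene_sets[[nm]], n_perm, seed,
                                 min_size),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(set = nm, es = r$es, nes = r$nes, p = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no gene set passed the size filter")
  out$fdr <- bh_adjust(out$p)
  out[order(out$p), ]
}

#' Per-sample gene-set scores (ssGSEA formulation)
#'
#' For each sample, genes are ranked by expression and a weighted-ECDF
#' difference statistic (exponent `alpha`) is accumulated along the ranking
#' for each set; scores are then linearly rescaled per set across samples to
#' \[-1, 1\]. Scores depend on each sample's expression only through ranks, so
#' they are invariant to sample-wise monotone transforms.
#'
#' @param expr genes x samples expression matrix without missing values.
#' @param gene_sets named list of sets; sets without expressed members error.
#' @param alpha rank-weight exponent (default 0.25).
#' @return sets x samples numeric matrix.
#' @export
ssgsea_matrix <- function(expr, gene_sets, alpha = 0.25) {
  if (anyNA(expr)) stopf("ssgsea_matrix: expression must be complete")
  G <- nrow(expr)
  for (nm in names(gene_sets))
    if (!any(gene_sets[[nm]] %in% rownames(expr)))
      stopf("gene set '%s' has no expressed members", nm)
  scores <- matrix(0, length(gene_sets), ncol(expr),
                   dimnames = list(names(gene_sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(expr[, j], decreasing = TRUE)
    rw <- r[ord]^alpha
    gn <- rownames(expr)[ord]
    for (i in seq_along(gene_sets)) {
      hit <- gn %in% gene_sets[[i]]
      p_in <- cumsum(rw * hit) / sum(rw * hit)
      p_out <- cumsum(!hit) / (G - sum(hit))
      scores[i, j] <- sum(p_in - p_out)
    }
  }
  # rescale per set across samples to [-1, 1]
  for (i in seq_len(nrow(scores))) {
    rng <- range(scores[i, ])
    scores[i, ] <- if (diff(rng) == 0) 0 else
      2 * (scores[i, ] - rng[1]) / diff(rng) - 1
  }
  scores
}
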