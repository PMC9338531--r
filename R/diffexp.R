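#' Layer thresholds for differential expression
#'
#' Transcriptome: |log2 FC| > log2(1.5); proteome: |log2 FC| > log2(1.2);
#' both with p < 0.05 (raw p drives the call, BH q reported alongside).
#' @noRd
de_threshold <- function(layer) {
  switch(layer, mrna = log2(1.5), protein = log2(1.2),
         stopf("unknown layer '%s'", layer))
}

#' Differential expression between tumor and control
#'
#' Per-gene moderated t-statistics (limma empirical-Bayes variance shrinkage)
#' on log2-scale abundances after per-sample median centering, with the
#' layer-specific fold-change gates: |log2 FC| > log2(1.5) for transcripts and
#' > log2(1.2) for proteins, combined with p < 0.05. A plain Welch t
#' alternative is available via `method = "welch"`.
#'
#' @param mat log2-scale genes x samples matrix (no missing values).
#' @param groups per-sample grouping collapsed to tumor vs control (any
#'   non-"tumor" label counts as control).
#' @param layer `"protein"` or `"mrna"` (sets the fold-change gate).
#' @param method `"limma"` (default) or `"welch"`.
#' @param normalize median-center each sample first (default TRUE).
#' @return data.frame of class `de_result`: `gene`, `layer`, `log2fc`
#'   (tumor - control), `p`, `q`, `status` in up/down/ns.
#' @export
run_de <- function(mat, groups, layer = c("protein", "mrna"),
                   method = c("limma", "welch"), normalize = TRUE) {
  layer <- match.arg(layer)
  method <- match.arg(method)
  g2 <- as_group2(groups)
  if (any(table(g2) < 2)) stopf("run_de needs >= 2 samples per group")
  if (anyNA(mat)) stopf("run_de: impute missing values first")
  if (normalize) mat <- sweep(mat, 2, apply(mat, 2, stats::median))
  if (method == "limma") {
    design <- stats::model.matrix(~g2)
    fit <- limma::eBayes(limma::lmFit(mat, design))
    log2fc <- fit$coefficients[, 2]
    p <- fit$p.value[, 2]
  } else {
    rw <- row_welch(mat[, g2 == "tumor", drop = FALSE],
                    mat[, g2 == "control", drop = FALSE])
    log2fc <- rw$delta
    p <- rw$p
  }
  thr <- de_threshold(layer)
  status <- ifelse(p < 0.05 & log2fc > thr, "up",
                   ifelse(p < 0.05 & log2fc < -thr, "down", "ns"))
  out <- data.frame(gene = rownames(mat), layer = layer,
                    log2fc = unname(log2fc), p = unname(p),
                    q = unname(bh_adjust(p)), status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- thr
  class(out) <- c("de_result", "data.frame")
  out
}

#' Cross-layer concordance classification of differential genes
#'
#' CO-UP: up in both layers; CO-DOWN: down in both; DISCORDANT: significant
#' with opposite signs; NONE: not significant in at least one layer.
#'
#' @param de_protein,de_mrna [run_de] tables over the same gene universe.
#' @return list with `table` (gene, protein_status, mrna_status, class) and
#'   `counts` (named class counts).
#' @export
classify_concordance <- function(de_protein, de_mrna) {
  if (!setequal(de_protein$gene, de_mrna$gene))
    stopf("classify_concordance: gene universes differ")
  m <- de_mrna[match(de_protein$gene, de_mrna$gene), ]
  sp <- de_protein$status
  sm <- m$status
  cls <- ifelse(sp == "up" & sm == "up", "CO-UP",
         ifelse(sp == "down" & sm == "down", "CO-DOWN",
         ifelse(sp != "ns" & sm != "ns", "DISCORDANT", "NONE")))
  tab <- data.frame(gene = de_protein$gene, protein_status = sp,
                    mrna_status = sm, class = cls, stringsAsFactors = FALSE)
  counts <- table(factor(cls, levels = c("CO-UP", "CO-DOWN", "DISCORDANT",
                                         "NONE")))
  list(table = tab, counts = c(counts))
}
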