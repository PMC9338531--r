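#' Univariate logistic screen of proteins
#'
#' One single-covariate logistic regression per protein against the binary
#' tumor/control label; proteins with Wald p < `p_max` are kept. Constant
#' proteins are excluded with a warning; separation-flagged proteins are kept
#' (their shift is, if anything, extreme) and marked.
#'
#' @param protein_matrix log2 proteins x samples matrix (no missing values).
#' @param labels binary labels (tumor = 1) or group vector.
#' @param p_max Wald significance gate (default 0.05).
#' @return list with `significant` (gene IDs), `table` (gene, beta, p,
#'   separation flag).
#' @export
univariate_screen <- function(protein_matrix, labels, p_max = 0.05) {
  y <- normalize_labels(labels)
  rows <- lapply(rownames(protein_matrix), function(g) {
    x <- protein_matrix[g, ]
    if (stats::sd(x) == 0) {
      warnf("univariate_screen: '%s' constant, excluded", g)
      return(NULL)
    }
    fit <- logistic_fit(x, y)
    data.frame(gene = g, beta = unname(fit$coefficients[2]),
               p = unname(fit$p[2]), separation = fit$separation,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sig <- tab$gene[(!is.na(tab$p) & tab$p < p_max) | tab$separation]
  list(significant = sig, table = tab)
}

normalize_labels <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  as.integer(as_group2(labels) == "tumor")
}

#' Selection-frequency lasso over repeated cross-validation
#'
#' Repeats `n_iterations` times: a fresh 10-fold split chooses lambda by CV
#' (1-SE rule), the model is refit at that lambda, and the nonzero support is
#' recorded. A protein's selection frequency is the fraction of iterations in
#' which it was selected; the selected set keeps frequencies >= `freq_min`.
#'
#' @param X samples x proteins matrix (standardized internally by glmnet).
#' @param labels binary labels (tumor = 1).
#' @param n_iterations repeats of the full CV-lasso (default 200).
#' @param freq_min selection-frequency cutoff (default 0.5; 0 yields the
#'   union of all supports).
#' @param seed integer seed; iteration i uses fold seed `seed + i`.
#' @param n_folds CV folds (default 10).
#' @param rule lambda rule, `"1se"` (default) or `"min"`.
#' @return list with `frequencies` (named, in \[0, 1\]) and `selected`.
#' @export
lasso_select <- function(X, labels, n_iterations = 200, freq_min = 0.5,
                         seed = 1, n_folds = 10, rule = "1se") {
  X <- as.matrix(X)
  if (ncol(X) == 0) stopf("lasso_select: empty candidate set")
  y <- normalize_labels(labels)
  counts <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (i in seq_len(n_iterations)) {
    lam <- cv_lambda(X, y, n_folds = n_folds, seed = seed + i, rule = rule)
    cv <- attr(lam, "cv_fit")
    beta <- stats::coef(cv, s = lam)[-1, 1]
    counts <- counts + (beta != 0)
  }
  freq <- counts / n_iterations
  # freq_min = 0 degenerates to the union of all supports
  list(frequencies = freq,
       selected = names(freq)[freq >= freq_min & freq > 0])
}

#' Stepwise logistic refinement of the lasso-selected set
#'
#' Backward stepwise logistic regression starting from the full model on the
#' selected proteins. The default criterion (`"fwer"`) eliminates, one at a
#' time, the covariate with the largest likelihood-ratio p-value until every
#' remaining covariate has p below `alpha / m_universe` — a Bonferroni gate
#' referred to the full screened protein universe. Candidates that reach this
#' stage have already survived two marginal screens and the repeated
#' cross-validated lasso on the same samples, so any chance association that
#' got this far is, within the realized sample, indistinguishable from
#' signal; only a multiplicity penalty that remembers how many proteins were
#' screened can remove it. An information-criterion alternative
#' (`criterion = "aic"`, bidirectional `stats::step`) is available but
#' retains every screen survivor by construction. Reaching the empty model
#' yields an empty set (not an error).
#'
#' @param selected candidate protein IDs (nonempty).
#' @param X samples x proteins matrix covering them.
#' @param labels binary labels (tumor = 1).
#' @param criterion `"fwer"` (default) or `"aic"`.
#' @param m_universe size of the originally screened protein universe used by
#'   the Bonferroni gate; defaults to `length(selected)`.
#' @param alpha family-wise error level of the `"fwer"` gate.
#' @return character vector of retained protein IDs (possibly empty).
#' @export
stepwise_refine <- function(selected, X, labels,
                            criterion = c("fwer", "aic"),
                            m_universe = NULL, alpha = 0.05) {
  criterion <- match.arg(criterion)
  if (!length(selected)) stopf("stepwise_refine: empty selected set")
  y <- normalize_labels(labels)
  dat <- data.frame(y = y, as.data.frame(X[, selected, drop = FALSE]))
  key <- stats::setNames(selected, make.names(selected))

  if (criterion == "aic") {
    full <- suppressWarnings(
      stats::glm(y ~ ., data = dat, family = stats::binomial()))
    sc <- suppressWarnings(
      stats::step(full, direction = "both", trace = 0,
                  scope = list(lower = y ~ 1, upper = stats::formula(full))))
    kept <- setdiff(names(stats::coef(sc)), "(Intercept)")
    return(unname(key[names(key) %in% kept]))
  }

  m <- m_universe %||% length(selected)
  gate <- alpha / m
  # marginal gate first: in a joint model of co-selected candidates the
  # conditional tests are anti-conservative (n is small, the candidates were
  # all picked on these samples), so each candidate must first clear the
  # Bonferroni level on its own. LRT rather than Wald throughout: robust to
  # near-separation of strong markers.
  null_dev <- suppressWarnings(
    stats::glm(y ~ 1, data = dat, family = stats::binomial()))$deviance
  marg_p <- vapply(names(key), function(v) {
    fit <- suppressWarnings(
      stats::glm(stats::reformulate(v, "y"), data = dat,
                 family = stats::binomial()))
    stats::pchisq(null_dev - fit$deviance, df = 1, lower.tail = FALSE)
  }, numeric(1))
  current <- names(key)[marg_p <= gate]
  # backward elimination among the survivors for a minimal adequate model
  while (length(current) > 1) {
    fit <- suppressWarnings(
      stats::glm(stats::reformulate(current, "y"), data = dat,
                 family = stats::binomial()))
    dr <- suppressWarnings(stats::drop1(fit, test = "LRT"))
    p <- dr[["Pr(>Chi)"]][-1]
    names(p) <- rownames(dr)[-1]
    worst <- which.max(p)
    if (p[worst] > gate) current <- setdiff(current, names(p)[worst])
    else break
  }
  unname(key[names(key) %in% current])
}

#' Benchmark candidate and reference markers by ROC AUC
#'
#' Rank-based AUC per marker using protein abundance as the score.
#'
#' @param final candidate marker IDs.
#' @param reference_markers reference marker IDs (must be present).
#' @param protein_matrix log2 proteins x samples matrix.
#' @param labels binary labels (tumor = 1).
#' @return data.frame (`gene`, `role`, `auc`) sorted by AUC descending.
#' @export
benchmark_auc <- function(final, reference_markers, protein_matrix, labels) {
  y <- normalize_labels(labels)
  all_m <- c(final, reference_markers)
  missing <- setdiff(all_m, rownames(protein_matrix))
  if (length(missing))
    stopf("markers absent from matrix: %s", paste(missing, collapse = ", "))
  out <- data.frame(
    gene = all_m,
    role = c(rep("candidate", length(final)),
             rep("reference", length(reference_markers))),
    auc = vapply(all_m, function(g) roc_auc(protein_matrix[g, ], y),
                 numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$auc), ]
}

#' Run the full diagnostic-marker funnel
#'
#' Stage 1: differentially expressed proteins (proteome thresholds) and the
#' univariate logistic screen; stage 2: their overlap enters the repeated
#' CV-lasso; stage 3: selection frequencies gate the lasso set; stage 4:
#' stepwise AIC refinement yields the final markers, benchmarked by ROC
#' against the reference markers.
#'
#' @param protein_matrix log2 proteins x samples matrix (imputed).
#' @param groups per-sample group labels (collapsed to tumor vs control).
#' @param reference_markers reference marker IDs for the AUC benchmark.
#' @param n_iterations,freq_min,seed lasso stage parameters ([lasso_select]).
#' @param de_method DE engine for stage 1 ([run_de]).
#' @return object of class `funnel_report`.
#' @export
run_funnel <- function(protein_matrix, groups, reference_markers = character(0),
                       n_iterations = 200, freq_min = 0.5, seed = 1,
                       de_method = "limma") {
  y <- normalize_labels(groups)
  de <- run_de(protein_matrix, groups, layer = "protein", method = de_method)
  stage1_de <- de$gene[de$status != "ns"]
  scr <- univariate_screen(protein_matrix, y)
  stage1_logistic <- scr$significant
  overlap <- intersect(stage1_de, stage1_logistic)
  if (!length(overlap)) stopf("run_funnel: empty stage-2 overlap")
  Xo <- t(protein_matrix[overlap, , drop = FALSE])
  las <- lasso_select(Xo, y, n_iterations = n_iterations,
                      freq_min = freq_min, seed = seed)
  final <- if (length(las$selected))
    stepwise_refine(las$selected, Xo, y,
                    m_universe = nrow(protein_matrix)) else character(0)
  auc <- if (length(c(final, reference_markers)))
    benchmark_auc(final, reference_markers, protein_matrix, y) else NULL
  structure(list(stage1_de = stage1_de, stage1_logistic = stage1_logistic,
                 stage2_overlap = overlap,
                 lasso_frequencies = las$frequencies,
                 lasso_selected = las$selected,
                 final_markers = final, auc = auc),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("diagnostic biomarker funnel\n")
  cat(sprintf("  stage 1: %d DE proteins, %d logistic hits\n",
              length(x$stage1_de), length(x$stage1_logistic)))
  cat(sprintf("  stage 2 overlap: %d -> lasso selected: %d -> final: %s\n",
              length(x$stage2_overlap), length(x$lasso_selected),
              if (length(x$final_markers))
                paste(x$final_markers, collapse = ", ") else "(none)"))
  if (!is.null(x$auc)) {
    cat("  AUC benchmark:\n")
    for (i in seq_len(nrow(x$auc)))
      cat(sprintf("    %-10s %-9s %.3f\n", x$auc$gene[i], x$auc$role[i],
                  x$auc$auc[i]))
  }
  invisible(x)
}
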