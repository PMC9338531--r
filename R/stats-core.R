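#' Uniform container for a single statistical test
#'
#' All hypothesis tests in the package return a `test_result`: a list with the
#' test statistic, two-sided p-value, point estimate (rho / r / beta / effect),
#' confidence limits where the test provides them, and the number of
#' observations actually used.
#'
#' @param statistic test statistic value.
#' @param p_value two-sided p-value in \[0, 1\].
#' @param estimate effect estimate (correlation, difference, log-hazard, ...).
#' @param ci_low,ci_high confidence limits (NA when the test has none).
#' @param n_used number of observations entering the test.
#' @param method short label of the test performed.
#' @param note optional flag (e.g. "constant input", "separation").
#' @return an object of class `test_result`.
#' @export
test_result <- function(statistic, p_value, estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_used = NA_integer_, method = "", note = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 estimate = unname(estimate), ci_low = unname(ci_low),
                 ci_high = unname(ci_high), n_used = as.integer(n_used),
                 method = method, note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, estimate = %.4g, p = %.4g (n = %d)\n",
              x$method, x$statistic, x$estimate, x$p_value, x$n_used))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

pairwise_complete <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Spearman rank correlation
#'
#' Two-sided Spearman test on pairwise-complete observations; average ranks for
#' ties. Exact p for n <= 9 (no ties), large-sample t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length.
#' @return a [test_result] with `estimate` = rho.
#' @export
spearman_rho <- function(x, y) {
  pc <- pairwise_complete(x, y)
  if (pc$n < 3) stopf("spearman_rho needs >= 3 complete pairs (got %d)", pc$n)
  if (stats::sd(pc$x) == 0 || stats::sd(pc$y) == 0)
    return(test_result(NA_real_, NA_real_, NA_real_, n_used = pc$n,
                       method = "Spearman", note = "constant input"))
  exact <- pc$n <= 9 && !anyDuplicated(pc$x) && !anyDuplicated(pc$y)
  ct <- suppressWarnings(
    stats::cor.test(pc$x, pc$y, method = "spearman", exact = exact))
  test_result(ct$statistic, ct$p.value, ct$estimate, n_used = pc$n,
              method = "Spearman")
}

#' Pearson correlation
#'
#' @inheritParams spearman_rho
#' @return a [test_result] with `estimate` = r and Fisher-z CI.
#' @export
pearson_r <- function(x, y) {
  pc <- pairwise_complete(x, y)
  if (pc$n < 3) stopf("pearson_r needs >= 3 complete pairs (got %d)", pc$n)
  if (stats::sd(pc$x) == 0 || stats::sd(pc$y) == 0)
    return(test_result(NA_real_, NA_real_, NA_real_, n_used = pc$n,
                       method = "Pearson", note = "constant input"))
  ct <- stats::cor.test(pc$x, pc$y, method = "pearson")
  ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
  test_result(ct$statistic, ct$p.value, ct$estimate, ci[1], ci[2],
              n_used = pc$n, method = "Pearson")
}

#' Mann-Whitney U test
#'
#' Two-sided; exact distribution when min(n) <= 8 and no ties, otherwise normal
#' approximation with tie correction. Returns p = 1 when every value across
#' both groups is tied.
#'
#' @param a,b numeric vectors (nonempty).
#' @return a [test_result]; `statistic` is the U statistic for group `a`,
#'   `estimate` the difference in medians.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stopf("mann_whitney_u: both groups nonempty")
  if (length(unique(c(a, b))) == 1L)
    return(test_result(length(a) * length(b) / 2, 1, 0,
                       n_used = length(a) + length(b),
                       method = "Mann-Whitney U", note = "all values tied"))
  exact <- min(length(a), length(b)) <= 8 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact))
  test_result(wt$statistic, wt$p.value,
              stats::median(a) - stats::median(b),
              n_used = length(a) + length(b), method = "Mann-Whitney U")
}

#' Welch two-sample t-test
#'
#' Two-sided, unequal variances (Welch-Satterthwaite df). Degenerate input
#' (zero variance in both groups with equal means) yields t = 0, p = 1.
#'
#' @param a,b numeric vectors with >= 2 values each.
#' @return a [test_result]; `estimate` = mean(a) - mean(b).
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stopf("welch_t needs n >= 2 per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(test_result(0, 1, 0, n_used = length(a) + length(b),
                         method = "Welch t", note = "constant input"))
    return(test_result(Inf * sign(mean(a) - mean(b)), 0, mean(a) - mean(b),
                       n_used = length(a) + length(b),
                       method = "Welch t", note = "constant input"))
  }
  tt <- stats::t.test(a, b)
  test_result(tt$statistic, tt$p.value, mean(a) - mean(b),
              tt$conf.int[1], tt$conf.int[2],
              n_used = length(a) + length(b), method = "Welch t")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: q_i = min over j >= i of p_(j) * m / j.
#'
#' @param p_values numeric vector in \[0, 1\] (NA passed through).
#' @return q-values, same order as input.
#' @export
bh_adjust <- function(p_values) stats::p.adjust(p_values, method = "BH")

#' Kaplan-Meier survival curve
#'
#' @param times nonnegative follow-up times.
#' @param events 0/1 event indicators.
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `surv`
#'   (product-limit estimate at each observed time).
#' @export
km_curve <- function(times, events) {
  stopifnot(all(times >= 0), all(events %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv)
}

#' Log-rank test between two groups
#'
#' @param times,events as in [km_curve].
#' @param groups two-level grouping (factor or vector).
#' @return a [test_result] with chi-squared statistic (1 df) and two-sided p.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stopf("logrank_test needs exactly 2 groups")
  if (sum(events) == 0)
    return(test_result(NA_real_, NA_real_, NA_real_, n_used = length(times),
                       method = "log-rank", note = "no events"))
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  test_result(sd_$chisq, p, n_used = length(times), method = "log-rank")
}

#' Univariate Cox proportional-hazards fits
#'
#' Fits one Cox model per covariate column (partial likelihood, Efron tie
#' handling) and reports beta, HR with Wald 95% CI and p. Constant covariates
#' and monotone-likelihood (separation-like) fits are flagged.
#'
#' @param covariates numeric vector or matrix (columns = covariates).
#' @param times,events survival outcome.
#' @return a list of [test_result] (one per covariate); `estimate` is beta
#'   (log hazard ratio), `statistic` the Wald z.
#' @export
cox_fit <- function(covariates, times, events) {
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(sum(events) >= 1)
  out <- lapply(seq_len(ncol(x)), function(j) {
    xj <- x[, j]
    if (stats::sd(xj, na.rm = TRUE) == 0)
      stopf("cox_fit: covariate '%s' is constant", colnames(x)[j])
    warned <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(times, events) ~ xj, ties = "efron"),
      warning = function(w) {
        if (grepl("infinite|converge", conditionMessage(w))) warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(fit$var[1, 1]))
    note <- if (warned || abs(beta) > 15) "possible monotone likelihood" else NULL
    test_result(beta / se, s$coefficients[1, "Pr(>|z|)"], beta,
                beta - 1.96 * se, beta + 1.96 * se,
                n_used = fit$n, method = "Cox PH (Efron)", note = note)
  })
  names(out) <- colnames(x)
  if (ncol(x) == 1) out[[1]] else out
}

#' Logistic regression (IRLS)
#'
#' Unpenalized binomial GLM with Wald tests; complete separation is flagged.
#'
#' @param X numeric matrix or vector of covariates.
#' @param y binary outcome (0/1 or two-level factor), both classes present.
#' @return list with `coefficients` (incl. intercept), `se`, `z`, `p`,
#'   `deviance`, `converged`, `separation`.
#' @export
logistic_fit <- function(X, y) {
  X <- as.matrix(X)
  y <- if (is.factor(y)) as.integer(y) - 1L else as.integer(y)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stopf("logistic_fit: y must contain both classes")
  dat <- data.frame(y = y, X)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  mu <- stats::fitted(fit)
  sep <- any(mu > 1 - 1e-8) || any(mu < 1e-8)
  cf <- summary(fit)$coefficients
  list(coefficients = cf[, "Estimate"], se = cf[, "Std. Error"],
       z = cf[, "z value"], p = cf[, "Pr(>|z|)"],
       deviance = fit$deviance, converged = fit$converged, separation = sep)
}

#' Lasso-penalized logistic regression path
#'
#' Coordinate-descent solution path (glmnet) over a decreasing lambda grid.
#'
#' @param X standardized covariate matrix.
#' @param y binary outcome.
#' @param lambdas optional decreasing lambda grid (glmnet default otherwise).
#' @return the fitted `glmnet` object (coefficients via `coef(fit, s = ...)`).
#' @export
lasso_logistic_path <- function(X, y, lambdas = NULL) {
  y <- if (is.factor(y)) as.integer(y) - 1L else as.integer(y)
  if (length(unique(y)) != 2) stopf("lasso_logistic_path: y must be binary")
  glmnet::glmnet(as.matrix(X), y, family = "binomial", lambda = lambdas,
                 standardize = TRUE)
}

#' Cross-validated lambda for the lasso logistic model
#'
#' @inheritParams lasso_logistic_path
#' @param n_folds number of CV folds (default 10).
#' @param seed integer seed controlling the fold split.
#' @param rule `"1se"` (default) or `"min"`.
#' @return chosen lambda (numeric scalar), with the `cv.glmnet` fit attached as
#'   attribute `"cv_fit"`.
#' @export
cv_lambda <- function(X, y, n_folds = 10, seed = 1, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  y <- if (is.factor(y)) as.integer(y) - 1L else as.integer(y)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(as.matrix(X), y, family = "binomial",
                          nfolds = n_folds)
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  attr(lam, "cv_fit") <- cv
  lam
}

#' K-means clustering (best of n_init Lloyd runs)
#'
#' @param X numeric matrix (rows clustered).
#' @param k number of clusters (<= nrow(X)).
#' @param seed integer seed (makes the result deterministic).
#' @param n_init random restarts; best inertia kept.
#' @return list with `labels`, `centers`, `inertia`.
#' @export
kmeans_fit <- function(X, k, seed = 1, n_init = 10) {
  X <- as.matrix(X)
  if (k > nrow(X)) stopf("kmeans_fit: k (%d) > rows (%d)", k, nrow(X))
  set.seed(seed)
  # Lloyd restarts can land on empty clusters; harmless across n_init retries
  km <- withCallingHandlers(
    stats::kmeans(X, centers = k, nstart = n_init, iter.max = 100,
                  algorithm = "Lloyd"),
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(labels = km$cluster, centers = km$centers, inertia = km$tot.withinss)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation: probability that a random positive scores above a
#' random negative, ties counted one half.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels (1 = positive); both classes required.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  stopifnot(all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("roc_auc: both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
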