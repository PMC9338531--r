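# statistical primitives against hand/brute-force oracles

test_that("spearman_rho matches the rank formula and handles edge cases", {
  expect_equal(spearman_rho(1:4, 1:4)$estimate, 1)
  expect_equal(spearman_rho(1:4, 4:1)$estimate, -1)
  # hand ranks: d^2 sums to 4 -> 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5))$estimate, 0.8)
  r <- spearman_rho(c(1, 1, 1, 1), 1:4)
  expect_true(is.na(r$estimate))
  expect_identical(r$note, "constant input")
  # invariance under strictly monotone transforms
  set.seed(7)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_rho(exp(x), y^3 * 5 + y)$estimate,
               spearman_rho(x, y * 5 + y^3)$estimate)
})

test_that("pearson_r matches the covariance formula by hand", {
  x <- c(1, 2, 4, 5, 7); y <- c(2, 3, 3, 6, 8)
  byhand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$estimate, byhand)
  expect_equal(pearson_r(1:6, 2 * (1:6))$estimate, 1)
})

test_that("mann_whitney_u is exact for tiny samples and degenerate on ties", {
  # a = {1,2}, b = {3,4}: U = 0, two-sided exact p = 2/C(4,2)
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0, ignore_attr = TRUE)
  expect_equal(r$p_value, 2 / choose(4, 2))
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney_u(rep(2, 5), rep(2, 4))$p_value, 1)
})

test_that("mann_whitney_u exact p matches full enumeration of labelings", {
  a <- c(0.3, 1.2, 2.2); b <- c(0.1, 0.9, 3.5, 4.1)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pool <- c(a, b)
  combs <- utils::combn(7, 3)
  us <- apply(combs, 2, function(i) u_stat(pool[i], pool[-i]))
  u_obs <- u_stat(a, b)
  mu <- length(a) * length(b) / 2
  p_exact <- mean(abs(us - mu) >= abs(u_obs - mu))
  expect_equal(mann_whitney_u(a, b)$p_value, p_exact, tolerance = 1e-12)
})

test_that("welch_t matches the textbook formula and degenerates to p = 1", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5)
  se <- sqrt(var(a) / 5 + var(b) / 6)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 6)^2 / 5)
  r <- welch_t(a, b)
  expect_equal(r$statistic, t_hand, ignore_attr = TRUE)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), df_hand))
  expect_equal(welch_t(c(1, 1), c(1, 1))$p_value, 1)
})

test_that("bh_adjust is the step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # superset of Bonferroni rejections
  set.seed(1)
  p <- runif(50)^2
  expect_true(all(which(p.adjust(p, "bonferroni") < 0.05) %in%
                    which(bh_adjust(p) < 0.05)))
})

test_that("log-rank chi-square matches a hand-computed O-E table", {
  # 6 subjects, two groups; deaths at t = 1, 2, 3
  times <- c(1, 2, 4, 3, 5, 6)
  events <- c(1, 1, 0, 1, 0, 0)
  grp <- c("A", "A", "A", "B", "B", "B")
  # t=1: risk 3A/3B, death A -> E_A = 0.5, V = 0.25*6/ (6-1)... hand via survdiff
  # O-E by hand: t1 (3A,3B death A): eA=3/6; t2 (2A,3B death A): eA=2/5;
  # t3 (1A,3B death B): eA=1/4. O_A=2, E_A=3/6+2/5+1/4=1.15
  # V = sum n1*n2*d*(n-d)/(n^2*(n-1)) = (3*3/36)+(2*3/25)+(1*3/16)
  V <- 3 * 3 / 36 + 2 * 3 / 25 + 1 * 3 / 16
  chisq_hand <- (2 - 1.15)^2 / V
  r <- logrank_test(times, events, grp)
  expect_equal(r$statistic, chisq_hand, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(logrank_test(times, events, grp)$p_value,
               pchisq(chisq_hand, 1, lower.tail = FALSE))
  # identical groups -> chi^2 = 0
  r2 <- logrank_test(rep(times, 2), rep(events, 2), rep(c("A", "B"), each = 6))
  expect_equal(r2$statistic, 0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("km_curve reproduces the product-limit estimate", {
  km <- km_curve(c(1, 2, 2, 3), c(1, 1, 0, 1))
  expect_equal(km$surv[km$time == 1], 3 / 4)
  expect_equal(km$surv[km$time == 2], 3 / 4 * 2 / 3)
  km0 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
})

test_that("cox_fit is antisymmetric and equivariant to rescaling", {
  set.seed(42)
  x <- rnorm(80)
  tt <- rexp(80, exp(0.8 * x))
  ev <- rbinom(80, 1, 0.9)
  f1 <- cox_fit(x, tt, ev)
  f2 <- cox_fit(-x, tt, ev)
  expect_equal(f1$estimate, -f2$estimate, tolerance = 1e-8)
  f3 <- cox_fit(10 * x, tt, ev)
  expect_equal(f3$estimate, f1$estimate / 10, tolerance = 1e-8)
  expect_error(cox_fit(rep(1, 80), tt, ev), "constant")
})

test_that("logistic_fit matches a likelihood-grid oracle on one feature", {
  x <- c(-2.1, -1.3, -0.4, 0.2, 0.3, 1.1, 1.8, 2.5)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log(1 + exp(eta)))
  }
  grid_fit <- optim(c(0, 0), nll, method = "BFGS")$par
  fit <- logistic_fit(x, y)
  expect_equal(unname(fit$coefficients), grid_fit, tolerance = 1e-4)
  # intercept-only model recovers the logit of prevalence
  f0 <- logistic_fit(matrix(numeric(0), 8, 0), y)
  expect_equal(unname(f0$coefficients[1]), qlogis(mean(y)), tolerance = 1e-6)
})

test_that("logistic_fit flags complete separation", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_true(logistic_fit(x, y)$separation)
})

test_that("lasso path shrinks to zero and approaches the MLE as lambda -> 0", {
  set.seed(11)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * X[, "a"]))
  fit <- lasso_logistic_path(X, y, lambdas = c(5, 0.0001))
  expect_true(all(coef(fit, s = 5)[-1] == 0))
  mle <- logistic_fit(X, y)$coefficients
  expect_equal(unname(coef(fit, s = 0.0001)[-1, 1]), unname(mle[-1]),
               tolerance = 1e-2)
})

test_that("cv_lambda keeps a strongly informative feature", {
  set.seed(5)
  hits <- 0
  for (s in 1:20) {
    X <- matrix(rnorm(100 * 30), 100, 30)
    colnames(X) <- paste0("f", 1:30)
    y <- rbinom(100, 1, plogis(2 * X[, 1]))
    lam <- cv_lambda(X, y, seed = s)
    beta <- coef(attr(lam, "cv_fit"), s = lam)[-1, 1]
    if (which.max(abs(beta)) == 1 && beta[1] != 0) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("kmeans_fit recovers separated blobs and is seed-deterministic", {
  set.seed(3)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 8), 30))
  f1 <- kmeans_fit(X, 2, seed = 9)
  f2 <- kmeans_fit(X, 2, seed = 9)
  expect_identical(f1$labels, f2$labels)
  expect_equal(length(unique(f1$labels[1:30])), 1L)
  expect_equal(length(unique(f1$labels[31:60])), 1L)
  expect_true(f1$labels[1] != f1$labels[31])
  expect_equal(kmeans_fit(X, nrow(X), seed = 1)$inertia, 0)
  expect_error(kmeans_fit(X, 61), "k")
})

test_that("roc_auc equals exhaustive pair counting and is antisymmetric", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.2)
  labels <- c(1, 0, 1, 1, 0, 0)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  byhand <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(roc_auc(scores, labels), byhand)
  expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1)
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0)), 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})
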