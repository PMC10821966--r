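test_that("ridge classifier: separability, shrinkage and glmnet agreement", {
  set.seed(31)
  n <- 60
  y <- rep(0:1, n / 2)
  x <- cbind(a = y + rnorm(n, 0, 0.05), b = rnorm(n))
  fit <- fit_ridge(x, y, n_folds = 5)
  expect_equal(auc_rank(predict_ridge(fit, x)$score, y), 1)
  # coefficient norm shrinks monotonically with the penalty
  norms <- vapply(10^seq(-2, 4, 1), function(a)
    sqrt(sum(fistulomics:::ridge_solve(x, y, a)[-1]^2)), 0)
  expect_true(all(diff(norms) < 0))
  expect_error(fit_ridge(x, rep(1, n)), "single-class")
  expect_error(fit_ridge(x[1:12, ], y[1:12], n_folds = 10), "n_folds")

  # independent oracle: glmnet solves the same penalized likelihood
  # (its lambda is ours divided by n)
  xx <- scale(matrix(rnorm(200 * 4), 200, 4))
  yy <- rbinom(200, 1, stats::plogis(xx[, 1] - 0.5 * xx[, 3]))
  for (lam in c(0.5, 5)) {
    ours <- fistulomics:::ridge_solve(xx, yy, lam)
    g <- glmnet::glmnet(xx, yy, family = "binomial", alpha = 0,
                        lambda = lam / 200, standardize = FALSE, thresh = 1e-12)
    expect_equal(ours, as.numeric(stats::coef(g)), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("ridge on label-independent features stays near chance AUC", {
  set.seed(33)
  n <- 300
  x <- matrix(rnorm(n * 6), n, 6)
  y <- rep(0:1, n / 2)
  fit <- fit_ridge(x[1:210, ], y[1:210], seed = 2)
  sc <- predict_ridge(fit, x[211:300, ])
  expect_lt(abs(auc_rank(sc$score, y[211:300]) - 0.5), 0.08)
})

test_that("AUC equals brute-force concordant-pair counting", {
  # 6-sample hand case
  expect_equal(auc_rank(c(.9, .8, .7, .4, .3, .2), c(1, 1, 0, 1, 0, 0)), 8 / 9)
  expect_equal(auc_rank(1:4, c(0, 0, 1, 1)), 1)
  expect_equal(auc_rank(4:1, c(0, 0, 1, 1)), 0)    # anti-correlated
  brute_auc <- function(s, y) {
    s1 <- s[y == 1]; s0 <- s[y == 0]
    cnt <- 0
    for (a in s1) for (b in s0) cnt <- cnt + (a > b) + 0.5 * (a == b)
    cnt / (length(s1) * length(s0))
  }
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(n), 1))                 # ties included
    expect_equal(auc_rank(s, y), brute_auc(s, y))
  }
})

test_that("threshold metrics at 0.5 and degenerate precision convention", {
  pr <- c(.9, .8, .7, .2, .6, .1)
  y <- c(1, 1, 0, 1, 0, 0)
  m <- evaluate_metrics(pr, y)
  expect_named(m, c("AUC", "ACC", "Pre", "Re", "F1"))
  expect_equal(m[["ACC"]], 3 / 6)
  expect_equal(m[["Pre"]], 2 / 4)
  expect_equal(m[["Re"]], 2 / 3)
  expect_true(all(m >= 0 & m <= 1))
  m0 <- evaluate_metrics(rep(0.1, 4), c(1, 0, 1, 0))
  expect_equal(m0[["Pre"]], 0)
  expect_equal(m0[["F1"]], 0)
  expect_error(evaluate_metrics(pr, rep(1, 6)), "single class")
})

test_that("DeLong variance matches the placement-value formula; bootstrap covers the AUC", {
  s <- c(.9, .8, .7, .4, .35, .3, .2, .15)
  y <- c(1, 1, 0, 1, 0, 1, 0, 0)
  ci <- auc_ci(s, y, method = "delong")
  # brute-force placement values
  s1 <- s[y == 1]; s0 <- s[y == 0]
  v10 <- sapply(s1, function(a) mean((a > s0) + 0.5 * (a == s0)))
  v01 <- sapply(s0, function(b) mean((s1 > b) + 0.5 * (s1 == b)))
  va <- stats::var(v10) / length(s1) + stats::var(v01) / length(s0)
  a <- mean(outer(s1, s0, ">") + 0.5 * outer(s1, s0, "=="))
  expect_equal(ci$auc, a)
  expect_equal(ci$lower, max(0, a - qnorm(0.975) * sqrt(va)), tolerance = 1e-12)
  expect_equal(ci$upper, min(1, a + qnorm(0.975) * sqrt(va)), tolerance = 1e-12)
  # perfect separation: upper bound clipped to 1
  expect_equal(auc_ci(1:6, c(0, 0, 0, 1, 1, 1), method = "delong")$upper, 1)
  # bootstrap percentile CI covers the point AUC in nearly all fixtures
  set.seed(47)
  cover <- vapply(1:30, function(i) {
    n <- 40
    y <- rep(0:1, n / 2)
    s <- rnorm(n) + 0.8 * y
    ci <- auc_ci(s, y, method = "bootstrap", n_boot = 300, seed = i)
    ci$lower <= ci$auc && ci$auc <= ci$upper
  }, TRUE)
  expect_gte(mean(cover), 0.99)
})

test_that("paired model comparison is the paired Student t-test", {
  a <- c(0.81, 0.78, 0.83, 0.80, 0.79)
  b <- c(0.74, 0.75, 0.78, 0.73, 0.77)
  pt <- paired_model_test(a, b)
  d <- a - b
  expect_equal(pt$t, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(pt$p, 2 * stats::pt(-abs(pt$t), df = 4))
  expect_warning(tie <- paired_model_test(a, a), "tie")
  expect_equal(tie$p, 1)
  set.seed(51)
  big <- paired_model_test(a + 0.05 + rnorm(5, 0, 1e-4), a)
  expect_lt(big$p, 0.001)
})

test_that("net benefit follows the TP/FP trade-off formula", {
  # hand case: n = 10, prevalence 0.4, t = 0.25, TP = 3, FP = 2
  prob <- c(.9, .9, .9, .3, .3, .1, .1, .1, .1, .1)
  y <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  nb <- net_benefit_curve(prob, y, 0.25)
  expect_equal(nb$net_benefit, 0.3 - 0.2 * (0.25 / 0.75))
  expect_equal(nb$treat_none, 0)
  # treat-all tends to prevalence as t -> 0
  nb2 <- net_benefit_curve(prob, y, c(0.001, 0.5))
  expect_equal(nb2$treat_all[1], 0.4, tolerance = 1e-2)
  # perfect classifier: NB = prevalence below the least positive probability
  pp <- ifelse(y == 1, 0.95, 0.05)
  nb3 <- net_benefit_curve(pp, y, c(0.1, 0.5, 0.9))
  expect_equal(nb3$net_benefit[1:2], c(0.4, 0.4))
  expect_error(net_benefit_curve(prob, y, 1), "excluded")
  expect_error(net_benefit_curve(c(1.2, prob[-1]), y, 0.5), "\\[0, 1\\]")
})

test_that("stratified split preserves class counts and partitions the cohort", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(30:120, 1)
    y <- rbinom(n, 1, runif(1, 0.3, 0.7))
    sp <- stratified_split(y, 0.7, seed = rep)
    expect_identical(sort(c(sp$train, sp$test)), seq_len(n))
    for (cl in 0:1)
      expect_lte(abs(sum(y[sp$train] == cl) - 0.7 * sum(y == cl)), 1)
  }
})

test_that("repeated evaluation is reproducible and reports a sane structure", {
  set.seed(71)
  n <- 80
  y <- rep(0:1, n / 2)
  x <- cbind(matrix(rnorm(n * 20), n, 20), sig = y + rnorm(n, 0, 0.8))
  colnames(x) <- c(paste0("n", 1:20), "sig")
  r1 <- repeated_evaluation(x, y, n_iter = 3, n_resamples = 20, min_keep = 5,
                            alpha_grid = 10^seq(-1, 1, 1), seed = 4,
                            model_tag = "toy")
  r2 <- repeated_evaluation(x, y, n_iter = 3, n_resamples = 20, min_keep = 5,
                            alpha_grid = 10^seq(-1, 1, 1), seed = 4,
                            model_tag = "toy")
  expect_identical(r1$per_iteration, r2$per_iteration)
  s <- r1$summary
  expect_true(all(s$mean >= 0 & s$mean <= 1))
  expect_true(all(s$sd >= 0))
  expect_true(all(s$ci_lower <= s$mean & s$mean <= s$ci_upper))
  # single iteration: STD undefined, flagged as NA
  r3 <- repeated_evaluation(x, y, n_iter = 1, n_resamples = 10, min_keep = 5,
                            alpha_grid = 1, seed = 4)
  expect_true(all(is.na(r3$summary$sd)))
})
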