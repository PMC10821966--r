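#' Default ridge penalty grid
#'
#' 13 penalties log-spaced between 1e-3 and 1e3.
#' @return Numeric vector of length 13.
#' @export
default_alpha_grid <- function() 10^seq(-3, 3, by = 0.5)

#' L2-regularized logistic (ridge) classifier with cross-validated penalty
#'
#' Fits penalized logistic regression by iteratively reweighted least
#' squares, minimizing `-loglik + alpha/2 * ||beta||^2` (intercept
#' unpenalized), with the penalty chosen from `alpha_grid` by stratified
#' `n_folds`-fold cross-validation maximizing the AUC of the pooled
#' out-of-fold scores (pooling keeps the criterion well-defined for the
#' small folds of desk-scale cohorts). Ties in CV AUC go to the strongest
#' penalty. A `family = "linear"` variant — ridge regression on the 0/1
#' labels with the same CV — is available since plain "ridge" can denote
#' either; the logistic form is the default because downstream threshold
#' metrics and decision curves need calibrated probabilities.
#'
#' @param x Numeric matrix (observations x features).
#' @param y 0/1 labels; both classes required, and at least `n_folds`
#'   observations per class.
#' @param alpha_grid Candidate penalties.
#' @param n_folds Cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @param family `"logistic"` (default) or `"linear"`.
#' @return A `ridge_fit`: list with `coef` (intercept first), `alpha`,
#'   `cv_auc` (per grid point), `family`, `features`.
#' @export
fit_ridge <- function(x, y, alpha_grid = default_alpha_grid(), n_folds = 10,
                      seed = 1L, family = c("logistic", "linear")) {
  family <- match.arg(family)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class training data")
  if (min(table(y)) < n_folds)
    stop("need at least n_folds = ", n_folds, " samples per class; got ",
         paste(table(y), collapse = "/"))
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in c(0L, 1L)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  cv_auc <- vapply(alpha_grid, function(a) {
    oof <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      b <- ridge_solve(x[tr, , drop = FALSE], y[tr], a, family)
      oof[!tr] <- cbind(1, x[!tr, , drop = FALSE]) %*% b
    }
    auc_rank(oof, y)
  }, 0)
  best <- max(which(cv_auc == max(cv_auc)))  # ties -> strongest penalty
  alpha <- alpha_grid[best]
  structure(list(coef = ridge_solve(x, y, alpha, family), alpha = alpha,
                 cv_auc = stats::setNames(cv_auc, alpha_grid),
                 family = family, features = colnames(x)),
            class = "ridge_fit")
}

ridge_solve <- function(x, y, alpha, family = "logistic", max_iter = 50,
                        tol = 1e-8) {
  X <- cbind(1, x)
  p <- ncol(X)
  P <- diag(c(0, rep(1, p - 1L)), p)
  if (family == "linear")
    return(drop(solve(crossprod(X) + alpha * P, crossprod(X, y))))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(crossprod(X, X * w) + alpha * P,
                           crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

#' @rdname fit_ridge
#' @param fit A `ridge_fit`.
#' @param newdata Matrix with the fitted feature columns.
#' @return `predict_ridge()`: list with `score` (linear predictor) and
#'   `prob` (logistic probability; for the linear family, the score clipped
#'   to \[0, 1\]).
#' @export
predict_ridge <- function(fit, newdata) {
  stopifnot(inherits(fit, "ridge_fit"))
  newdata <- as.matrix(newdata)
  score <- drop(cbind(1, newdata) %*% fit$coef)
  prob <- if (fit$family == "logistic") stats::plogis(score)
          else pmin(pmax(score, 0), 1)
  list(score = score, prob = prob)
}

#' Rank-based AUC
#'
#' Area under the ROC curve by the Mann-Whitney statistic: concordant score
#' pairs count 1, ties 0.5.
#'
#' @param scores Numeric scores (larger = more EF-like).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold and ranking metrics of a fitted classifier
#'
#' AUC from score ranks plus accuracy, precision, recall and F1 at
#' probability threshold 0.5. Precision is reported as 0 when no positive
#' predictions are made (and F1 as 0 when precision + recall is 0).
#'
#' @param prob Predicted probabilities.
#' @param labels 0/1 labels (both classes present).
#' @param score Optional ranking score (defaults to `prob`).
#' @return Named vector: `AUC`, `ACC`, `Pre`, `Re`, `F1`.
#' @export
evaluate_metrics <- function(prob, labels, score = prob) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("degenerate cohort: single class")
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  re <- tp / (tp + fn)
  f1 <- if (pre + re > 0) 2 * pre * re / (pre + re) else 0
  c(AUC = auc_rank(score, labels), ACC = mean(pred == labels),
    Pre = pre, Re = re, F1 = f1)
}

#' Confidence interval for the AUC
#'
#' DeLong's analytic method (placement-value variance, normal interval,
#' clipped to \[0, 1\]) or a stratified bootstrap percentile interval with
#' `n_boot` resamples. The modelled protocol quotes "DeLong with 2000
#' iterations", which conflates the two; both are provided and the bootstrap
#' is the default labelled output.
#'
#' @param scores,labels As in [auc_rank()].
#' @param method `"bootstrap"` or `"delong"`.
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @return List with `auc`, `lower`, `upper`, `method`.
#' @export
auc_ci <- function(scores, labels, method = c("bootstrap", "delong"),
                   n_boot = 2000, conf = 0.95, seed = 1L) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  a <- auc_rank(scores, labels)
  s1 <- scores[labels == 1L]; s0 <- scores[labels == 0L]
  n1 <- length(s1); n0 <- length(s0)
  if (method == "delong") {
    # placement values
    v10 <- vapply(s1, function(s) (sum(s > s0) + 0.5 * sum(s == s0)) / n0, 0)
    v01 <- vapply(s0, function(s) (sum(s1 > s) + 0.5 * sum(s1 == s)) / n1, 0)
    va <- stats::var(v10) / n1 + stats::var(v01) / n0
    if (n1 < 2L || n0 < 2L || !is.finite(va)) {
      warning("too few observations for a DeLong variance; returning [0, 1]")
      return(list(auc = a, lower = 0, upper = 1, method = method))
    }
    z <- stats::qnorm(1 - (1 - conf) / 2)
    lo <- max(0, a - z * sqrt(va)); hi <- min(1, a + z * sqrt(va))
  } else {
    set.seed(seed)
    ab <- vapply(seq_len(n_boot), function(b) {
      sb1 <- sample(s1, n1, replace = TRUE)
      sb0 <- sample(s0, n0, replace = TRUE)
      auc_rank(c(sb1, sb0), rep(c(1L, 0L), c(n1, n0)))
    }, 0)
    q <- stats::quantile(ab, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  list(auc = a, lower = lo, upper = hi, method = method)
}

#' Paired comparison of two models' per-iteration metrics
#'
#' Two-sided paired Student t-test on matched per-iteration metric vectors
#' (typically AUCs over the repeated splits). Identical vectors return
#' p = 1 by convention; a perfectly constant nonzero difference returns
#' p = 0 — both with a warning, since the t statistic is undefined.
#'
#' @param metrics_a,metrics_b Equal-length numeric vectors (>= 2 values).
#' @return List with `p`, `t`, `mean_diff`.
#' @export
paired_model_test <- function(metrics_a, metrics_b) {
  stopifnot(length(metrics_a) == length(metrics_b), length(metrics_a) >= 2L)
  d <- metrics_a - metrics_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      warning("identical metric vectors; p = 1 (exact tie)")
      return(list(p = 1, t = 0, mean_diff = 0))
    }
    warning("constant nonzero difference; t statistic degenerate, p = 0")
    return(list(p = 0, t = sign(mean(d)) * Inf, mean_diff = mean(d)))
  }
  tt <- stats::t.test(metrics_a, metrics_b, paired = TRUE)
  list(p = tt$p.value, t = unname(tt$statistic), mean_diff = mean(d))
}

#' Decision-curve analysis: net benefit
#'
#' Net benefit of acting on the model at risk threshold t:
#' `NB(t) = TP/n - (FP/n) * t / (1 - t)` (positives called at `prob >= t`),
#' with the treat-all reference `pi - (1 - pi) * t / (1 - t)` (pi =
#' prevalence) and the treat-none reference 0.
#'
#' @param prob Predicted probabilities in \[0, 1\].
#' @param labels 0/1 labels.
#' @param thresholds Risk thresholds, strictly inside (0, 1).
#' @return A `net_benefit_curve` data.frame with columns `threshold`,
#'   `net_benefit`, `treat_all`, `treat_none`.
#' @export
net_benefit_curve <- function(prob, labels,
                              thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1); t = 1 is excluded")
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(thresholds, function(t) {
    pos <- prob >= t
    (sum(pos & labels == 1L) - sum(pos & labels == 0L) * t / (1 - t)) / n
  }, 0)
  structure(data.frame(threshold = thresholds,
                       net_benefit = nb,
                       treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
                       treat_none = 0),
            class = c("net_benefit_curve", "data.frame"))
}

#' Stratified train/test split
#'
#' Splits indices 7:3 (by default) preserving the class balance to within
#' one patient per cohort.
#'
#' @param labels 0/1 labels.
#' @param frac Training fraction.
#' @param seed Seed.
#' @return List with integer index vectors `train`, `test`.
#' @export
stratified_split <- function(labels, frac = 0.7, seed = 1L) {
  set.seed(seed)
  tr <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(labels == cl)
    sample(idx, round(frac * length(idx)))
  }))
  list(train = sort(tr), test = setdiff(seq_along(labels), tr))
}

#' Repeated-split evaluation of one feature group
#'
#' The full per-model protocol: for each of `n_iter` iterations, draw a
#' stratified 7:3 train/test split, standardize on the training cohort,
#' run the resampling-frequency screen and redundancy pruning on the
#' training cohort, choose the feature-prefix subset, fit the ridge
#' classifier and evaluate the five metrics on both cohorts. Aggregates are
#' mean, STD and the normal 95% CI of the mean over iterations.
#'
#' `subset_selection = "test"` reproduces the modelled protocol (the prefix
#' is chosen by test-cohort AUC — an information leak inherent to that
#' design); `"nested"` instead picks it on an inner 7:3 split of the
#' training cohort and is the leakage-free mode used for null calibration.
#'
#' @param features Numeric matrix (patients x features) with column names.
#' @param labels 0/1 labels.
#' @param n_iter Number of repeated splits (30 in the modelled protocol).
#' @param split Training fraction (0.7).
#' @param seed Base seed; iteration i uses `seed + i - 1`.
#' @param n_resamples,p_thresh,top_frac,min_keep,r_thresh Selection
#'   parameters, see [resample_screen()] and [rank_and_prune()].
#' @param subset_selection `"test"` or `"nested"`.
#' @param alpha_grid,n_folds Ridge CV parameters.
#' @param scaling `"train"` (fit scaler on the training cohort; default) or
#'   `"global"` (fit on all data before splitting, for replication of
#'   protocols that standardized once).
#' @param model_tag Label stored in the report.
#' @return An `eval_report`: list with `per_iteration` (data.frame),
#'   `summary` (mean/STD/CI per metric and cohort), `selected` (list of
#'   chosen feature sets), `dca` (net-benefit curves of the first
#'   iteration's fit) and `model_tag`.
#' @export
repeated_evaluation <- function(features, labels, n_iter = 30, split = 0.7,
                                seed = 1L, n_resamples = 100, p_thresh = 0.01,
                                top_frac = 0.10, min_keep = 40, r_thresh = 0.5,
                                subset_selection = c("test", "nested"),
                                alpha_grid = default_alpha_grid(), n_folds = 10,
                                scaling = c("train", "global"),
                                model_tag = "model") {
  subset_selection <- match.arg(subset_selection)
  scaling <- match.arg(scaling)
  labels <- as.integer(labels)
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  rows <- vector("list", n_iter)
  selected <- vector("list", n_iter)
  dca <- NULL
  for (i in seq_len(n_iter)) {
    it_seed <- seed + i - 1L
    sp <- stratified_split(labels, split, it_seed)
    xtr_raw <- features[sp$train, , drop = FALSE]
    if (scaling == "global") {
      xall <- standardize(features)
      xtr <- xall[sp$train, , drop = FALSE]
      xte <- xall[sp$test, , drop = FALSE]
    } else {
      xtr <- standardize(xtr_raw)
      xte <- standardize(xtr_raw, features[sp$test, , drop = FALSE])
    }
    ytr <- labels[sp$train]; yte <- labels[sp$test]
    # small cohorts cannot sustain 10-fold CV per class; cap at the class size
    n_folds_i <- min(n_folds, min(table(ytr)))
    trace <- resample_screen(xtr, ytr, n_resamples = n_resamples,
                             p_thresh = p_thresh, seed = it_seed)
    pruned <- rank_and_prune(trace, xtr, top_frac = top_frac,
                             min_keep = min_keep, r_thresh = r_thresh)
    if (length(pruned) == 0L) {
      # nothing screened through: fall back to the highest-|t| feature so the
      # iteration still yields a (null-like) model rather than aborting
      pruned <- names(sort(trace$mean_abs_t, decreasing = TRUE))[1L]
    }
    if (subset_selection == "test") {
      ps <- prefix_search(pruned, xtr, ytr, xte, yte,
                          alpha_grid = alpha_grid, n_folds = n_folds_i,
                          seed = it_seed)
    } else {
      inner <- stratified_split(ytr, split, it_seed + 10000L)
      ps <- prefix_search(pruned, xtr[inner$train, , drop = FALSE],
                          ytr[inner$train],
                          xtr[inner$test, , drop = FALSE], ytr[inner$test],
                          alpha_grid = alpha_grid,
                          n_folds = min(n_folds_i, min(table(ytr[inner$train]))),
                          seed = it_seed)
    }
    fs <- ps$features
    fit <- fit_ridge(xtr[, fs, drop = FALSE], ytr, alpha_grid = alpha_grid,
                     n_folds = n_folds_i, seed = it_seed)
    ptr <- predict_ridge(fit, xtr[, fs, drop = FALSE])
    pte <- predict_ridge(fit, xte[, fs, drop = FALSE])
    rows[[i]] <- rbind(
      data.frame(iteration = i, cohort = "train",
                 t(evaluate_metrics(ptr$prob, ytr, ptr$score))),
      data.frame(iteration = i, cohort = "test",
                 t(evaluate_metrics(pte$prob, yte, pte$score))))
    selected[[i]] <- fs
    if (i == 1L)
      dca <- list(train = net_benefit_curve(ptr$prob, ytr),
                  test = net_benefit_curve(pte$prob, yte))
  }
  per_it <- do.call(rbind, rows)
  metrics <- c("AUC", "ACC", "Pre", "Re", "F1")
  summ <- do.call(rbind, lapply(c("train", "test"), function(co) {
    sub <- per_it[per_it$cohort == co, metrics, drop = FALSE]
    mn <- colMeans(sub)
    sd_ <- if (n_iter > 1L) apply(sub, 2, stats::sd) else rep(NA_real_, 5)
    se <- sd_ / sqrt(n_iter)
    data.frame(model = model_tag, cohort = co, metric = metrics,
               mean = unname(mn), sd = unname(sd_),
               ci_lower = unname(mn - 1.96 * se),
               ci_upper = unname(mn + 1.96 * se), row.names = NULL)
  }))
  structure(list(per_iteration = per_it, summary = summ, selected = selected,
                 dca = dca, model_tag = model_tag, n_iter = n_iter,
                 seed = seed, subset_selection = subset_selection),
            class = "eval_report")
}
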