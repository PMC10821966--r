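#' Standardize features using training statistics
#'
#' Z-scores every column of `apply_to` using the mean and population standard
#' deviation (denominator n) of the corresponding `train` column. Columns
#' with zero training SD are mapped to 0 everywhere — the zero-variance rule
#' that also underlies the screening filter.
#'
#' @param train Numeric matrix (patients x features) supplying the statistics.
#' @param apply_to Matrix to transform (defaults to `train`).
#' @return Transformed matrix with the same dimnames as `apply_to`.
#' @export
standardize <- function(train, apply_to = train) {
  if (nrow(train) == 0L) stop("training matrix is empty")
  mu <- colMeans(train)
  sd_pop <- sqrt(colMeans(train^2) - mu^2)
  sd_pop[sd_pop < .Machine$double.eps^0.5 * pmax(abs(mu), 1)] <- 0
  out <- sweep(apply_to, 2, mu, `-`)
  scale_by <- ifelse(sd_pop > 0, sd_pop, 1)
  out <- sweep(out, 2, scale_by, `/`)
  out[, sd_pop == 0] <- 0
  out
}

# Vectorized equal-variance two-sample Student t-test across columns.
# Returns list(t, p); columns with pooled variance 0 get t = 0, p = 1.
col_t_test <- function(x, labels) {
  g1 <- labels == 1L
  n1 <- sum(g1); n0 <- sum(!g1)
  m1 <- colMeans(x[g1, , drop = FALSE]); m0 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- colMeans(x[g1, , drop = FALSE]^2) - m1^2
  v0 <- colMeans(x[!g1, , drop = FALSE]^2) - m0^2
  sp2 <- (n1 * v1 + n0 * v0) / (n1 + n0 - 2)   # pooled (population sums n*var)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t <- ifelse(se > 0, (m1 - m0) / se, 0)
  p <- 2 * stats::pt(-abs(t), df = n1 + n0 - 2)
  p[se == 0] <- 1
  list(t = t, p = p)
}

#' Resampling-frequency feature screening
#'
#' The stability-screening stage: draw `n_resamples` stratified subsamples of
#' `frac` of the data without replacement; within each, drop zero-variance
#' columns and keep columns whose two-sided equal-variance Student t-test
#' against the EF label has `p < p_thresh`; record the indicator `x_i` per
#' feature and resample. The selection frequency of feature i is
#' `f_i = sum_resamples(x_i) / n_resamples`. Resamples are stratified by
#' label so that no draw is single-class; should one occur it is redrawn.
#'
#' @param features Numeric matrix (patients x features), already standardized
#'   or raw (the t-test is scale-invariant).
#' @param labels 0/1 vector; both classes must be present.
#' @param n_resamples Number of subsamples (100 in the modelled procedure).
#' @param frac Subsample fraction (0.7).
#' @param p_thresh Univariate significance threshold (0.01).
#' @param seed Integer seed fixing the resampling.
#' @return A `selection_trace`: list with `frequency` (named f_i), `mean_abs_t`
#'   (mean |t| over resamples), `kept` (indicator matrix resamples x features)
#'   and the call parameters.
#' @export
resample_screen <- function(features, labels, n_resamples = 100, frac = 0.7,
                            p_thresh = 0.01, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  set.seed(seed)
  idx1 <- which(labels == 1L); idx0 <- which(labels == 0L)
  k1 <- max(1L, round(frac * length(idx1)))
  k0 <- max(1L, round(frac * length(idx0)))
  m <- ncol(features)
  kept <- matrix(FALSE, n_resamples, m, dimnames = list(NULL, colnames(features)))
  abs_t <- matrix(0, n_resamples, m)
  for (r in seq_len(n_resamples)) {
    take <- c(sample(idx1, k1), sample(idx0, k0))
    x <- features[take, , drop = FALSE]
    tt <- col_t_test(x, labels[take])
    nz <- apply_var_filter(x)
    kept[r, ] <- nz & tt$p < p_thresh
    abs_t[r, ] <- abs(tt$t)
  }
  structure(list(frequency = colMeans(kept),
                 mean_abs_t = colMeans(abs_t),
                 kept = kept,
                 n_resamples = n_resamples, frac = frac,
                 p_thresh = p_thresh, seed = seed),
            class = "selection_trace")
}

apply_var_filter <- function(x) {
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  v > .Machine$double.eps * pmax(mu^2, 1)
}

#' Frequency ranking and Pearson redundancy pruning
#'
#' Orders screened features by selection frequency (ties broken by mean |t|
#' over resamples, then name, for a deterministic ranking), keeps the top
#' `max(ceil(top_frac * m), min_keep)` of the m features with nonzero
#' frequency (capped at m), then greedily removes redundancy: walking down
#' the ranking, a feature is dropped if its absolute Pearson correlation with
#' any already-kept feature exceeds `r_thresh` on the training data.
#'
#' @param trace A `selection_trace` from [resample_screen()].
#' @param train Training feature matrix (for the correlations).
#' @param top_frac Fraction of survivors entering pruning (0.10).
#' @param min_keep Minimum number entering pruning (40).
#' @param r_thresh Absolute-correlation threshold (0.5).
#' @return Character vector of retained feature names, in frequency order;
#'   empty (with a warning) if nothing survived screening.
#' @export
rank_and_prune <- function(trace, train, top_frac = 0.10, min_keep = 40,
                           r_thresh = 0.5) {
  stopifnot(inherits(trace, "selection_trace"))
  f <- trace$frequency
  survivors <- names(f)[f > 0]
  if (length(survivors) == 0L) {
    warning("no features survived screening")
    return(character(0))
  }
  ord <- order(-f[survivors], -trace$mean_abs_t[match(survivors, names(f))],
               survivors)
  ranked <- survivors[ord]
  n_top <- min(length(ranked), max(ceiling(top_frac * length(ranked)), min_keep))
  ranked <- ranked[seq_len(n_top)]
  keep <- character(0)
  for (fname in ranked) {
    if (length(keep) == 0L) { keep <- fname; next }
    r <- suppressWarnings(
      stats::cor(train[, fname], train[, keep, drop = FALSE]))
    r[is.na(r)] <- 0
    if (all(abs(r) <= r_thresh)) keep <- c(keep, fname)
  }
  keep
}

#' Nested-prefix subset search
#'
#' Evaluates the nested feature prefixes of the pruned, frequency-ranked list
#' (top-1, top-2, ..., top-K), fitting the ridge classifier on the training
#' cohort for each prefix and scoring it on the evaluation cohort; returns
#' the prefix with the largest evaluation AUC (ties go to the smaller
#' subset). In the modelled protocol the evaluation cohort is the *testing*
#' cohort — a deliberate reproduction of that design, which leaks test
#' information into subset size; see [repeated_evaluation()]'s
#' `subset_selection = "nested"` for the leakage-free alternative.
#'
#' @param pruned Character vector of candidate features (frequency order).
#' @param train,train_labels Training data.
#' @param eval_data,eval_labels Evaluation data used to pick the subset size.
#' @param alpha_grid,n_folds,seed Passed to [fit_ridge()].
#' @return List with `features` (the chosen prefix), `auc` (its evaluation
#'   AUC) and `auc_by_size` (evaluation AUC per prefix size).
#' @export
prefix_search <- function(pruned, train, train_labels, eval_data, eval_labels,
                          alpha_grid = default_alpha_grid(), n_folds = 10,
                          seed = 1L) {
  if (length(pruned) == 0L) stop("pruned feature list is empty")
  aucs <- numeric(length(pruned))
  for (k in seq_along(pruned)) {
    fs <- pruned[seq_len(k)]
    fit <- fit_ridge(train[, fs, drop = FALSE], train_labels,
                     alpha_grid = alpha_grid, n_folds = n_folds, seed = seed)
    sc <- predict_ridge(fit, eval_data[, fs, drop = FALSE])
    aucs[k] <- auc_rank(sc$score, eval_labels)
  }
  best <- which.max(aucs)   # which.max returns the first (smallest) maximizer
  list(features = pruned[seq_len(best)], auc = aucs[best], auc_by_size = aucs)
}
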