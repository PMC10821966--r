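#' Extract radiomics and dosiomics feature matrices for a cohort
#'
#' Runs the per-VOI extractors over every patient: radiomics profiles of the
#' CT ([extract_radiomics_profile()]) and dosiomics profiles of the dose
#' ([extract_dose_profile()]) for ESO, GTV and the union VOI EG. Column
#' names are prefixed with the VOI so matrices can be concatenated without
#' collision. The per-patient filter bank is computed once and shared across
#' the three VOIs.
#'
#' @param cohort A `synthetic_cohort` (or any list of patients with `ct`,
#'   `dose`, `eso_mask`, `gtv_mask`, `id`).
#' @param cfg A [filter_config()] for the radiomics block.
#' @param x_percent,x_gy,dose_bins Dosiomics parameters.
#' @param vois VOIs to extract (subset of ESO, GTV, EG).
#' @return List with `radiomics` and `dosiomics`, each a named list of
#'   patients x features matrices per VOI, plus `labels` and `patient_ids`.
#' @export
extract_cohort_features <- function(cohort, cfg = filter_config(),
                                    x_percent = default_dx_grid(),
                                    x_gy = default_vx_grid(),
                                    dose_bins = 25,
                                    vois = c("ESO", "GTV", "EG")) {
  stopifnot(length(cohort) > 0L)
  ids <- vapply(cohort, `[[`, "", "id")
  rad <- stats::setNames(vector("list", length(vois)), vois)
  dos <- stats::setNames(vector("list", length(vois)), vois)
  rows_r <- lapply(vois, function(v) vector("list", length(cohort)))
  names(rows_r) <- vois
  rows_d <- rows_r
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    masks <- list(ESO = p$eso_mask, GTV = p$gtv_mask,
                  EG = combine_masks(p$eso_mask, p$gtv_mask))
    bank <- build_filter_bank(p$ct, cfg)
    for (v in vois) {
      r <- extract_radiomics_profile(p$ct, masks[[v]], cfg, bank = bank)
      d <- extract_dose_profile(p$dose, masks[[v]], x_percent, x_gy, dose_bins)
      names(r) <- paste0(v, "_", names(r))
      names(d) <- paste0(v, "_", names(d))
      rows_r[[v]][[i]] <- r
      rows_d[[v]][[i]] <- d
    }
  }
  for (v in vois) {
    rad[[v]] <- do.call(rbind, rows_r[[v]])
    dos[[v]] <- do.call(rbind, rows_d[[v]])
    rownames(rad[[v]]) <- rownames(dos[[v]]) <- ids
  }
  labels <- vapply(cohort, function(p) as.integer(p$label), 0L)
  list(radiomics = rad, dosiomics = dos, labels = labels, patient_ids = ids)
}

#' Assemble the nine VOI-by-omics feature groups
#'
#' Builds the nine model feature matrices: \{ESO, GTV, EG\} x \{R, D, RD\}.
#' RD groups are column concatenations of the VOI's radiomics and dosiomics
#' blocks. By default (`eg_mode = "union"`) the EG groups are features
#' extracted on the union mask — EG as a VOI in its own right; with
#' `eg_mode = "concat"` they are instead the concatenated ESO and GTV
#' feature sets, the reading suggested by per-VOI attributions of selected
#' features inside combined models. Both modes keep all nine tags.
#'
#' @param features Output of [extract_cohort_features()] (needs ESO, GTV and
#'   — for union mode — EG).
#' @param eg_mode `"union"` or `"concat"`.
#' @return Named list of nine matrices: `ESO-R`, `GTV-R`, `EG-R`, `ESO-D`,
#'   `GTV-D`, `EG-D`, `ESO-RD`, `GTV-RD`, `EG-RD`.
#' @export
assemble_feature_groups <- function(features, eg_mode = c("union", "concat")) {
  eg_mode <- match.arg(eg_mode)
  rad <- features$radiomics; dos <- features$dosiomics
  ids <- features$patient_ids
  for (m in c(rad, dos))
    if (!identical(rownames(m), ids))
      stop("patient index mismatch across feature tables")
  eg_r <- if (eg_mode == "union") rad$EG else cbind(rad$ESO, rad$GTV)
  eg_d <- if (eg_mode == "union") dos$EG else cbind(dos$ESO, dos$GTV)
  if (is.null(eg_r) || is.null(eg_d))
    stop("EG features unavailable: extract the EG VOI or use eg_mode = 'concat'")
  groups <- list(
    `ESO-R` = rad$ESO, `GTV-R` = rad$GTV, `EG-R` = eg_r,
    `ESO-D` = dos$ESO, `GTV-D` = dos$GTV, `EG-D` = eg_d,
    `ESO-RD` = cbind(rad$ESO, dos$ESO),
    `GTV-RD` = cbind(rad$GTV, dos$GTV),
    `EG-RD` = cbind(eg_r, eg_d))
  stopifnot(!anyDuplicated(names(groups)))
  groups
}

#' Run the full nine-model study
#'
#' End-to-end orchestration: cohort generation (or ingestion from a cohort
#' directory), per-VOI feature extraction, assembly of the nine feature
#' groups, repeated-split evaluation of each group, paired model comparison
#' and decision-curve analysis — followed by report serialization
#' (`table2_metrics.csv`, `table3_ci.csv`, `dca_curves.csv`,
#' `pairwise_tests.csv`, `selected_features.csv`, `config.json`). Every CSV
#' carries a `run_id` column (a hash of the configuration plus the seed) so
#' reruns are attributable; identical configuration and seed reproduce
#' byte-identical outputs.
#'
#' @param cohort A `cohort_spec`, a generated `synthetic_cohort` or a cohort
#'   directory path ([write_cohort()] layout).
#' @param out_dir Output directory for the report bundle (`NULL` to skip
#'   writing).
#' @param cfg Radiomics [filter_config()].
#' @param n_iter,seed,subset_selection,n_resamples Evaluation parameters,
#'   see [repeated_evaluation()].
#' @param eg_mode EG assembly mode, see [assemble_feature_groups()].
#' @param x_percent,x_gy,dose_bins Dosiomics parameters.
#' @return List with `reports` (nine `eval_report`s), `table2`, `table3`,
#'   `pairwise`, `dca`, `run_id` (invisibly if `out_dir` is set).
#' @export
run_study <- function(cohort, out_dir = NULL, cfg = filter_config(),
                      n_iter = 30, seed = 1L,
                      subset_selection = c("test", "nested"),
                      n_resamples = 100, eg_mode = c("union", "concat"),
                      x_percent = default_dx_grid(), x_gy = default_vx_grid(),
                      dose_bins = 25) {
  subset_selection <- match.arg(subset_selection)
  eg_mode <- match.arg(eg_mode)
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (length(cohort) < 10L) stop("cohort too small for a 7:3 split study")
  feats <- extract_cohort_features(cohort, cfg, x_percent, x_gy, dose_bins,
                                   vois = if (eg_mode == "union")
                                     c("ESO", "GTV", "EG") else c("ESO", "GTV"))
  groups <- assemble_feature_groups(feats, eg_mode)
  config <- list(n_patients = length(cohort), n_iter = n_iter, seed = seed,
                 subset_selection = subset_selection, eg_mode = eg_mode,
                 n_resamples = n_resamples,
                 log_sigmas = cfg$log_sigmas, bin_numbers = cfg$bin_numbers,
                 wavelet_subbands = cfg$wavelet_subbands,
                 dx_grid = x_percent, vx_grid = x_gy, dose_bins = dose_bins)
  run_id <- config_hash(config)
  reports <- lapply(names(groups), function(tag) {
    repeated_evaluation(groups[[tag]], feats$labels, n_iter = n_iter,
                        seed = seed, n_resamples = n_resamples,
                        subset_selection = subset_selection, model_tag = tag)
  })
  names(reports) <- names(groups)

  summ <- do.call(rbind, lapply(reports, `[[`, "summary"))
  table2 <- stats::reshape(
    summ[, c("model", "cohort", "metric", "mean")],
    idvar = c("metric", "cohort"), timevar = "model", direction = "wide")
  names(table2) <- sub("^mean\\.", "", names(table2))
  table2 <- table2[order(match(table2$metric, c("AUC", "ACC", "Pre", "Re", "F1")),
                         table2$cohort), ]
  auc_ci_tab <- summ[summ$metric == "AUC",
                     c("model", "cohort", "mean", "sd", "ci_lower", "ci_upper")]

  pairs <- utils::combn(names(reports), 2, simplify = FALSE)
  if (n_iter < 2L) pairs <- list()   # paired t-tests need >= 2 iterations
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(c("train", "test"), function(co) {
      a <- reports[[pr[1]]]$per_iteration
      b <- reports[[pr[2]]]$per_iteration
      pt <- suppressWarnings(paired_model_test(a$AUC[a$cohort == co],
                                               b$AUC[b$cohort == co]))
      data.frame(model_a = pr[1], model_b = pr[2], cohort = co,
                 mean_diff = pt$mean_diff, t = pt$t, p = pt$p)
    }))
  }))
  if (is.null(pairwise))
    pairwise <- data.frame(model_a = character(0), model_b = character(0),
                           cohort = character(0), mean_diff = numeric(0),
                           t = numeric(0), p = numeric(0))

  dca <- do.call(rbind, lapply(names(reports), function(tag) {
    do.call(rbind, lapply(c("train", "test"), function(co) {
      cbind(model = tag, cohort = co, reports[[tag]]$dca[[co]])
    }))
  }))

  out <- list(reports = reports, table2 = table2, table3 = auc_ci_tab,
              pairwise = pairwise, dca = dca, run_id = run_id,
              config = config, labels = feats$labels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) {
      df$run_id <- rep_len(run_id, nrow(df))
      utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
    }
    wr(table2, "table2_metrics.csv")
    wr(auc_ci_tab, "table3_ci.csv")
    wr(pairwise, "pairwise_tests.csv")
    wr(dca, "dca_curves.csv")
    sel <- do.call(rbind, lapply(names(reports), function(tag) {
      data.frame(model = tag,
                 iteration = rep(seq_along(reports[[tag]]$selected),
                                 lengths(reports[[tag]]$selected)),
                 feature = unlist(reports[[tag]]$selected))
    }))
    wr(sel, "selected_features.csv")
    jsonlite::write_json(c(config, list(run_id = run_id)),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1))
  sprintf("%08x", h %% .Machine$integer.max)
}
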