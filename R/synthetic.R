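#' Synthetic cohort specification
#'
#' States the world a generated cohort lives in: cohort size, target
#' esophageal-fistula prevalence, the coefficients of the label-generating
#' logistic model, residual logit noise, lattice geometry and the RNG seed
#' (which fixes all randomness). Defaults emulate the modelled clinical
#' cohort: prevalence 149/287 (the 1:1.08 EF:NEF balance), anisotropic
#' 3 mm slices, and an effect vector in which an esophagus CT texture driver
#' dominates while dose-shape (a craniocaudal GTV dose moment), esophagus
#' high-dose coverage (V50) and the fraction-dose covariate contribute —
#' mirroring the finding that esophagus radiomics carry most of the signal
#' with dose features adding to it.
#'
#' @param n_patients Number of patients (>= 2, or 0 for an empty cohort).
#' @param prevalence Target EF fraction in (0, 1).
#' @param effect_vector Named coefficients on the standardized drivers
#'   `eso_texture` (GLCM joint entropy of CT in ESO), `eso_v50` (fraction of
#'   ESO receiving > 50 Gy), `gtv_moment` (dose moment eta_003 in GTV) and
#'   `fraction_dose` (indicator of 2.0 Gy fractions).
#' @param noise_sd Residual logit noise standard deviation.
#' @param grid_shape,spacing Lattice dimensions and voxel size (mm).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 287,
                        prevalence = 149 / 287,
                        effect_vector = c(eso_texture = 1.2, eso_v50 = 0.8,
                                          gtv_moment = 0.8, fraction_dose = 0.5),
                        noise_sd = 0.5,
                        grid_shape = c(16, 16, 24),
                        spacing = c(2, 2, 3),
                        seed = 1L) {
  if (n_patients != 0 && n_patients < 2) stop("n_patients must be 0 or >= 2")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  known <- c("eso_texture", "eso_v50", "gtv_moment", "fraction_dose")
  if (is.null(names(effect_vector)) || !all(names(effect_vector) %in% known))
    stop("effect_vector names must be among: ", paste(known, collapse = ", "))
  ev <- stats::setNames(numeric(length(known)), known)
  ev[names(effect_vector)] <- effect_vector
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 effect_vector = ev, noise_sd = noise_sd,
                 grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic esophageal-cancer cohort
#'
#' Builds `n_patients` complete synthetic patients: a tubular esophagus mask
#' with per-patient radius jitter and a gently curving axis, an ellipsoidal
#' GTV centered on the tube (so tumor and esophagus always overlap), CT
#' intensities as a smoothed Gaussian random field with tissue offsets, a
#' target-conformal anisotropic Gaussian dose distribution scaled to the
#' per-patient prescription (30 fractions of the sampled fraction dose), and
#' clinical covariates drawn from the pooled category frequencies of the
#' modelled cohort ([table1_fixtures()] is the single source of truth). The
#' EF label is drawn from `Bernoulli(plogis(b0 + beta . z + noise))` where
#' `z` are the cohort-standardized drivers computed by the real dosiomics /
#' radiomics operations and `b0` is solved so the expected prevalence matches
#' the specification. The same seed reproduces the cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A list of patients (class `synthetic_cohort`), each with elements
#'   `id`, `ct`, `dose`, `eso_mask`, `gtv_mask`, `clinical` (one-row
#'   data.frame), `label` (0/1) and `drivers`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_patients == 0L) return(structure(list(), class = "synthetic_cohort",
                                              spec = spec))
  d <- spec$grid_shape
  sp <- spec$spacing
  ext <- d * sp
  if (any(ext[1:2] < 24) || ext[3] < 36)
    stop("grid too small to contain the esophagus and tumor VOIs: need >= 24 mm ",
         "laterally and >= 36 mm craniocaudally, got ",
         paste(round(ext), collapse = " x "), " mm")
  set.seed(spec$seed)
  marg <- lapply(table1_fixtures(), colSums)
  patients <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    patients[[i]] <- generate_patient(i, d, sp, marg)
  }
  drv <- t(vapply(patients, function(p) p$drivers, numeric(4L)))
  z <- apply(drv, 2, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  eta <- drop(z %*% spec$effect_vector) +
    stats::rnorm(spec$n_patients, 0, spec$noise_sd)
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) - spec$prevalence,
                       c(-30, 30))$root
  y <- stats::rbinom(spec$n_patients, 1L, stats::plogis(b0 + eta))
  for (i in seq_len(spec$n_patients)) patients[[i]]$label <- y[i]
  structure(patients, class = "synthetic_cohort", spec = spec)
}

generate_patient <- function(i, d, sp, marg) {
  id <- sprintf("P%03d", i)
  # physical coordinates of voxel centers
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  ext <- d * sp

  # esophagus: axial tube, jittered radius, sinusoidal axis wiggle
  r_eso <- max(3.5, stats::rnorm(1, 5, 0.6))
  cx0 <- ext[1] / 2 + stats::rnorm(1, 0, 1.5)
  cy0 <- ext[2] / 2 + stats::rnorm(1, 0, 1.5)
  amp <- stats::runif(1, 0, 2); phase <- stats::runif(1, 0, 2 * pi)
  eso <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    cx <- cx0 + amp * sin(2 * pi * zs[k] / ext[3] + phase)
    rk <- r_eso * stats::runif(1, 0.9, 1.1)
    eso[, , k] <- outer((xs - cx)^2, (ys - cy0)^2, `+`) <= rk^2
  }

  # GTV: ellipsoid centered on the tube near mid-height
  cz <- ext[3] / 2 + stats::rnorm(1, 0, ext[3] / 10)
  ax <- stats::runif(1, 7, 11); ay <- stats::runif(1, 7, 11)
  az <- stats::runif(1, 10, 16)
  gx <- cx0 + stats::rnorm(1, 0, 2); gy <- cy0 + stats::rnorm(1, 0, 2)
  u2 <- outer(((xs - gx) / ax)^2, ((ys - gy) / ay)^2, `+`)
  gtv <- outer(u2, ((zs - cz) / az)^2, `+`) <= 1
  if (!any(gtv & eso)) {  # enforce anatomical contact (tumor abuts esophagus)
    gtv <- outer(outer(((xs - cx0) / ax)^2, ((ys - cy0) / ay)^2, `+`),
                 ((zs - ext[3] / 2) / az)^2, `+`) <= 1
  }

  # CT: smoothed Gaussian random field + tissue offsets
  grf <- gaussian_smooth(volume_grid(array(stats::rnorm(prod(d)), d), sp), 4)$values
  grf <- grf / stats::sd(grf) * 30
  ct_vals <- grf - 50 + 80 * eso + 120 * gtv +
    array(stats::rnorm(prod(d), 0, 10), d)
  ct <- volume_grid(ct_vals, sp)

  # clinical covariates from pooled category frequencies
  draw <- function(tab) sample(names(tab), 1L, prob = tab)
  frac_dose <- if (draw(marg$fraction_dose) == "1.8") 1.8 else 2.0
  clinical <- data.frame(
    patient_id = id,
    gender = draw(marg$gender),
    age = round(min(87, max(39, stats::rnorm(1, 66, 8)))),
    bmi = round(min(32.7, max(13.8, stats::rnorm(1, 21.6, 3))), 1),
    pathology = draw(marg$pathology),
    t_stage = draw(marg$t_stage),
    n_stage = draw(marg$n_stage),
    m_stage = draw(marg$m_stage),
    overall_stage = draw(marg$overall_stage),
    lesion_location = draw(marg$lesion_location),
    treatment = draw(marg$treatment),
    fraction_dose = frac_dose,
    stringsAsFactors = FALSE)

  # dose: anisotropic Gaussian conformal to the GTV, scaled to prescription
  rx <- frac_dose * 30                 # 54 or 60 Gy total
  sigd <- c(ax, ay, az) * 1.3 + 4
  dz2 <- outer(outer(((xs - gx) / sigd[1])^2, ((ys - gy) / sigd[2])^2, `+`),
               ((zs - cz) / sigd[3])^2, `+`)
  dose_vals <- rx * exp(-0.5 * dz2) *
    (1 + array(stats::rnorm(prod(d), 0, 0.02), d))
  dose_vals[dose_vals < 0] <- 0
  dose <- volume_grid(dose_vals, sp)

  eso_m <- voi_mask(eso, "ESO")
  gtv_m <- voi_mask(gtv, "GTV")
  drivers <- c(
    eso_texture = unname(extract_texture(ct, eso_m, 20)["glcm_JointEntropy"]),
    eso_v50 = unname(compute_dvh(dose, eso_m, 50, 50)$Vx),
    gtv_moment = unname(compute_dose_moments(dose, gtv_m)["moment_eta_003"]),
    fraction_dose = as.numeric(frac_dose == 2.0))

  list(id = id, ct = ct, dose = dose, eso_mask = eso_m, gtv_mask = gtv_m,
       clinical = clinical, drivers = drivers, label = NA_integer_)
}

#' Clinical contingency-table fixtures
#'
#' The printed EF/NEF counts of the modelled cohort's clinical
#' characteristics table (287 patients: 149 EF, 138 NEF), as named 2-row
#' contingency tables. These serve both as fixtures for the clinical
#' statistics and as the single source of truth for the synthetic generator's
#' covariate marginals. Categories with all-zero counts (T1, overall stage I)
#' are retained here and dropped by [pearson_chi2()] before testing.
#'
#' @return Named list of integer matrices with rows `EF`, `NEF`.
#' @export
table1_fixtures <- function() {
  tb <- function(ef, nef, cats)
    matrix(as.integer(c(ef, nef)), nrow = 2, byrow = TRUE,
           dimnames = list(c("EF", "NEF"), cats))
  list(
    gender = tb(c(115, 34), c(94, 44), c("Male", "Female")),
    pathology = tb(c(147, 2), c(138, 0), c("Squamous", "Adenocarcinoma")),
    t_stage = tb(c(0, 10, 105, 34), c(0, 11, 101, 26), c("T1", "T2", "T3", "T4")),
    n_stage = tb(c(13, 92, 39, 5), c(22, 70, 38, 8), c("N0", "N1", "N2", "N3")),
    m_stage = tb(c(126, 23), c(120, 18), c("M0", "M1")),
    overall_stage = tb(c(0, 15, 81, 53), c(0, 22, 73, 43), c("I", "II", "III", "IV")),
    lesion_location = tb(c(9, 23, 103, 14), c(11, 24, 80, 23),
                         c("Cervical", "Upper", "Middle", "Lower")),
    treatment = tb(c(99, 23, 27), c(87, 18, 33), c("CCRT", "SRT", "RT")),
    fraction_dose = tb(c(78, 71), c(106, 32), c("1.8", "2.0")))
}

#' Write / read a cohort directory
#'
#' Serializes a synthetic cohort to the on-disk layout used for real data:
#' per-patient `<id>_ct.nii.gz`, `<id>_dose.nii.gz`, `<id>_eso.nii.gz`,
#' `<id>_gtv.nii.gz`, plus `clinical.csv`, `labels.csv` and a
#' `cohort_spec.yaml` recording all generator parameters and the seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: a list with
#'   per-patient volumes/masks, `clinical` and `labels`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort) {
    write_nifti(p$ct, file.path(dir, paste0(p$id, "_ct.nii.gz")))
    write_nifti(p$dose, file.path(dir, paste0(p$id, "_dose.nii.gz")))
    write_nifti(p$eso_mask, file.path(dir, paste0(p$id, "_eso.nii.gz")))
    write_nifti(p$gtv_mask, file.path(dir, paste0(p$id, "_gtv.nii.gz")))
  }
  clin <- do.call(rbind, lapply(cohort, `[[`, "clinical"))
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(data.frame(patient_id = vapply(cohort, `[[`, "", "id"),
                              label = vapply(cohort, `[[`, 0L, "label")),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    ev <- spec$effect_vector
    writeLines(c(
      sprintf("n_patients: %d", spec$n_patients),
      sprintf("prevalence: %.10g", spec$prevalence),
      "effect_vector:",
      sprintf("  %s: %.10g", names(ev), ev),
      sprintf("noise_sd: %.10g", spec$noise_sd),
      sprintf("grid_shape: [%s]", paste(spec$grid_shape, collapse = ", ")),
      sprintf("spacing: [%s]", paste(spec$spacing, collapse = ", ")),
      sprintf("seed: %d", spec$seed)),
      file.path(dir, "cohort_spec.yaml"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  clin <- utils::read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
  labs <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  pats <- lapply(clin$patient_id, function(id) {
    list(id = id,
         ct = read_nifti(file.path(dir, paste0(id, "_ct.nii.gz"))),
         dose = read_nifti(file.path(dir, paste0(id, "_dose.nii.gz"))),
         eso_mask = as_voi_mask(read_nifti(file.path(dir, paste0(id, "_eso.nii.gz"))), "ESO"),
         gtv_mask = as_voi_mask(read_nifti(file.path(dir, paste0(id, "_gtv.nii.gz"))), "GTV"),
         clinical = clin[clin$patient_id == id, , drop = FALSE],
         label = labs$label[match(id, labs$patient_id)])
  })
  structure(pats, class = "synthetic_cohort")
}
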