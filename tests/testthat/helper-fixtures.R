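# Shared fixtures, built lazily once per test session. Cohort generation and
# feature extraction are the expensive steps, so tests that share a world
# (planted-driver cohort, default-effect cohort) reuse one instance.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

random_grid <- function(dim = c(5, 5, 5), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  volume_grid(array(stats::rnorm(prod(dim)), dim), spacing = spacing)
}

full_mask <- function(dim = c(5, 5, 5), name = "GTV") {
  voi_mask(array(TRUE, dim), name)
}

sphere_mask <- function(r = 20, margin = 3) {
  n <- 2 * (r + margin) + 1
  c0 <- r + margin + 1
  co <- (1:n) - c0
  d2 <- outer(outer(co^2, co^2, `+`), co^2, `+`)
  voi_mask(array(d2 <= r^2, c(n, n, n)), "GTV")
}

# cohort with a single strong dose-moment driver and no logit noise
planted_cohort <- function() cached("planted", {
  generate_cohort(cohort_spec(n_patients = 300,
                              effect_vector = c(gtv_moment = 3),
                              noise_sd = 0, seed = 21))
})

planted_gtv_dose_features <- function() cached("planted_dose", {
  co <- planted_cohort()
  t(vapply(co, function(p) extract_dose_profile(p$dose, p$gtv_mask),
           numeric(213)))
})

# cohort under the default (mixed-driver) effect vector
mixed_cohort <- function() cached("mixed", {
  generate_cohort(cohort_spec(n_patients = 300, seed = 41))
})

# reduced filter configuration: original image only, one bin number.
# Keeps extraction tractable inside the suite's runtime budget; the
# directional and null properties do not depend on the full 12x5 bank.
reduced_cfg <- function() filter_config(log_sigmas = numeric(0),
                                        wavelet_subbands = character(0),
                                        bin_numbers = 20)

mixed_cohort_groups <- function() cached("mixed_groups", {
  co <- mixed_cohort()
  fe <- extract_cohort_features(co, reduced_cfg())
  list(groups = assemble_feature_groups(fe), labels = fe$labels)
})

cohort_labels <- function(cohort) vapply(cohort, `[[`, 0L, "label")
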