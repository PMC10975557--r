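# Shared fixtures: all synthetic data are generated in code, at fixed seeds.

aa_ref_vec <- function() {
  setNames(aa_reference()$geometric_mean, aa_reference()$abbrev)
}

aa_ref_closed <- function() close_composition(aa_ref_vec())

# Small analyzed cohort (no exclusion rows) for model-level tests.
small_cohort <- function(n = 300, seed = 101, ...) {
  cfg <- generator_config(
    n = n, seed = seed,
    exclusion_counts = c(missing_questionnaire = 0, implausible_energy = 0,
                         missing_items = 0, disease = 0),
    ...
  )
  generate_cohort(cfg)
}

# A toy 3-part composition spec fitted on exactly linear clr data, so the
# model recovers the generating clr coefficients with zero residual noise.
toy_fit <- function(a = c(A = 2, B = -3, C = 1), n = 40, seed = 5,
                    sign_convention = "reversed") {
  stopifnot(abs(sum(a)) < 1e-12)
  set.seed(seed)
  w <- matrix(exp(rnorm(n * length(a), sd = 0.2)), n)
  colnames(w) <- names(a)
  comp <- close_composition(w)
  dat <- tibble::as_tibble(comp)
  dat$y <- drop(clr_transform(comp) %*% a)
  spec <- model_spec("glucose", covariates = character(),
                     composition_cols = names(a),
                     sign_convention = sign_convention)
  spec$outcome <- "y"
  spec$outcome_label <- "y"
  spec$log_transform <- FALSE
  fit_composition_model(dat, spec)
}
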