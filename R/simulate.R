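# Synthetic cohort generator: logistic-normal 18-part amino-acid
# composition, covariate marginals matching the study population the
# package is calibrated to, and outcomes generated linearly from the clr
# composition plus covariates with Gaussian noise. Ground-truth effects
# travel with the generated table so recovery tests can score themselves.

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the calibration cohort: n = 1238 adolescents,
#' logistic-normal composition centred on the [aa_reference()] geometric
#' means with per-component log-scale SDs matched to the reference share
#' SDs, covariate marginals from the descriptive statistics of the same
#' population, fasting glucose with mean 90.6 mg/dL and total SD close to
#' 5.6, lognormal insulin with geometric mean 6.19 uU/mL, and
#' 15/40/150/4 disjoint exclusion rows injected on top of `n`.
#'
#' The default ground-truth clr effect vector for glucose makes leucine
#' protective (negative clr coefficient) and isoleucine and methionine
#' adverse, the qualitative pattern the analysis is designed to detect;
#' insulin (and hence the HOMA indices) carries no composition effect by
#' default.
#'
#' @param n Analyzed cohort size (clean rows), default 1238.
#' @param seed Integer RNG seed.
#' @param composition_mean Named vector of geometric-mean shares (percent).
#' @param composition_sd Named vector of per-component share SDs (percent).
#' @param log_covariance Optional D x D PSD covariance of log shares;
#'   default `diag((composition_sd / composition_mean)^2)`.
#' @param true_clr_effects List with sum-zero named vectors `glucose` and
#'   `log_insulin`: outcome change per unit clr coordinate.
#' @param covariate_effects List of named vectors (per outcome) of linear
#'   effects of numeric covariates, applied to deviations from their
#'   nominal means.
#' @param noise_sd Named vector: residual SD of `glucose` (mg/dL) and
#'   `log_insulin` (log units).
#' @param outcome_mean Named vector: marginal mean glucose (mg/dL) and mean
#'   log insulin.
#' @param exclusion_counts Named integer vector of rows to inject per
#'   exclusion reason (disjoint flags).
#' @param confound_protein_bcaa Optional slope tying protein (%E) to the
#'   centred BCAA share sum, for confounding stress tests; default 0
#'   (covariates independent of composition).
#' @param eer EER table used to keep clean rows energy-plausible and to
#'   construct implausible-energy rows.
#' @return A list of class `aa_generator_config`.
#' @export
generator_config <- function(n = 1238,
                             seed = 1L,
                             composition_mean = NULL,
                             composition_sd = NULL,
                             log_covariance = NULL,
                             true_clr_effects = NULL,
                             covariate_effects = NULL,
                             noise_sd = c(glucose = 5.0, log_insulin = 0.45),
                             outcome_mean = c(glucose = 90.6,
                                              log_insulin = log(6.19)),
                             exclusion_counts = c(missing_questionnaire = 15,
                                                  implausible_energy = 40,
                                                  missing_items = 150,
                                                  disease = 4),
                             confound_protein_bcaa = 0,
                             eer = synthetic_eer_table()) {
  ref <- aa_reference()
  comp_names <- ref$abbrev
  composition_mean <- composition_mean %||%
    setNames(ref$geometric_mean, comp_names)
  composition_sd <- composition_sd %||% setNames(ref$sd, comp_names)
  if (is.null(log_covariance)) {
    cv <- composition_sd / setNames(ref$arithmetic_mean, comp_names)
    log_covariance <- diag(cv^2)
    dimnames(log_covariance) <- list(comp_names, comp_names)
  }
  if (is.null(true_clr_effects)) {
    a <- setNames(numeric(length(comp_names)), comp_names)
    a[c("ILE", "LEU", "MET")] <- c(35, -60, 25)
    true_clr_effects <- list(
      glucose = a,
      log_insulin = setNames(numeric(length(comp_names)), comp_names)
    )
  }
  for (nm in names(true_clr_effects)) {
    if (abs(sum(true_clr_effects[[nm]])) > 1e-8) {
      abort(paste0("`true_clr_effects$", nm, "` must sum to zero"))
    }
  }
  covariate_effects <- covariate_effects %||% list(
    glucose = c(zbmi = 0.5, energy_kcal = 0.0015,
                protein_pctE = 0.4, fiber_g1000 = -0.7),
    log_insulin = c(zbmi = 0.15)
  )
  if (any(noise_sd <= 0)) abort("`noise_sd` must be positive")
  structure(
    list(n = n, seed = as.integer(seed),
         composition_mean = composition_mean,
         composition_sd = composition_sd,
         log_covariance = log_covariance,
         true_clr_effects = true_clr_effects,
         covariate_effects = covariate_effects,
         noise_sd = noise_sd,
         outcome_mean = outcome_mean,
         exclusion_counts = exclusion_counts,
         confound_protein_bcaa = confound_protein_bcaa,
         eer = eer),
    class = "aa_generator_config"
  )
}

# Square root factor of a PSD matrix; chol when possible, else eigen with a
# tolerance-checked spectrum.
.psd_factor <- function(sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  ev <- eigen(sigma, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values), 1))) {
    abort("`log_covariance` is not positive semi-definite")
  }
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(sigma))
}

# Truncated-normal draws by resampling (bounds are several SDs out for all
# default marginals, so the expected number of redraws is tiny).
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower[bad] | x[bad] > upper[bad]]
  }
  x
}

#' Draw logistic-normal compositions
#'
#' Log shares are drawn from a multivariate normal centred at
#' `log(composition_mean)` with covariance `log_covariance`, exponentiated
#' and closed to 100. Component-wise geometric means converge to
#' `composition_mean` (closed) as n grows.
#'
#' @param n Number of compositions.
#' @param config A [generator_config()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A tibble of `n` rows with one share column per component.
#' @export
generate_composition <- function(n, config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- log(config$composition_mean)
  d <- length(mu)
  l <- .psd_factor(config$log_covariance)
  z <- matrix(rnorm(n * d), n, d)
  logw <- sweep(z %*% t(l), 2, mu, `+`)
  comp <- close_composition(exp(logw))
  colnames(comp) <- names(mu)
  tibble::as_tibble(comp)
}

# Marginals of the calibration population used for covariate generation.
.covariate_marginals <- function() {
  list(
    male_prop = 0.526,
    age_months = c(163.5, 3.4),
    height_cm = c(160, 7),
    bmi = c(19.2, 2.6),
    zbmi = c(-0.25, 0.90),
    physical_activity = 0.765,
    sleep_h = c(7.4, 0.7),
    screen_h = c(4.2, 1.0),
    single_parent = 0.057,
    passive_smoking = 0.515,
    siblings = c(`1` = 0.095, `2` = 0.475, `3+` = 0.430),
    energy_kcal = c(2266.4, 634.9),
    protein_pctE = c(14.2, 2.3),
    fiber_g1000 = c(5.5, 1.4),
    satfat_pctE = c(10.6, 2.5),
    glycemic_load = c(68.4, 22.5)
  )
}

.generate_rows <- function(n, config) {
  mg <- .covariate_marginals()
  sex <- factor(ifelse(runif(n) < mg$male_prop, "male", "female"),
                levels = c("female", "male"))
  # energy kept inside the plausibility window so clean rows survive the
  # energy filter; bounds come from the generator's EER table
  eer <- config$eer
  ei <- match(as.character(sex), eer$sex)
  if (anyNA(ei)) abort("generator EER table lacks a row for some sex")
  energy <- .rtnorm(n, mg$energy_kcal[1], mg$energy_kcal[2],
                    lower = 0.5 * eer$eer_low_pal[ei],
                    upper = 1.5 * eer$eer_high_pal[ei])
  comp <- generate_composition(n, config)
  protein <- .rtnorm(n, mg$protein_pctE[1], mg$protein_pctE[2], lower = 5)
  if (config$confound_protein_bcaa != 0) {
    bcaa <- rowSums(comp[, c("ILE", "LEU", "VAL")])
    protein <- protein + config$confound_protein_bcaa * (bcaa - mean(bcaa))
  }
  height <- .rtnorm(n, mg$height_cm[1], mg$height_cm[2], lower = 120)
  bmi_v <- .rtnorm(n, mg$bmi[1], mg$bmi[2], lower = 13)
  tbl <- tibble::tibble(
    sex = sex,
    age_months = rnorm(n, mg$age_months[1], mg$age_months[2]),
    height_cm = height,
    bmi = bmi_v,
    weight_kg = bmi_v * (height / 100)^2,
    zbmi = rnorm(n, mg$zbmi[1], mg$zbmi[2]),
    physical_activity = as.integer(runif(n) < mg$physical_activity),
    sleep_h = .rtnorm(n, mg$sleep_h[1], mg$sleep_h[2], lower = 3),
    screen_h = .rtnorm(n, mg$screen_h[1], mg$screen_h[2], lower = 0.2),
    single_parent = as.integer(runif(n) < mg$single_parent),
    passive_smoking = as.integer(runif(n) < mg$passive_smoking),
    siblings = factor(
      sample(names(mg$siblings), n, replace = TRUE, prob = mg$siblings),
      levels = names(mg$siblings)
    ),
    energy_kcal = energy,
    protein_pctE = protein,
    fiber_g1000 = .rtnorm(n, mg$fiber_g1000[1], mg$fiber_g1000[2], lower = 0.5),
    satfat_pctE = .rtnorm(n, mg$satfat_pctE[1], mg$satfat_pctE[2], lower = 2),
    glycemic_load = .rtnorm(n, mg$glycemic_load[1], mg$glycemic_load[2],
                            lower = 10)
  )
  dplyr::bind_cols(tbl, comp)
}

.generate_outcomes <- function(rows, config) {
  mg <- .covariate_marginals()
  comp_names <- names(config$composition_mean)
  clr <- clr_transform(as.matrix(rows[comp_names]))
  mu <- log(config$composition_mean)
  clr_centred <- sweep(clr, 2, mu - mean(mu), `-`)
  lin <- function(outcome) {
    a <- config$true_clr_effects[[outcome]]
    eff <- drop(clr_centred[, names(a), drop = FALSE] %*% a)
    for (cv in names(config$covariate_effects[[outcome]])) {
      eff <- eff + config$covariate_effects[[outcome]][[cv]] *
        (rows[[cv]] - mg[[cv]][1])
    }
    eff
  }
  n <- nrow(rows)
  det_glu <- config$outcome_mean[["glucose"]] + lin("glucose")
  # keep glucose well above the 3.5 mmol/L HOMA-beta pole (~63 mg/dL) and
  # in a physiologic fasting range; redraws are ~4.5 SD events
  glucose <- det_glu + rnorm(n, 0, config$noise_sd[["glucose"]])
  bad <- which(glucose < 67 | glucose > 125)
  while (length(bad)) {
    glucose[bad] <- det_glu[bad] +
      rnorm(length(bad), 0, config$noise_sd[["glucose"]])
    bad <- bad[glucose[bad] < 67 | glucose[bad] > 125]
  }
  log_ins <- config$outcome_mean[["log_insulin"]] + lin("log_insulin") +
    rnorm(n, 0, config$noise_sd[["log_insulin"]])
  rows$glucose <- glucose
  rows$insulin <- exp(log_ins)
  add_glycemic_markers(rows)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces `n` clean participant rows plus the configured number of
#' excluded rows (unanswered questionnaire, implausible energy, missing
#' items, physician-diagnosed disease; flags disjoint by construction), in
#' the package's canonical cohort schema. Outcomes are linear in the
#' centred clr composition and in selected covariates with Gaussian noise;
#' HOMA columns are derived exactly as in the analysis. The generating
#' effect vectors are attached as the `"truth"` attribute
#' (see [cohort_truth()]).
#'
#' @param config A [generator_config()].
#' @return A tibble of `n + sum(exclusion_counts)` rows with attribute
#'   `truth`.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n = 200, seed = 7))
#' dplyr::count(coh, missing_questionnaire, missing_items, disease)
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "aa_generator_config"))
  set.seed(config$seed)
  n <- config$n
  ex <- config$exclusion_counts
  m <- sum(ex)
  rows <- .generate_rows(n + m, config)
  rows <- .generate_outcomes(rows, config)
  rows$missing_questionnaire <- FALSE
  rows$implausible_energy <- FALSE
  rows$missing_items <- FALSE
  rows$disease <- FALSE
  if (m > 0) {
    idx <- n + seq_len(m)
    reason <- rep(names(ex), times = ex)
    comp_names <- names(config$composition_mean)
    diet_cols <- c(comp_names, "energy_kcal", "protein_pctE", "fiber_g1000",
                   "satfat_pctE", "glycemic_load", "sleep_h", "screen_h")
    mq <- idx[reason == "missing_questionnaire"]
    rows[mq, diet_cols] <- NA_real_
    rows$missing_questionnaire[mq] <- TRUE
    ie <- idx[reason == "implausible_energy"]
    rows$energy_kcal[ie] <- rep_len(c(600, 5500), length(ie))
    rows$implausible_energy[ie] <- TRUE
    mi <- idx[reason == "missing_items"]
    rows$fiber_g1000[mi] <- NA_real_
    rows$missing_items[mi] <- TRUE
    dz <- idx[reason == "disease"]
    rows$disease[dz] <- TRUE
  }
  rows <- dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(rows))), rows)
  attr(rows, "truth") <- list(
    seed = config$seed,
    true_clr_effects = config$true_clr_effects,
    covariate_effects = config$covariate_effects,
    noise_sd = config$noise_sd,
    outcome_mean = config$outcome_mean
  )
  rows
}

#' Ground-truth record of a generated cohort
#'
#' @param cohort A tibble from [generate_cohort()].
#' @return The list of generating parameters (seed, clr effect vectors,
#'   covariate effects, noise SDs, outcome means).
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth", exact = TRUE)
  if (is.null(truth)) abort("`cohort` carries no ground-truth record")
  truth
}

#' True first-pivot coefficients implied by a clr effect vector
#'
#' Under the pivot parameterisation the first-coordinate coefficient for
#' component i equals `-sqrt(D/(D-1)) * a_i` (reversed sign convention;
#' negated again for the standard convention), where `a` is the sum-zero
#' clr effect vector. Used to score parameter-recovery simulations.
#'
#' @param a Sum-zero named clr effect vector.
#' @param sign_convention `"reversed"` or `"standard"`.
#' @return Named vector of true first-pivot coefficients.
#' @export
true_pivot_coefficients <- function(a, sign_convention = c("reversed", "standard")) {
  sign_convention <- match.arg(sign_convention)
  d <- length(a)
  s <- if (sign_convention == "reversed") -1 else 1
  s * sqrt(d / (d - 1)) * a
}
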