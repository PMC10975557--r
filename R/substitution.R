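# Predicted-outcome differences for amino-acid replacements at the
# cohort's geometric-mean composition, with delta-method confidence
# intervals (exact for a linear model; CI = effect +/- 2 SE).

#' Geometric-mean reference composition of a cohort
#'
#' Component-wise geometric means across rows, re-closed to 100. This is
#' the reference point at which substitution effects are evaluated.
#'
#' @param data Cohort table (or matrix) of positive share columns.
#' @param cols Composition columns; `NULL` auto-detects the amino-acid
#'   columns.
#' @return Named numeric vector summing to 100.
#' @export
reference_composition <- function(data, cols = NULL) {
  if (is.matrix(data)) {
    comp <- data
  } else {
    data <- tibble::as_tibble(data)
    cols <- .aa_find_columns(data, cols)
    comp <- as.matrix(data[cols])
  }
  .check_positive_rows(comp)
  close_composition(setNames(exp(colMeans(log(comp))), colnames(comp)))
}

# ilr-space contrast between the perturbed and reference composition;
# covariates and the intercept cancel in the predicted difference, so the
# contrast is zero everywhere except the ilr coordinates.
.effect_contrast <- function(fit, ref, p) {
  pert <- apply_perturbation(ref, p)
  dz <- ilr_transform(pert, fit$basis) - ilr_transform(ref, fit$basis)
  contrast <- setNames(numeric(length(fit$coefficients)),
                       names(fit$coefficients))
  contrast[fit$ilr_terms] <- dz
  contrast
}

#' Substitution effect of one replacement
#'
#' Predicted outcome difference between the perturbed and the reference
#' composition, holding all covariates fixed (they cancel exactly in a
#' linear model). The effect is the contrast `c' b` with `c` the ilr-space
#' difference of the two compositions; its standard error is the
#' delta-method `sqrt(c' Cov(b) c)` and the confidence interval is
#' `effect +/- 2 SE`.
#'
#' @param fit An `aa_fit` from [fit_composition_model()].
#' @param p An [perturbation()].
#' @param ref Reference composition; defaults to the geometric-mean
#'   composition of the data the model was fitted on.
#' @return One-row tibble: `outcome`, `kind`, `target`, `source`, `delta`,
#'   `effect`, `se`, `ci_low`, `ci_high`. Effects are in outcome units
#'   (mg/dL for glucose, natural-log units for the log-modelled outcomes).
#' @export
substitution_effect <- function(fit, p, ref = NULL) {
  stopifnot(inherits(fit, "aa_fit"), inherits(p, "aa_perturbation"))
  if (is.null(fit$basis)) abort("`fit` must come from fit_composition_model()")
  ref <- ref %||% fit$reference
  contrast <- .effect_contrast(fit, ref, p)
  effect <- sum(contrast * fit$coefficients)
  se <- sqrt(drop(contrast %*% fit$vcov %*% contrast))
  tibble::tibble(
    outcome = fit$outcome_label,
    kind = p$kind,
    target = .match_component(p$target, names(ref)),
    source = if (is.null(p$source)) NA_character_
             else .match_component(p$source, names(ref)),
    delta = p$delta,
    effect = effect,
    se = se,
    ci_low = effect - 2 * se,
    ci_high = effect + 2 * se
  )
}

#' One-to-all substitution effects for every component
#'
#' For each component in turn: increase its share by `delta` percentage
#' points of total amino acids and decrease each of the other D-1 shares by
#' `delta/(D-1)`, at the reference composition.
#'
#' @inheritParams substitution_effect
#' @param delta Replacement size in percentage points, default 0.1.
#' @return A tibble of class `aa_substitution` with one row per component,
#'   in canonical order; columns as in [substitution_effect()].
#' @export
one_to_all_table <- function(fit, delta = 0.1, ref = NULL) {
  ref <- ref %||% fit$reference
  rows <- purrr::map_dfr(names(ref), function(comp) {
    substitution_effect(fit, perturbation("one_to_all", comp, delta = delta),
                        ref = ref)
  })
  structure(rows, class = c("aa_substitution", class(rows)))
}

#' One-to-one substitution effect matrix
#'
#' Effects for every ordered pair (target increased by `delta`, source
#' decreased by `delta`) at the reference composition, in long format. To
#' first order in `delta` the matrix is antisymmetric
#' (`effect(i,j) ~ -effect(j,i)`), but the exact log-scale computation
#' leaves an O(delta^2) asymmetry between increasing and decreasing a
#' component.
#'
#' @inheritParams one_to_all_table
#' @return A tibble of class `aa_effect_matrix`: one row per ordered pair
#'   (`target`, `source`), diagonal absent; columns as in
#'   [substitution_effect()].
#' @export
one_to_one_matrix <- function(fit, delta = 0.1, ref = NULL) {
  ref <- ref %||% fit$reference
  pairs <- expand.grid(source = names(ref), target = names(ref),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$target != pairs$source, c("target", "source")]
  pairs <- pairs[order(match(pairs$target, names(ref)),
                       match(pairs$source, names(ref))), ]
  rows <- purrr::pmap_dfr(pairs, function(target, source) {
    substitution_effect(
      fit, perturbation("one_to_one", target, source, delta = delta),
      ref = ref
    )
  })
  structure(rows, class = c("aa_effect_matrix", class(rows)))
}

#' Spread a one-to-one effect table into a matrix
#'
#' @param x An `aa_effect_matrix` (long format).
#' @param value Which column to spread, default `"effect"`.
#' @return A D x D numeric matrix (rows = target/increased component,
#'   columns = source/decreased component) with `NA` on the diagonal.
#' @export
effect_matrix <- function(x, value = "effect") {
  stopifnot(inherits(x, "aa_effect_matrix"))
  comps <- unique(x$target)
  m <- matrix(NA_real_, length(comps), length(comps),
              dimnames = list(target = comps, source = comps))
  m[cbind(x$target, x$source)] <- x[[value]]
  m
}
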