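# Multivariate linear models of glycemic outcomes on pivot ilr coordinates
# plus covariates; the repeated-ordering sweep that yields one first-pivot
# coefficient per amino acid; covariate screening, VIF, and the grouped
# (amalgamated) 4-part variant.

#' Specify a composition-outcome regression model
#'
#' @param outcome One of `"glucose"`, `"insulin"`, `"homa_ir"`,
#'   `"homa_beta"`. Insulin and the HOMA indices are natural-log
#'   transformed before fitting (they are right-skewed); glucose is
#'   modelled on the raw mg/dL scale.
#' @param covariates Character vector of adjustment columns. The default is
#'   the full adjustment set: age, sex, BMI z-score, physical activity,
#'   sleep duration, screen time, single parent, passive smoking, siblings,
#'   energy, protein and total dietary fiber.
#' @param composition_cols Names of the composition share columns; `NULL`
#'   (default) auto-detects the 18 amino-acid columns.
#' @param sign_convention Pivot-basis sign convention, `"reversed"`
#'   (default) or `"standard"`; see [pivot_basis()].
#' @return A list of class `aa_model_spec`.
#' @export
#' @examples
#' model_spec("glucose")
model_spec <- function(outcome = c("glucose", "insulin", "homa_ir", "homa_beta"),
                       covariates = default_covariates(),
                       composition_cols = NULL,
                       sign_convention = c("reversed", "standard")) {
  outcome <- match.arg(outcome)
  sign_convention <- match.arg(sign_convention)
  log_outcomes <- c("insulin", "homa_ir", "homa_beta")
  structure(
    list(
      outcome = outcome,
      outcome_label = if (outcome %in% log_outcomes)
        paste0("log_", outcome) else outcome,
      log_transform = outcome %in% log_outcomes,
      covariates = covariates,
      composition_cols = composition_cols,
      sign_convention = sign_convention
    ),
    class = "aa_model_spec"
  )
}

#' @rdname model_spec
#' @export
default_covariates <- function() {
  c("age_months", "sex", "zbmi", "physical_activity", "sleep_h", "screen_h",
    "single_parent", "passive_smoking", "siblings", "energy_kcal",
    "protein_pctE", "fiber_g1000")
}

#' Ordinary least squares with classical covariance
#'
#' Fits `y = X b + e` by QR decomposition and returns the coefficient
#' vector, the classical covariance `sigma2 (X'X)^-1`, the residual
#' variance and degrees of freedom. Errors on rank deficiency, naming the
#' collinear columns.
#'
#' @param x Design matrix (including an intercept column if wanted).
#' @param y Response vector.
#' @return A list of class `aa_fit` with elements `coefficients`, `vcov`,
#'   `sigma2`, `df_resid`, `n`, `fitted`, `residuals`, `r_squared`.
#' @export
fit_linear <- function(x, y) {
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y)) abort("design matrix / outcome contain missing values")
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) abort("need more observations than parameters")
  qx <- qr(x)
  if (qx$rank < p) {
    keep <- qx$pivot[seq_len(qx$rank)]
    drop <- setdiff(seq_len(p), keep)
    abort(paste0(
      "design matrix is rank deficient; collinear column(s): ",
      paste(colnames(x)[drop] %||% drop, collapse = ", ")
    ))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(x %*% beta)
  res <- y - fitted
  df_resid <- n - p
  sigma2 <- sum(res^2) / df_resid
  xtx_inv <- chol2inv(chol(crossprod(x)))
  dimnames(xtx_inv) <- list(colnames(x), colnames(x))
  tss <- sum((y - mean(y))^2)
  structure(
    list(
      coefficients = setNames(as.numeric(beta), colnames(x)),
      vcov = sigma2 * xtx_inv,
      sigma2 = sigma2,
      df_resid = df_resid,
      n = n,
      fitted = fitted,
      residuals = as.numeric(res),
      r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_
    ),
    class = "aa_fit"
  )
}

#' @export
print.aa_fit <- function(x, ...) {
  cat(sprintf("<aa_fit%s: n = %d, p = %d, sigma = %.4g, R^2 = %.4f>\n",
              if (!is.null(x$outcome_label)) paste0(" ", x$outcome_label) else "",
              x$n, length(x$coefficients), sqrt(x$sigma2), x$r_squared))
  invisible(x)
}

# Build the model pieces shared by all pivot orderings: clr matrix of the
# composition, covariate design block, and (transformed) outcome vector.
.model_frame <- function(data, spec) {
  data <- tibble::as_tibble(data)
  comp_cols <- spec$composition_cols %||% .aa_find_columns(data)
  if (length(intersect(comp_cols, spec$covariates))) {
    abort("covariates must be distinct from composition columns")
  }
  comp <- close_composition(as.matrix(data[comp_cols]))
  clr <- clr_transform(comp)
  miss <- spec$covariates[!spec$covariates %in% names(data)]
  if (length(miss)) {
    abort(paste0("covariate column(s) not in data: ", paste(miss, collapse = ", ")))
  }
  covdf <- as.data.frame(data[spec$covariates])
  if (anyNA(covdf)) abort("covariates contain missing values; filter the cohort first")
  covmat <- if (length(spec$covariates)) {
    mm <- stats::model.matrix(~ ., covdf)
    mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
  } else {
    matrix(numeric(0), nrow(data), 0)
  }
  ycol <- data[[spec$outcome]]
  if (is.null(ycol)) abort(paste0("outcome column `", spec$outcome, "` not in data"))
  y <- if (spec$log_transform) log(ycol) else ycol
  list(comp_cols = comp_cols, comp = comp, clr = clr, covmat = covmat, y = y)
}

.fit_with_first <- function(mf, spec, first) {
  comp_cols <- mf$comp_cols
  order <- c(first, setdiff(comp_cols, first))
  basis <- pivot_basis(order, components = comp_cols,
                       sign_convention = spec$sign_convention)
  z <- mf$clr %*% t(basis)
  x <- cbind(`(Intercept)` = 1, z, mf$covmat)
  fit <- fit_linear(x, mf$y)
  fit$outcome <- spec$outcome
  fit$outcome_label <- spec$outcome_label
  fit$log_transform <- spec$log_transform
  fit$basis <- basis
  fit$composition_cols <- comp_cols
  fit$ilr_terms <- rownames(basis)
  fit$spec <- spec
  fit$reference <- close_composition(
    setNames(exp(colMeans(log(mf$comp))), comp_cols)
  )
  fit
}

#' Fit one composition-outcome model
#'
#' Fits the multivariate linear model of the (possibly log-transformed)
#' outcome on the D-1 pivot ilr coordinates of the amino-acid composition
#' plus covariates. Fitted values, residuals and residual variance do not
#' depend on which component is pivoted first; only the coordinate system
#' (and hence individual coefficients) does.
#'
#' @param data Cohort table (analyzed rows: complete, strictly positive
#'   shares).
#' @param spec A [model_spec()].
#' @param first Component to place first in the pivot ordering (default:
#'   the first composition column).
#' @return An `aa_fit` carrying the basis, composition columns, and the
#'   cohort's geometric-mean reference composition.
#' @export
fit_composition_model <- function(data, spec = model_spec(), first = NULL) {
  mf <- .model_frame(data, spec)
  .fit_with_first(mf, spec, first %||% mf$comp_cols[1])
}

#' First-pivot coefficients for every component ordering
#'
#' Repeats the regression D times, each time rotating a different component
#' into the first pivot position, and reports that component's
#' first-coordinate coefficient, its classical standard error and the
#' two-sided t-test p-value on the residual degrees of freedom. Under the
#' reversed sign convention a positive coefficient means a *lower* outcome
#' when the component's share rises at the expense of the geometric mean of
#' the rest.
#'
#' The D coefficients are a rescaled clr projection of a single fit, so
#' they sum to zero by construction.
#'
#' @inheritParams fit_composition_model
#' @param keep_fits Keep the D individual `aa_fit` objects as an attribute
#'   (`"fits"`)? Default `FALSE`.
#' @return A tibble of class `aa_pivot_table` with one row per component:
#'   `component`, `outcome`, `estimate`, `std_error`, `statistic`, `df`,
#'   `p_value`, in canonical component order.
#' @export
pivot_sweep <- function(data, spec = model_spec(), keep_fits = FALSE) {
  mf <- .model_frame(data, spec)
  fits <- lapply(mf$comp_cols, function(cc) .fit_with_first(mf, spec, cc))
  rows <- purrr::map2_dfr(fits, mf$comp_cols, function(fit, cc) {
    est <- fit$coefficients[["ilr1"]]
    se <- sqrt(fit$vcov["ilr1", "ilr1"])
    tstat <- est / se
    tibble::tibble(
      component = cc,
      outcome = spec$outcome_label,
      estimate = est,
      std_error = se,
      statistic = tstat,
      df = fit$df_resid,
      p_value = 2 * pt(-abs(tstat), fit$df_resid)
    )
  })
  out <- structure(rows, class = c("aa_pivot_table", class(rows)))
  attr(out, "sign_convention") <- spec$sign_convention
  if (keep_fits) attr(out, "fits") <- setNames(fits, mf$comp_cols)
  out
}

#' Screen candidate nutrient covariates by simple regression
#'
#' Each candidate is regressed alone (simple linear regression) against
#' fasting glucose and against log insulin; it is selected when either
#' slope is significant at `alpha`. Selected candidates are meant to be
#' added to the fixed adjustment set of [default_covariates()].
#'
#' @param data Cohort table with `glucose`, `insulin` and the candidate
#'   columns.
#' @param candidates Candidate column names; default: energy, protein,
#'   saturated fat, total dietary fiber, glycemic load.
#' @param alpha Significance threshold, default 0.05.
#' @return A tibble with `candidate`, `p_glucose`, `p_log_insulin`,
#'   `selected`.
#' @export
covariate_screen <- function(data,
                             candidates = c("energy_kcal", "protein_pctE",
                                            "satfat_pctE", "fiber_g1000",
                                            "glycemic_load"),
                             alpha = 0.05) {
  data <- tibble::as_tibble(data)
  slope_p <- function(y, x) {
    f <- lm(y ~ x)
    stats::coef(summary(f))["x", "Pr(>|t|)"]
  }
  purrr::map_dfr(candidates, function(cand) {
    x <- data[[cand]]
    if (is.null(x)) abort(paste0("candidate column `", cand, "` not in data"))
    pg <- slope_p(data$glucose, x)
    pi <- slope_p(log(data$insulin), x)
    tibble::tibble(candidate = cand, p_glucose = pg, p_log_insulin = pi,
                   selected = pg < alpha | pi < alpha)
  })
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on all the others (with intercept). Perfectly collinear columns are
#' reported as `Inf`.
#'
#' @param x Numeric matrix or data frame of predictors (no intercept
#'   column).
#' @return A tibble with `term`, `r_squared`, `vif`.
#' @export
vif_values <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  purrr::map_dfr(seq_len(ncol(x)), function(j) {
    # a perfect fit here is the collinearity we are probing for, not a
    # modelling problem; silence lm's perfect-fit warning
    f <- lm(x[, j] ~ x[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(f)$r.squared)
    tibble::tibble(
      term = colnames(x)[j],
      r_squared = r2,
      vif = if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
    )
  })
}

#' Amalgamate amino-acid shares into side-chain groups
#'
#' Sums the share columns of each group (amalgamation) and re-closes the
#' resulting parts to 100, yielding a coarser composition (4 parts under
#' the default grouping).
#'
#' @param data Cohort table with amino-acid share columns.
#' @param grouping Named list of component vectors forming a partition of
#'   the composition columns; default [aa_groups()].
#' @param cols Composition columns; `NULL` auto-detects.
#' @return `data` as a tibble with the original share columns replaced by
#'   one column per group.
#' @export
amalgamate_composition <- function(data, grouping = aa_groups(), cols = NULL) {
  data <- tibble::as_tibble(data)
  cols <- .aa_find_columns(data, cols)
  key <- .aa_normalize(cols)
  members <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, key)) {
    abort("`grouping` must partition the composition columns exactly")
  }
  comp <- as.matrix(data[cols])
  colnames(comp) <- key
  groups <- vapply(grouping, function(g) rowSums(comp[, g, drop = FALSE]),
                   numeric(nrow(comp)))
  if (nrow(comp) == 1L) groups <- matrix(groups, nrow = 1,
                                         dimnames = list(NULL, names(grouping)))
  groups <- close_composition(groups)
  dplyr::bind_cols(
    data[setdiff(names(data), cols)],
    tibble::as_tibble(groups)
  )
}

#' Pivot sweep over amalgamated amino-acid groups
#'
#' Convenience wrapper: amalgamates the composition per `grouping`, then
#' runs [pivot_sweep()] on the grouped parts.
#'
#' @inheritParams amalgamate_composition
#' @param spec A [model_spec()]; its `composition_cols` are replaced by the
#'   group names.
#' @param keep_fits Passed to [pivot_sweep()].
#' @return An `aa_pivot_table` with one row per group.
#' @export
grouped_pivot_sweep <- function(data, spec = model_spec(),
                                grouping = aa_groups(), keep_fits = FALSE) {
  gdata <- amalgamate_composition(data, grouping,
                                  cols = spec$composition_cols)
  gspec <- spec
  gspec$composition_cols <- names(grouping)
  pivot_sweep(gdata, gspec, keep_fits = keep_fits)
}
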