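# End-to-end orchestration: simulate or load a cohort, filter, derive
# markers, screen covariates, fit the four outcome models over all pivot
# orderings, compute substitution effects, and report.

#' Geometric mean with a 95% confidence interval
#'
#' Computed as the exponential of the t-based confidence interval of the
#' mean of the natural logs.
#'
#' @param x Positive numeric vector.
#' @param conf_level Confidence level, default 0.95.
#' @return Named numeric vector `c(gm, ci_low, ci_high)`.
#' @export
geometric_mean_ci <- function(x, conf_level = 0.95) {
  .check_marker_positive(x, "x")
  lx <- log(x)
  n <- length(lx)
  se <- sd(lx) / sqrt(n)
  tq <- qt(1 - (1 - conf_level) / 2, n - 1)
  m <- mean(lx)
  c(gm = exp(m), ci_low = exp(m - tq * se), ci_high = exp(m + tq * se))
}

#' Descriptive statistics of an analyzed cohort
#'
#' Arithmetic mean and SD for approximately symmetric variables; geometric
#' mean with a 95% CI for the right-skewed outcomes (insulin and the HOMA
#' indices); counts and percentages for categorical variables.
#'
#' @param data Analyzed cohort tibble.
#' @return A tibble with columns `variable`, `statistic`
#'   (`"mean_sd"`, `"geometric_mean_ci"` or `"count_percent"`), `center`,
#'   `low`, `high` (SD stored in both `low` and `high` for `mean_sd` rows;
#'   percent in `low`/`high` for counts).
#' @export
descriptive_table <- function(data) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  num_vars <- c("age_months", "bmi", "zbmi", "sleep_h", "screen_h",
                "energy_kcal", "protein_pctE", "fiber_g1000", "satfat_pctE",
                "glycemic_load", "glucose")
  skew_vars <- c("insulin", "homa_ir", "homa_beta")
  rows <- list()
  if ("sex" %in% names(data)) {
    for (lev in levels(factor(data$sex))) {
      cnt <- sum(data$sex == lev)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = paste0("sex_", lev), statistic = "count_percent",
        center = cnt, low = 100 * cnt / n, high = 100 * cnt / n
      )
    }
  }
  for (v in intersect(num_vars, names(data))) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, statistic = "mean_sd",
      center = mean(data[[v]]), low = sd(data[[v]]), high = sd(data[[v]])
    )
  }
  for (v in intersect(skew_vars, names(data))) {
    ci <- geometric_mean_ci(data[[v]])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, statistic = "geometric_mean_ci",
      center = ci[["gm"]], low = ci[["ci_low"]], high = ci[["ci_high"]]
    )
  }
  for (v in intersect(c("physical_activity", "single_parent",
                        "passive_smoking"), names(data))) {
    cnt <- sum(data[[v]] == 1)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, statistic = "count_percent",
      center = cnt, low = 100 * cnt / n, high = 100 * cnt / n
    )
  }
  if ("siblings" %in% names(data)) {
    for (lev in levels(factor(data$siblings))) {
      cnt <- sum(data$siblings == lev)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = paste0("siblings_", lev), statistic = "count_percent",
        center = cnt, low = 100 * cnt / n, high = 100 * cnt / n
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Composition summary table
#'
#' Per-component geometric mean, arithmetic mean and SD of the amino-acid
#' shares in an analyzed cohort.
#'
#' @param data Analyzed cohort tibble.
#' @param cols Composition columns; `NULL` auto-detects.
#' @return A tibble with `component`, `geometric_mean`, `arithmetic_mean`,
#'   `sd`, `cv`.
#' @export
composition_table <- function(data, cols = NULL) {
  data <- tibble::as_tibble(data)
  cols <- .aa_find_columns(data, cols)
  comp <- as.matrix(data[cols])
  tibble::tibble(
    component = cols,
    geometric_mean = unname(exp(colMeans(log(comp)))),
    arithmetic_mean = unname(colMeans(comp)),
    sd = unname(apply(comp, 2, sd)),
    cv = unname(apply(comp, 2, sd) / colMeans(comp))
  )
}

#' Configure an end-to-end analysis run
#'
#' Exactly one of `cohort` (an existing participant table) or `generator`
#' (a [generator_config()] for a synthetic cohort) must be supplied.
#'
#' @param cohort Optional cohort tibble (the serum-available roster, one
#'   row per participant).
#' @param generator Optional [generator_config()].
#' @param eer EER table used by the energy-plausibility filter.
#' @param delta Replacement size for the substitution analyses, percentage
#'   points of total amino acids (default 0.1).
#' @param outcomes Outcomes to model.
#' @param sign_convention Pivot sign convention for all models.
#' @param out_dir Optional output directory; when given, all tables are
#'   written as CSV alongside a machine-readable JSON and a run log.
#' @param required_items Columns whose missingness triggers the
#'   missing-items exclusion; default: fiber (a mandatory questionnaire
#'   item in the canonical schema).
#' @return A list of class `aa_run_config`.
#' @export
pipeline_config <- function(cohort = NULL, generator = NULL,
                            eer = synthetic_eer_table(),
                            delta = 0.1,
                            outcomes = c("glucose", "insulin", "homa_ir",
                                         "homa_beta"),
                            sign_convention = c("reversed", "standard"),
                            out_dir = NULL,
                            required_items = "fiber_g1000") {
  if (is.null(cohort) == is.null(generator)) {
    abort("supply exactly one of `cohort` or `generator`")
  }
  structure(
    list(cohort = cohort, generator = generator, eer = eer, delta = delta,
         outcomes = outcomes,
         sign_convention = match.arg(sign_convention),
         out_dir = out_dir, required_items = required_items),
    class = "aa_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain a `generator:` mapping (scalar fields of
#' [generator_config()]: `n`, `seed`, `confound_protein_bcaa`) or a
#' `cohort_csv:` path to an existing cohort table, plus the scalar
#' [pipeline_config()] fields `delta`, `sign_convention`, `out_dir`,
#' `outcomes`, and optional `eer_csv` / table paths.
#'
#' @param path Path to a YAML file.
#' @return An `aa_run_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  generator <- NULL
  if (!is.null(obj$generator)) {
    gen <- obj$generator
    # YAML 1.1 reads a bare `n` key as the boolean FALSE; map it back
    names(gen)[names(gen) %in% c("FALSE", "no")] <- "n"
    keep <- intersect(names(gen), names(formals(generator_config)))
    generator <- do.call(generator_config, gen[keep])
  }
  cohort <- NULL
  if (!is.null(obj$cohort_csv)) {
    cohort <- readr::read_csv(obj$cohort_csv, show_col_types = FALSE)
  }
  eer <- if (!is.null(obj$eer_csv)) read_eer_table(obj$eer_csv)
         else synthetic_eer_table()
  pipeline_config(
    cohort = cohort, generator = generator, eer = eer,
    delta = obj$delta %||% 0.1,
    outcomes = obj$outcomes %||% c("glucose", "insulin", "homa_ir",
                                   "homa_beta"),
    sign_convention = obj$sign_convention %||% "reversed",
    out_dir = obj$out_dir
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or take) a cohort, apply the exclusion chain, derive glycemic
#' markers, screen the candidate nutrient covariates, fit every outcome on
#' the pivot ilr coordinates across all component orderings, and compute
#' one-to-all and one-to-one substitution effects at the geometric-mean
#' reference, plus the grouped 4-part analysis and VIF diagnostics.
#'
#' @param config An [pipeline_config()].
#' @return A list of class `aa_report`: `flow`, `descriptives`,
#'   `composition`, `screen`, `covariates_used`, `pivot` (one
#'   `aa_pivot_table` per outcome), `grouped` (per outcome),
#'   `reference`, `one_to_all` and `one_to_one` (per outcome), `vif`,
#'   `meta`. With `out_dir` set, each table is also written as CSV, the
#'   whole bundle as JSON, and a run log recording the seed, package
#'   version and pivot orderings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "aa_run_config"))
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  seed <- if (!is.null(config$generator)) config$generator$seed else NA_integer_
  say("aacoda %s | seed: %s", as.character(utils::packageVersion("aacoda")),
      seed)
  cohort <- if (!is.null(config$cohort)) {
    tibble::as_tibble(config$cohort)
  } else {
    generate_cohort(config$generator)
  }
  say("stage filter: %d rows entering the exclusion chain", nrow(cohort))
  excl <- apply_exclusions(cohort, eer = config$eer,
                           required_items = config$required_items)
  analyzed <- excl$analyzed
  say("stage filter: %d analyzed", nrow(analyzed))
  if (!all(c("homa_ir", "homa_beta") %in% names(analyzed))) {
    analyzed <- add_glycemic_markers(analyzed)
  }
  screen <- covariate_screen(analyzed)
  covs <- union(default_covariates(), screen$candidate[screen$selected])
  say("stage screen: covariates used: %s", paste(covs, collapse = ", "))
  comp_cols <- .aa_find_columns(analyzed)
  specs <- lapply(config$outcomes, function(oc) {
    model_spec(oc, covariates = covs, composition_cols = comp_cols,
               sign_convention = config$sign_convention)
  })
  names(specs) <- config$outcomes
  say("stage fit: pivot orderings rotate each of %d components first (%s)",
      length(comp_cols), paste(comp_cols, collapse = " "))
  pivot <- lapply(specs, function(sp) pivot_sweep(analyzed, sp))
  grouped <- lapply(specs, function(sp) grouped_pivot_sweep(analyzed, sp))
  fits <- lapply(specs, function(sp) fit_composition_model(analyzed, sp))
  ref <- fits[[1]]$reference
  one_all <- lapply(fits, one_to_all_table, delta = config$delta)
  one_one <- lapply(fits, one_to_one_matrix, delta = config$delta)
  x_glu <- cbind(
    ilr_transform(as.matrix(analyzed[comp_cols]), fits[[1]]$basis),
    stats::model.matrix(~ ., as.data.frame(analyzed[covs]))[, -1]
  )
  vif_tbl <- vif_values(x_glu)
  say("stage diagnostics: max VIF %.3f (%s)",
      max(vif_tbl$vif), vif_tbl$term[which.max(vif_tbl$vif)])
  out <- structure(
    list(
      flow = excl$flow,
      descriptives = descriptive_table(analyzed),
      composition = composition_table(analyzed),
      screen = screen,
      covariates_used = covs,
      pivot = pivot,
      grouped = grouped,
      reference = ref,
      one_to_all = one_all,
      one_to_one = one_one,
      vif = vif_tbl,
      meta = list(seed = seed, delta = config$delta,
                  sign_convention = config$sign_convention,
                  n_analyzed = nrow(analyzed),
                  version = as.character(utils::packageVersion("aacoda")))
    ),
    class = "aa_report"
  )
  if (!is.null(config$out_dir)) {
    .write_report(out, config$out_dir, log_lines)
  }
  out
}

.write_report <- function(report, out_dir, log_lines) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    readr::write_csv(tibble::as_tibble(x), file.path(out_dir, paste0(name, ".csv")))
  }
  wr(flow_table(report$flow), "flow")
  wr(report$descriptives, "descriptives")
  wr(report$composition, "composition")
  wr(report$screen, "covariate_screen")
  wr(dplyr::bind_rows(report$pivot), "pivot_coefficients")
  wr(dplyr::bind_rows(report$grouped), "grouped_coefficients")
  wr(tibble::tibble(component = names(report$reference),
                    share = as.numeric(report$reference)),
     "reference_composition")
  wr(dplyr::bind_rows(report$one_to_all), "one_to_all_effects")
  wr(dplyr::bind_rows(report$one_to_one), "one_to_one_effects")
  wr(report$vif, "vif")
  js <- report_to_json(report)
  writeLines(js, file.path(out_dir, "report.json"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Serialize a pipeline report to JSON
#'
#' Every number appearing in the report's tables is present in the JSON;
#' the serialisation is deterministic given the report.
#'
#' @param report An `aa_report` from [run_pipeline()].
#' @return A JSON string.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "aa_report"))
  obj <- list(
    flow = list(enrolled = report$flow$enrolled,
                excluded = as.list(report$flow$excluded),
                analyzed = report$flow$analyzed),
    descriptives = report$descriptives,
    composition = report$composition,
    covariate_screen = report$screen,
    covariates_used = report$covariates_used,
    pivot = lapply(report$pivot, tibble::as_tibble),
    grouped = lapply(report$grouped, tibble::as_tibble),
    reference = as.list(report$reference),
    one_to_all = lapply(report$one_to_all, tibble::as_tibble),
    one_to_one = lapply(report$one_to_one, tibble::as_tibble),
    vif = report$vif,
    meta = report$meta
  )
  as.character(jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE,
                                digits = NA, na = "null", pretty = TRUE))
}

#' @export
print.aa_report <- function(x, ...) {
  cat("== aacoda analysis report ==\n")
  print(x$flow)
  cat(sprintf("outcomes: %s | delta = %g | sign convention: %s\n",
              paste(names(x$pivot), collapse = ", "),
              x$meta$delta, x$meta$sign_convention))
  sig <- dplyr::bind_rows(x$pivot)
  sig <- sig[sig$p_value < 0.05, c("outcome", "component", "estimate",
                                   "std_error", "p_value")]
  if (nrow(sig)) {
    cat("significant first-pivot coefficients (p < 0.05):\n")
    print(as.data.frame(sig), row.names = FALSE)
  } else {
    cat("no significant first-pivot coefficients at 0.05\n")
  }
  invisible(x)
}
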