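# Participant-flow exclusion chain: questionnaire completeness, dietary
# energy plausibility against estimated energy requirements (EER), missing
# items, and physician-diagnosed disease.

#' Energy-intake plausibility against estimated energy requirements
#'
#' An energy intake is plausible when it lies between half of the sex- and
#' age-specific estimated energy requirement at a low physical activity
#' level and 1.5 times the requirement at a high activity level. Both
#' boundaries are inclusive ("between" is read as a closed interval — the
#' weaker filter).
#'
#' @param energy_kcal Reported energy intake, kcal/day.
#' @param sex Sex codes matching the `sex` column of `eer`.
#' @param age_years Age in years, matched against `[age_min, age_max]`.
#' @param eer EER table with columns `sex`, `age_min`, `age_max`,
#'   `eer_low_pal`, `eer_high_pal` (kcal/day at low / high physical
#'   activity). See [synthetic_eer_table()] for a testing table.
#' @return Logical vector: `TRUE` when plausible. `NA` energy gives `NA`.
#' @export
#' @examples
#' eer <- tibble::tibble(sex = "male", age_min = 12, age_max = 14,
#'                       eer_low_pal = 2000, eer_high_pal = 2600)
#' energy_plausible(c(1000, 999.9, 3900, 3900.1), "male", 13, eer)
energy_plausible <- function(energy_kcal, sex, age_years, eer) {
  need <- c("sex", "age_min", "age_max", "eer_low_pal", "eer_high_pal")
  if (!all(need %in% names(eer))) {
    abort(paste0("EER table must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(eer$eer_low_pal <= 0) || any(eer$eer_high_pal < eer$eer_low_pal)) {
    abort("EER table needs 0 < eer_low_pal <= eer_high_pal")
  }
  n <- max(length(energy_kcal), length(sex), length(age_years))
  energy_kcal <- rep_len(energy_kcal, n)
  sex <- rep_len(sex, n)
  age_years <- rep_len(age_years, n)
  out <- logical(n)
  for (i in seq_len(n)) {
    row <- eer[eer$sex == sex[i] &
               eer$age_min <= age_years[i] & age_years[i] <= eer$age_max, ,
               drop = FALSE]
    if (nrow(row) == 0L) {
      abort(paste0("no EER row for sex `", sex[i], "`, age ", age_years[i]))
    }
    out[i] <- if (is.na(energy_kcal[i])) NA else
      0.5 * row$eer_low_pal[1] <= energy_kcal[i] &&
      energy_kcal[i] <= 1.5 * row$eer_high_pal[1]
  }
  out
}

#' Apply the participant exclusion chain
#'
#' Removes participants flagged for (in attribution order) an unanswered
#' questionnaire, implausible energy intake, missing questionnaire items, or
#' physician-diagnosed disease (any of diabetes, dyslipidemia, hypertension,
#' heart disease, kidney disease). A participant carrying several flags is
#' counted once, under the first flag in `attribution_order`; permuting the
#' order changes per-reason counts but never the analyzed set.
#'
#' @param cohort Cohort table. Logical flag columns `missing_questionnaire`,
#'   `implausible_energy`, `missing_items`, `disease` are used when present
#'   (missing columns are treated as all-`FALSE`).
#' @param eer Optional EER table; when supplied, `implausible_energy` is
#'   recomputed from `energy_kcal`, `sex`, and `age_months` via
#'   [energy_plausible()] (`NA` energy does not trigger the energy flag).
#' @param required_items Optional character vector of columns whose
#'   missingness defines the `missing_items` flag (recomputed when given).
#' @param attribution_order Permutation of the four reason names giving the
#'   first-hit attribution order.
#' @return A list of class `aa_exclusion` with elements `analyzed` (tibble
#'   of rows passing all filters) and `flow` (an `aa_flow` report; see
#'   [flow_table()]).
#' @export
apply_exclusions <- function(cohort, eer = NULL, required_items = NULL,
                             attribution_order = c("missing_questionnaire",
                                                   "implausible_energy",
                                                   "missing_items",
                                                   "disease")) {
  reasons <- c("missing_questionnaire", "implausible_energy",
               "missing_items", "disease")
  if (!setequal(attribution_order, reasons)) {
    abort("`attribution_order` must be a permutation of the four exclusion reasons")
  }
  cohort <- tibble::as_tibble(cohort)
  n <- nrow(cohort)
  flag <- function(name) {
    f <- cohort[[name]] %||% rep(FALSE, n)
    f & !is.na(f)
  }
  flags <- list(
    missing_questionnaire = flag("missing_questionnaire"),
    implausible_energy = flag("implausible_energy"),
    missing_items = flag("missing_items"),
    disease = flag("disease")
  )
  if (!is.null(eer)) {
    pl <- energy_plausible(cohort$energy_kcal, cohort$sex,
                           cohort$age_months / 12, eer)
    flags$implausible_energy <- !is.na(pl) & !pl
  }
  if (!is.null(required_items)) {
    miss <- Reduce(`|`, lapply(required_items, function(cl) is.na(cohort[[cl]])))
    flags$missing_items <- miss
  }
  any_flag <- Reduce(`|`, flags)
  taken <- rep(FALSE, n)
  counts <- integer(length(reasons))
  names(counts) <- attribution_order
  for (r in attribution_order) {
    hit <- flags[[r]] & !taken
    counts[r] <- sum(hit)
    taken <- taken | hit
  }
  flow <- structure(
    list(enrolled = n,
         excluded = counts[reasons],
         attribution_order = attribution_order,
         analyzed = n - sum(counts)),
    class = "aa_flow"
  )
  structure(
    list(analyzed = cohort[!any_flag, , drop = FALSE], flow = flow),
    class = "aa_exclusion"
  )
}

#' Participant-flow report as a tibble
#'
#' @param flow An `aa_flow` object from [apply_exclusions()].
#' @return A tibble with columns `stage` and `n`: the enrolled count, each
#'   exclusion reason (negative contribution), and the analyzed count.
#' @export
flow_table <- function(flow) {
  stopifnot(inherits(flow, "aa_flow"))
  tibble::tibble(
    stage = c("enrolled", names(flow$excluded), "analyzed"),
    n = c(flow$enrolled, -as.integer(flow$excluded), flow$analyzed)
  )
}

#' @export
print.aa_flow <- function(x, ...) {
  cat("Participant flow\n")
  cat(sprintf("  %-28s %6d\n", "entering filter", x$enrolled))
  for (r in names(x$excluded)) {
    cat(sprintf("  - excluded: %-16s %6d\n", r, x$excluded[[r]]))
  }
  cat(sprintf("  %-28s %6d\n", "analyzed", x$analyzed))
  invisible(x)
}

#' @export
print.aa_exclusion <- function(x, ...) {
  print(x$flow)
  cat(sprintf("analyzed table: %d rows x %d cols\n",
              nrow(x$analyzed), ncol(x$analyzed)))
  invisible(x)
}

#' Serialize a flow report to JSON
#'
#' @param flow An `aa_flow` object.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
flow_to_json <- function(flow, path = NULL) {
  stopifnot(inherits(flow, "aa_flow"))
  obj <- list(enrolled = flow$enrolled,
              excluded = as.list(flow$excluded),
              analyzed = flow$analyzed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Synthetic estimated-energy-requirement table for testing
#'
#' Sex-specific EER values (kcal/day) for early adolescence at low and high
#' physical activity levels, in the range of national dietary reference
#' intakes. Synthetic convenience table for tests and the default cohort
#' generator; supply a real reference via [read_eer_table()] for
#' substantive work.
#'
#' @return A tibble with columns `sex`, `age_min`, `age_max`,
#'   `eer_low_pal`, `eer_high_pal`.
#' @export
synthetic_eer_table <- function() {
  tibble::tibble(
    sex = c("male", "female"),
    age_min = c(10, 10),
    age_max = c(17, 17),
    eer_low_pal = c(2300, 2100),
    eer_high_pal = c(3100, 2800)
  )
}

#' Read an EER table from CSV
#'
#' @param path Path to a CSV with columns `sex`, `age_min`, `age_max`,
#'   `eer_low_pal`, `eer_high_pal`.
#' @return A validated tibble.
#' @export
read_eer_table <- function(path) {
  eer <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sex", "age_min", "age_max", "eer_low_pal", "eer_high_pal")
  if (!all(need %in% names(eer))) {
    abort(paste0("EER table must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(eer$eer_low_pal <= 0) || any(eer$eer_high_pal < eer$eer_low_pal)) {
    abort("EER table needs 0 < eer_low_pal <= eer_high_pal")
  }
  eer
}
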