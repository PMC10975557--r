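# Derived glycemic and anthropometric variables: unit conversion, HOMA
# indices, BMI and LMS-standardised BMI z-scores.

#' Convert fasting glucose from mg/dL to mmol/L
#'
#' @param glucose_mgdl Fasting plasma glucose in mg/dL; strictly positive.
#' @return Glucose in mmol/L (`glucose_mgdl * 0.05551`).
#' @export
#' @examples
#' glucose_to_mmol(90.6)
glucose_to_mmol <- function(glucose_mgdl) {
  .check_marker_positive(glucose_mgdl, "glucose_mgdl")
  glucose_mgdl * 0.05551
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = insulin (uU/mL) x glucose (mmol/L) / 22.5`, with glucose
#' converted from mg/dL internally.
#'
#' @param glucose_mgdl Fasting plasma glucose, mg/dL.
#' @param insulin_uUmL Fasting serum insulin, uU/mL.
#' @return Unitless HOMA-IR index.
#' @export
#' @examples
#' homa_ir(90.6, 6.19)
homa_ir <- function(glucose_mgdl, insulin_uUmL) {
  .check_marker_positive(insulin_uUmL, "insulin_uUmL")
  insulin_uUmL * glucose_to_mmol(glucose_mgdl) / 22.5
}

#' Homeostatic model assessment of beta-cell function (HOMA-beta)
#'
#' `HOMA-beta = 20 x insulin (uU/mL) / (glucose [mmol/L] - 3.5)`, in percent.
#' The index is undefined at or below the 3.5 mmol/L pole (hypoglycemic
#' range); such inputs raise an error rather than being clipped.
#'
#' @inheritParams homa_ir
#' @return HOMA-beta in percent.
#' @export
#' @examples
#' homa_beta(90.6, 6.19)
homa_beta <- function(glucose_mgdl, insulin_uUmL) {
  .check_marker_positive(insulin_uUmL, "insulin_uUmL")
  denom <- glucose_to_mmol(glucose_mgdl) - 3.5
  if (any(denom <= 0)) {
    abort(paste0(
      "HOMA-beta undefined: glucose at or below the 3.5 mmol/L pole for ",
      sum(denom <= 0), " value(s) (hypoglycemic-range input)"
    ))
  }
  20 * insulin_uUmL / denom
}

#' Body mass index
#'
#' `BMI = weight [kg] / height [cm]^2 x 10000`.
#'
#' @param weight_kg Body weight, kg.
#' @param height_cm Standing height, cm.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(50, 160)
bmi <- function(weight_kg, height_cm) {
  .check_marker_positive(weight_kg, "weight_kg")
  .check_marker_positive(height_cm, "height_cm")
  weight_kg / height_cm^2 * 10000
}

.check_marker_positive <- function(x, label) {
  if (any(!is.finite(x) | x <= 0)) {
    abort(paste0("`", label, "` must be strictly positive and finite"))
  }
  invisible(x)
}

#' Sex- and age-standardised BMI z-score (LMS method)
#'
#' Standardises BMI against an external Lambda-Mu-Sigma (LMS) growth
#' reference:
#' \deqn{z = \frac{(\mathrm{BMI}/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
#'       z = \frac{\ln(\mathrm{BMI}/M)}{S} \quad (L = 0).}
#' The reference row is the nearest `age_months` for the participant's sex
#' within `window` months; no extrapolation beyond the window is performed.
#'
#' @param bmi BMI values, kg/m^2.
#' @param sex Sex codes matching the `sex` column of `ref`.
#' @param age_months Age in months.
#' @param ref LMS reference table with columns `sex`, `age_months`, `L`,
#'   `M`, `S` (see [read_lms_reference()]; a synthetic table for testing is
#'   available from [synthetic_lms_reference()]).
#' @param window Maximum age distance (months) for reference lookup,
#'   default 6.
#' @return Numeric vector of BMI z-scores.
#' @export
#' @examples
#' ref <- synthetic_lms_reference()
#' zbmi(19.2, "male", 163, ref)
zbmi <- function(bmi, sex, age_months, ref, window = 6) {
  stopifnot(all(c("sex", "age_months", "L", "M", "S") %in% names(ref)))
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    abort("LMS reference must have M > 0 and S > 0")
  }
  n <- max(length(bmi), length(sex), length(age_months))
  bmi <- rep_len(bmi, n)
  sex <- rep_len(sex, n)
  age_months <- rep_len(age_months, n)
  .check_marker_positive(bmi, "bmi")
  out <- numeric(n)
  for (i in seq_len(n)) {
    rows <- ref[ref$sex == sex[i], , drop = FALSE]
    if (nrow(rows) == 0L) {
      abort(paste0("no LMS reference rows for sex `", sex[i], "`"))
    }
    dist <- abs(rows$age_months - age_months[i])
    j <- which.min(dist)
    if (dist[j] > window) {
      abort(paste0(
        "no LMS reference age within ", window, " months of ", age_months[i],
        " for sex `", sex[i], "`; available ages: ",
        paste(sort(unique(rows$age_months)), collapse = ", ")
      ))
    }
    l <- rows$L[j]; m <- rows$M[j]; s <- rows$S[j]
    # expm1 keeps the L -> 0 limit numerically continuous
    out[i] <- if (abs(l) < 1e-12) log(bmi[i] / m) / s
              else expm1(l * log(bmi[i] / m)) / (l * s)
  }
  out
}

#' Append derived glycemic markers to a cohort table
#'
#' Adds `glucose_mmol`, `homa_ir` and `homa_beta` columns computed from the
#' fasting glucose (mg/dL) and insulin (uU/mL) columns.
#'
#' @param data A data frame with the glucose and insulin columns.
#' @param glucose,insulin Column names (tidy-select style strings), defaults
#'   `"glucose"` and `"insulin"`.
#' @return `data` as a tibble with the three marker columns appended
#'   (recomputed if already present).
#' @export
#' @examples
#' add_glycemic_markers(tibble::tibble(glucose = 90.6, insulin = 6.19))
add_glycemic_markers <- function(data, glucose = "glucose", insulin = "insulin") {
  g <- data[[glucose]]
  i <- data[[insulin]]
  if (is.null(g) || is.null(i)) abort("glucose/insulin columns not found")
  dplyr::mutate(
    tibble::as_tibble(data),
    glucose_mmol = glucose_to_mmol(g),
    homa_ir = homa_ir(g, i),
    homa_beta = homa_beta(g, i)
  )
}

#' Synthetic LMS growth reference for testing
#'
#' A smooth, synthetic Lambda-Mu-Sigma reference for BMI-for-age (ages 6-18
#' years, both sexes). It is *not* a national growth standard: median BMI
#' rises linearly with age around adolescent-typical values, with constant
#' skewness (L = -1.5) and coefficient of variation (S = 0.1). Use a real
#' LMS table (via [read_lms_reference()]) for substantive work.
#'
#' @return A tibble with columns `sex` ("male"/"female"), `age_months`,
#'   `L`, `M`, `S`.
#' @export
synthetic_lms_reference <- function() {
  ages <- seq(72, 216, by = 6)
  purrr::map_dfr(c("male", "female"), function(s) {
    m0 <- if (s == "male") 15.3 else 15.1
    tibble::tibble(
      sex = s,
      age_months = ages,
      L = -1.5,
      M = m0 + (ages - 72) * (5.5 / 144),
      S = 0.1
    )
  })
}

#' Read an LMS reference table from CSV
#'
#' Expects columns `sex`, `age_months`, `L`, `M`, `S` with unique
#' (sex, age_months) keys.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_lms_reference <- function(path) {
  ref <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sex", "age_months", "L", "M", "S")
  if (!all(need %in% names(ref))) {
    abort(paste0("LMS reference must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(ref[c("sex", "age_months")])) {
    abort("LMS reference has duplicated (sex, age_months) keys")
  }
  if (any(ref$M <= 0) || any(ref$S <= 0)) abort("LMS reference needs M > 0, S > 0")
  ref
}
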