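# broom-style tidiers and ggplot2 autoplot methods for fitted objects and
# substitution-effect tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a composition-model fit
#'
#' @param x An `aa_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.aa_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  stat <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients),
    std.error = as.numeric(se),
    statistic = as.numeric(stat),
    p.value = 2 * pt(-abs(as.numeric(stat)), x$df_resid)
  )
}

#' Glance at a composition-model fit
#'
#' @param x An `aa_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `sigma`, `df.residual`,
#'   `nobs` and (when available) `outcome`.
#' @export
glance.aa_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = sqrt(x$sigma2),
    df.residual = x$df_resid,
    nobs = x$n,
    outcome = x$outcome_label %||% NA_character_
  )
}

.canonical_factor <- function(x) {
  cb <- .aa_codebook()
  lev <- unique(c(intersect(cb$abbrev, unique(x)), setdiff(unique(x), cb$abbrev)))
  factor(x, levels = lev)
}

#' Bar chart of substitution effects with confidence boxes
#'
#' One bar per component (one-to-all table) or per source component (a
#' single-target slice of a one-to-one table), with the 2-SE confidence
#' interval drawn as a box around the bar tip.
#'
#' @param object An `aa_substitution` (from [one_to_all_table()]) or
#'   `aa_effect_matrix` filtered to one target.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aa_substitution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$component <- .canonical_factor(df$target)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$effect)) +
    ggplot2::geom_col(fill = "grey55", width = 0.65) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.35, linewidth = 0.4
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = NULL,
      y = paste0("predicted difference (", unique(df$outcome), ")"),
      title = sprintf("Effect of a %g%% one-to-all replacement",
                      unique(df$delta))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Heatmap of the one-to-one substitution-effect matrix
#'
#' @param object An `aa_effect_matrix`.
#' @param ... Unused.
#' @return A ggplot object (tiles: target increased on the y axis, source
#'   decreased on the x axis).
#' @export
autoplot.aa_effect_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$target <- .canonical_factor(df$target)
  df$source <- .canonical_factor(df$source)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$target,
                                   fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(
      x = "decreased component", y = "increased component",
      fill = paste0("effect\n(", unique(df$outcome), ")"),
      title = sprintf("One-to-one %g%% replacement effects",
                      unique(df$delta))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Forest-style plot of first-pivot coefficients
#'
#' @param object An `aa_pivot_table` from [pivot_sweep()].
#' @param ... Unused.
#' @return A ggplot object showing each component's first-pivot coefficient
#'   with a 95% t-interval.
#' @export
autoplot.aa_pivot_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  tq <- qt(0.975, df$df)
  df$lo <- df$estimate - tq * df$std_error
  df$hi <- df$estimate + tq * df$std_error
  df$component <- .canonical_factor(df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$component)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi), height = 0.25
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(
      x = paste0("first-pivot coefficient (", unique(df$outcome), ")"),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
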