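# Aitchison-geometry primitives: closure, clr, pivot ilr bases, and the
# substitution perturbations used for nutrient-replacement modelling.
# Shares live on the 0-100 scale throughout; logs are natural.

#' Close a composition to a constant total
#'
#' Rescales a vector of strictly positive shares so it sums to `total`
#' (default 100, i.e. percent of total amino acids). Closure is idempotent
#' and preserves all ratios between components.
#'
#' @param x Numeric vector (optionally named) of strictly positive shares,
#'   or a numeric matrix / data frame whose rows are compositions.
#' @param total Target sum, default 100.
#' @return An object of the same shape as `x`, rescaled row-wise so every
#'   composition sums to `total`.
#' @export
#' @examples
#' close_composition(c(ILE = 1, LEU = 2, VAL = 1))
close_composition <- function(x, total = 100) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    .check_positive_rows(x)
    return(x * (total / rowSums(x)))
  }
  .check_positive(x)
  x * (total / sum(x))
}

.check_positive <- function(x) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    lab <- if (!is.null(names(x))) names(x)[bad] else as.character(bad)
    abort(paste0(
      "composition shares must be strictly positive; offending component(s): ",
      paste(lab, collapse = ", ")
    ))
  }
  invisible(x)
}

.check_positive_rows <- function(x) {
  bad <- which(!is.finite(x) | x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    lab <- if (!is.null(colnames(x))) colnames(x)[bad[, 2]] else as.character(bad[, 2])
    abort(paste0(
      "composition shares must be strictly positive; offending component(s): ",
      paste(unique(lab), collapse = ", "),
      " (first bad row: ", bad[1, 1], ")"
    ))
  }
  invisible(x)
}

#' Centred log-ratio transform
#'
#' `clr(x)_i = ln(x_i / g(x))` with `g` the geometric mean of the parts.
#' The result sums to zero and is invariant to closure (rescaling of `x`
#' by any positive constant).
#'
#' @param x Positive numeric vector, or matrix / data frame of row-wise
#'   compositions.
#' @return Numeric vector or matrix of clr coordinates (rows sum to 0).
#' @export
#' @examples
#' clr_transform(c(75, 25))
clr_transform <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    .check_positive_rows(x)
    lx <- log(x)
    return(lx - rowMeans(lx))
  }
  .check_positive(x)
  lx <- log(x)
  lx - mean(lx)
}

#' Pivot (one-vs-rest) isometric log-ratio basis
#'
#' Builds the orthonormal (D-1) x D contrast matrix of pivot coordinates for
#' a given component ordering. The first coordinate contrasts the
#' first-ordered component against the geometric mean of the remaining
#' D-1 components:
#' \deqn{z_1 = \pm\sqrt{(D-1)/D}\,\ln\!\big(x_{(1)} / g(x_{(2)},\dots,x_{(D)})\big)}
#' Under the default `"reversed"` sign convention the whole matrix is
#' negated, so a *positive* first-pivot regression coefficient corresponds
#' to a *negative* effect of increasing the first component's share.
#'
#' @param order Character vector: the pivot ordering (a permutation of the
#'   component names). The first element is the pivot component.
#' @param components Character vector giving the column order of the
#'   returned matrix (default: `order`). Use this to keep all bases aligned
#'   to one canonical column order.
#' @param sign_convention `"reversed"` (default) or `"standard"`.
#' @return A (D-1) x D numeric matrix with orthonormal, zero-sum rows;
#'   columns named by `components`, rows `ilr1` ... `ilr<D-1>`. Attributes
#'   `order` and `sign_convention` record the construction.
#' @export
#' @examples
#' pivot_basis(c("LEU", "ILE", "VAL"))
pivot_basis <- function(order, components = order,
                        sign_convention = c("reversed", "standard")) {
  sign_convention <- match.arg(sign_convention)
  if (anyDuplicated(order)) {
    abort("`order` contains duplicated component names")
  }
  if (length(order) != length(components) || !setequal(order, components)) {
    abort("`order` must be a permutation of `components`")
  }
  d <- length(order)
  if (d < 2L) abort("a composition needs at least 2 parts")
  v <- matrix(0, d - 1L, d)
  for (j in seq_len(d - 1L)) {
    nrm <- sqrt((d - j) / (d - j + 1))
    v[j, j] <- nrm
    v[j, (j + 1L):d] <- -nrm / (d - j)
  }
  if (sign_convention == "reversed") v <- -v
  b <- matrix(0, d - 1L, d, dimnames = list(paste0("ilr", seq_len(d - 1L)),
                                            components))
  b[, match(order, components)] <- v
  attr(b, "order") <- order
  attr(b, "sign_convention") <- sign_convention
  b
}

#' Isometric log-ratio coordinates
#'
#' Projects a composition onto the pivot coordinates of `basis`:
#' `ilr(x) = B clr(x)`. The Euclidean norm of the result does not depend on
#' the ordering used to build the basis (isometry).
#'
#' @param x Positive numeric vector named by component, or a matrix / data
#'   frame of row-wise compositions with named columns.
#' @param basis A basis from [pivot_basis()]; its column names select and
#'   order the components of `x`.
#' @return Numeric vector of length D-1, or an n x (D-1) matrix.
#' @export
#' @examples
#' b <- pivot_basis(c("LEU", "ILE", "VAL"))
#' ilr_transform(c(ILE = 4.56, LEU = 8.24, VAL = 5.39), b)
ilr_transform <- function(x, basis) {
  comp <- colnames(basis)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (!is.null(comp) && !is.null(colnames(x))) {
      if (!all(comp %in% colnames(x))) abort("composition columns missing from `x`")
      x <- x[, comp, drop = FALSE]
    }
    if (ncol(x) != ncol(basis)) abort("dimension mismatch between `x` and `basis`")
    return(clr_transform(x) %*% t(basis))
  }
  if (!is.null(comp) && !is.null(names(x))) {
    if (!all(comp %in% names(x))) abort("composition components missing from `x`")
    x <- x[comp]
  }
  if (length(x) != ncol(basis)) abort("dimension mismatch between `x` and `basis`")
  drop(basis %*% clr_transform(x))
}

#' Specify a substitution perturbation
#'
#' Describes the replacement of `delta` percentage points of total amino
#' acids. `one_to_all` increases `target` by `delta` and decreases each of
#' the other D-1 components by `delta/(D-1)`; `one_to_one` transfers `delta`
#' from `source` to `target`, leaving everything else untouched.
#'
#' @param kind `"one_to_all"` or `"one_to_one"`.
#' @param target Component whose share is increased.
#' @param source Component whose share is decreased (`one_to_one` only).
#' @param delta Size of the replacement in percentage points of total amino
#'   acids (default 0.1).
#' @return An object of class `aa_perturbation`.
#' @export
#' @examples
#' perturbation("one_to_one", target = "LEU", source = "ILE")
perturbation <- function(kind = c("one_to_all", "one_to_one"),
                         target, source = NULL, delta = 0.1) {
  kind <- match.arg(kind)
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0) {
    abort("`delta` must be a single non-negative number")
  }
  if (kind == "one_to_one") {
    if (is.null(source)) abort("one_to_one replacement needs a `source` component")
    if (identical(target, source)) abort("`target` and `source` must differ")
  } else if (!is.null(source)) {
    abort("`source` is only meaningful for one_to_one replacement")
  }
  structure(
    list(kind = kind, target = target, source = source, delta = delta),
    class = "aa_perturbation"
  )
}

#' @export
print.aa_perturbation <- function(x, ...) {
  if (x$kind == "one_to_all") {
    cat(sprintf("<one-to-all replacement: +%g%% %s, -%g%%/(D-1) each other>\n",
                x$delta, x$target, x$delta))
  } else {
    cat(sprintf("<one-to-one replacement: +%g%% %s from %s>\n",
                x$delta, x$target, x$source))
  }
  invisible(x)
}

#' Read / write a perturbation as JSON
#'
#' A perturbation is serialised as `{"kind", "target", "source", "delta"}`;
#' `source` is omitted for one-to-all replacements.
#'
#' @param json JSON string or path to a JSON file.
#' @param p An `aa_perturbation`.
#' @return [perturbation_from_json()] returns an `aa_perturbation`;
#'   [perturbation_to_json()] returns a JSON string.
#' @export
perturbation_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  perturbation(kind = obj$kind, target = obj$target,
               source = obj$source, delta = obj$delta %||% 0.1)
}

#' @rdname perturbation_from_json
#' @export
perturbation_to_json <- function(p) {
  stopifnot(inherits(p, "aa_perturbation"))
  obj <- p[!vapply(p, is.null, logical(1))]
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Apply a substitution perturbation to a composition
#'
#' Shifts shares additively on the percentage scale, so the total is
#' conserved exactly (no re-closure). Errors if any share would become
#' non-positive, naming the offending component.
#'
#' @param ref Named positive numeric vector summing to the closure total;
#'   typically the geometric-mean reference from [reference_composition()].
#' @param p An [perturbation()] object.
#' @return The perturbed composition, same names and total as `ref`.
#' @export
#' @examples
#' ref <- close_composition(setNames(aa_reference()$geometric_mean,
#'                                   aa_reference()$abbrev))
#' apply_perturbation(ref, perturbation("one_to_all", "LEU"))["LEU"]
apply_perturbation <- function(ref, p) {
  stopifnot(inherits(p, "aa_perturbation"))
  .check_positive(ref)
  if (is.null(names(ref))) abort("`ref` must be a named composition vector")
  target <- .match_component(p$target, names(ref))
  out <- ref
  if (p$kind == "one_to_all") {
    others <- setdiff(names(ref), target)
    out[target] <- out[target] + p$delta
    out[others] <- out[others] - p$delta / (length(ref) - 1L)
  } else {
    source <- .match_component(p$source, names(ref))
    out[target] <- out[target] + p$delta
    out[source] <- out[source] - p$delta
  }
  neg <- names(out)[out <= 0]
  if (length(neg)) {
    abort(paste0(
      "replacement of ", p$delta, " drives component(s) below zero: ",
      paste(neg, collapse = ", ")
    ))
  }
  out
}

# Match a user label against the names of a composition vector, tolerating
# full amino-acid names where the vector is named by abbreviation.
.match_component <- function(label, have) {
  if (label %in% have) return(label)
  cb <- .aa_codebook()
  if (all(have %in% cb$abbrev)) {
    ab <- tryCatch(.aa_normalize(label), error = function(e) NA_character_)
    if (!is.na(ab) && ab %in% have) return(ab)
  }
  abort(paste0("component `", label, "` not found in the composition"))
}
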