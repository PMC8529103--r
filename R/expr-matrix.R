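#' Construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' samples in columns, tagged with the scale its values live on: `"counts"`
#' for raw non-negative counts or `"log2"` for log2-transformed values.
#' Every pipeline operation propagates the tag, and operations that require
#' a particular scale (normalization, batch correction, prediction) refuse
#' input on the wrong one.
#'
#' @param values numeric matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param scale one of `"counts"` or `"log2"`.
#' @return the matrix with a `scale` attribute and class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale = c("counts", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("expression matrix needs rownames (gene ids) and colnames (sample ids)")
  }
  if (is.null(dimnames(values))) {
    dimnames(values) <- list(character(0), character(0))
  }
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g)) stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s)) stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (scale == "counts" && any(values < 0)) {
    stop("counts matrix contains negative values")
  }
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' Scale tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return `"counts"` or `"log2"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("matrix carries no scale tag; construct it with expr_matrix()")
  s
}

# internal: assert the tag, with the caller's error label
check_scale <- function(x, expected, error = NULL) {
  s <- expr_scale(x)
  if (!identical(s, expected)) {
    stop(if (is.null(error)) sprintf("expected a %s-scale matrix, got %s", expected, s)
         else error)
  }
  invisible(x)
}

# internal: keep class/scale when subsetting
reclass_expr <- function(values, template) {
  expr_matrix(values, scale = expr_scale(template))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s scale]\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}
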