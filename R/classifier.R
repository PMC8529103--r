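# numerically stable log(1 + exp(z))
log1pexp <- function(z) ifelse(z > 35, z, log1p(exp(pmin(z, 35))))

# Platt sigmoid calibration: fit (A, B) of p = 1 / (1 + exp(-(A*d + B)))
# by penalized maximum likelihood with Platt's smoothed targets
# t+ = (N+ + 1)/(N+ + 2), t- = 1/(N- + 2); the tiny L2 term keeps the fit
# defined on degenerate decision-value sets.
platt_fit <- function(d, is_target, ridge = 1e-6) {
  n1 <- sum(is_target); n0 <- sum(!is_target)
  t <- ifelse(is_target, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    z <- par[1L] * d + par[2L]
    sum(t * log1pexp(-z) + (1 - t) * log1pexp(z)) + ridge * sum(par^2)
  }
  opt <- stats::optim(c(1, 0), nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  c(A = opt$par[1L], B = opt$par[2L])
}

#' Train the multiclass tissue-of-origin model
#'
#' Fits one linear soft-margin SVM per tumor type (one-vs-rest, with
#' inverse-frequency class weights) on the standardized panel-gene features,
#' and calibrates each class's decision values to probabilities with a Platt
#' sigmoid fit on cross-validated decision values (stratified folds, fixed
#' seed) rather than training-set values, which would be overconfident.
#'
#' @param expr a log2-scale [expr_matrix()] containing every panel gene.
#' @param labels data.frame `sample_id`, `label`; every class needs at least
#'   4 samples so each calibration fold sees both outcomes.
#' @param panel a `gene_panel` (or data.frame coercible via
#'   [as_gene_panel()]).
#' @param cost SVM regularization parameter C.
#' @param n_folds number of stratified calibration folds.
#' @param seed seed controlling the fold assignment.
#' @return a `too_model`: class roster, per-class weights/biases over the
#'   panel gene set, per-class Platt parameters, feature standardization
#'   statistics, the panel, and a version tag.
#' @export
train_model <- function(expr, labels, panel, cost = 1, n_folds = 5L, seed = 1L) {
  check_scale(expr, "log2")
  panel <- as_gene_panel(panel)
  genes <- panel_gene_set(panel)
  absent <- setdiff(genes, rownames(expr))
  if (length(absent)) {
    stop("panel gene(s) absent from expression matrix: ",
         paste(absent, collapse = ", "))
  }
  lab <- stats::setNames(labels$label, labels$sample_id)[colnames(expr)]
  if (anyNA(lab)) stop("label missing for sample(s): ",
                       paste(colnames(expr)[is.na(lab)], collapse = ", "))
  classes <- sort(unique(lab))
  too_small <- names(which(table(lab) < 4L))
  if (length(too_small)) {
    stop("class(es) with fewer than 4 samples: ", paste(too_small, collapse = ", "))
  }
  std <- standardize_genes(unclass(expr)[genes, , drop = FALSE])
  x <- t(std$z)

  weights <- matrix(0, length(genes), length(classes),
                    dimnames = list(genes, classes))
  biases <- stats::setNames(numeric(length(classes)), classes)
  calibration <- matrix(0, 2L, length(classes),
                        dimnames = list(c("A", "B"), classes))
  for (cl in classes) {
    y <- factor(ifelse(lab == cl, cl, ".rest"), levels = c(cl, ".rest"))
    folds <- stratified_folds(as.character(y), n_folds,
                              derive_seed(seed, paste0("folds_", cl)))
    d_cv <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      held <- folds == f
      fit_f <- linear_svm_fit(x[!held, , drop = FALSE], droplevels(y[!held]),
                              cost = cost, positive = cl)
      d_cv[held] <- drop(x[held, , drop = FALSE] %*% fit_f$w) + fit_f$b
    }
    calibration[, cl] <- platt_fit(d_cv, y == cl)
    fit <- linear_svm_fit(x, y, cost = cost, positive = cl)
    weights[, cl] <- fit$w
    biases[cl] <- fit$b
  }
  structure(list(version = "1", class_names = classes,
                 panel = as.data.frame(panel), feature_genes = genes,
                 feature_center = std$center, feature_scale = std$scale,
                 weights = weights, biases = biases,
                 calibration = calibration, cost = cost,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 n_train = ncol(expr)),
            class = "too_model")
}

#' @export
print.too_model <- function(x, ...) {
  cat(sprintf("too_model: %d tumor types, %d panel genes (v%s)\n",
              length(x$class_names), length(x$feature_genes), x$version))
  invisible(x)
}

# standardized panel-gene feature rows for a query matrix, with optional
# mean imputation of missing panel genes
query_features <- function(model, expr, impute_mean = FALSE) {
  absent <- setdiff(model$feature_genes, rownames(expr))
  if (length(absent) && !impute_mean) {
    stop("panel gene(s) missing from query data: ", paste(absent, collapse = ", "))
  }
  x <- matrix(NA_real_, length(model$feature_genes), ncol(expr),
              dimnames = list(model$feature_genes, colnames(expr)))
  present <- intersect(model$feature_genes, rownames(expr))
  x[present, ] <- unclass(expr)[present, ]
  if (length(absent)) {
    x[absent, ] <- model$feature_center[absent]
    message("imputed training means for ", length(absent), " missing panel gene(s)")
  }
  t((x - model$feature_center) / model$feature_scale)
}

score_matrix <- function(model, feat) {
  d <- feat %*% model$weights +
    matrix(model$biases, nrow(feat), length(model$biases), byrow = TRUE)
  p <- stats::plogis(sweep(d, 2L, model$calibration["A", ], `*`) +
                       matrix(model$calibration["B", ], nrow(d), ncol(d), byrow = TRUE))
  bad <- rowSums(p) == 0
  if (any(bad)) {
    stop("degenerate_calibration: all class probabilities are zero for sample(s): ",
         paste(rownames(feat)[bad], collapse = ", "))
  }
  100 * p / rowSums(p)
}

#' Similarity scores for a single specimen
#'
#' Maps one specimen's panel-gene expression to per-type similarity scores:
#' each one-vs-rest decision value is passed through its Platt sigmoid and
#' the resulting probabilities are renormalized to sum to 100. Every score
#' lies in \[0, 100\], the scores sum to 100, and the type with the highest
#' score is the predicted tissue of origin. Exact ties go to the
#' lexicographically smallest type name and are flagged.
#'
#' @param model a `too_model`.
#' @param sample named numeric vector of log2-scale expression covering the
#'   panel genes.
#' @param impute_mean substitute training means for missing panel genes
#'   instead of erroring.
#' @return a list of class `similarity_report`: `sample_id`, named `scores`,
#'   `predicted_type`, `top_score`, `tie_flag`.
#' @export
similarity_scores <- function(model, sample, impute_mean = FALSE) {
  stopifnot(inherits(model, "too_model"), !is.null(names(sample)))
  expr <- expr_matrix(matrix(sample, ncol = 1,
                             dimnames = list(names(sample), "query")), "log2")
  feat <- query_features(model, expr, impute_mean)
  s <- drop(score_matrix(model, feat))
  top <- max(s)
  tied <- names(s)[abs(s - top) <= 1e-9]
  structure(list(sample_id = "query", scores = s,
                 predicted_type = min(tied), top_score = top,
                 tie_flag = length(tied) > 1L),
            class = "similarity_report")
}

#' Predict tissue of origin for a set of specimens
#'
#' @param object a `too_model`.
#' @param expr a log2-scale [expr_matrix()] of query specimens (an
#'   unnormalized counts matrix is refused).
#' @param impute_mean substitute training means for missing panel genes.
#' @param ... unused.
#' @return data.frame with one row per specimen: `sample_id`, one score
#'   column per tumor type, `predicted_type`, `top_score`, `tie_flag`.
#' @export
predict.too_model <- function(object, expr, impute_mean = FALSE, ...) {
  if (!identical(expr_scale(expr), "log2")) {
    stop("unnormalized_input: predict requires a log2-scale matrix")
  }
  empty <- data.frame(sample_id = character(0))
  for (cl in object$class_names) empty[[cl]] <- numeric(0)
  empty$predicted_type <- character(0)
  empty$top_score <- numeric(0)
  empty$tie_flag <- logical(0)
  if (ncol(expr) == 0L) return(empty)
  feat <- query_features(object, expr, impute_mean)
  s <- score_matrix(object, feat)
  pred <- apply(s, 1L, function(r) {
    tied <- names(r)[abs(r - max(r)) <= 1e-9]
    c(min(tied), length(tied) > 1L)
  })
  out <- data.frame(sample_id = rownames(feat), stringsAsFactors = FALSE)
  for (cl in object$class_names) out[[cl]] <- unname(s[, cl])
  out$predicted_type <- unname(pred[1L, ])
  out$top_score <- unname(apply(s, 1L, max))
  out$tie_flag <- as.logical(pred[2L, ])
  rownames(out) <- NULL
  out
}

#' Serialize a trained model to versioned JSON
#'
#' Floating-point values are written at full precision so that
#' `read_model(write_model(m))` reproduces the model bit-exactly.
#'
#' @param model a `too_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "too_model"))
  payload <- list(
    version = model$version,
    class_names = model$class_names,
    panel = model$panel,
    feature_genes = model$feature_genes,
    feature_center = as.list(model$feature_center),
    feature_scale = as.list(model$feature_scale),
    weights = apply(model$weights, 2L, as.list, simplify = FALSE),
    biases = as.list(model$biases),
    calibration = apply(model$calibration, 2L, as.list, simplify = FALSE),
    cost = model$cost, n_folds = model$n_folds, seed = model$seed,
    n_train = model$n_train)
  # 17 significant digits: exact binary64 round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 17,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized tissue-of-origin model
#'
#' @param path a JSON file written by [write_model()].
#' @return the reconstructed `too_model`.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$version, "1")) stop("unsupported model version: ", p$version)
  genes <- p$feature_genes
  classes <- p$class_names
  unwrap <- function(lst) vapply(lst, function(v) as.numeric(v), numeric(1))
  weights <- matrix(0, length(genes), length(classes),
                    dimnames = list(genes, classes))
  calibration <- matrix(0, 2L, length(classes),
                        dimnames = list(c("A", "B"), classes))
  for (cl in classes) {
    weights[, cl] <- unwrap(p$weights[[cl]])[genes]
    calibration[, cl] <- unwrap(p$calibration[[cl]])[c("A", "B")]
  }
  structure(list(version = p$version, class_names = classes,
                 panel = as.data.frame(p$panel), feature_genes = genes,
                 feature_center = unwrap(p$feature_center)[genes],
                 feature_scale = unwrap(p$feature_scale)[genes],
                 weights = weights,
                 biases = unwrap(p$biases)[classes],
                 calibration = calibration, cost = p$cost,
                 n_folds = as.integer(p$n_folds), seed = as.integer(p$seed),
                 n_train = as.integer(p$n_train)),
            class = "too_model")
}
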