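#' Fit a PCA model on panel-gene expression
#'
#' Samples are the observations and genes the variables; genes are centered
#' but not rescaled (panel genes share the log2 scale, and rescaling would
#' flatten marker effect sizes). The decomposition is the singular value
#' decomposition of the centered matrix; loading signs are fixed so the
#' largest-magnitude loading of each component is positive, making the fit
#' reproducible across platforms.
#'
#' @param mat a log2-scale [expr_matrix()], typically restricted to panel
#'   genes and already batch-corrected when mixing cohorts.
#' @param d number of components, at most `min(genes, samples) - 1`.
#' @return a list of class `pca_model`: `center` (gene means), `loadings`
#'   (genes x d, orthonormal), `explained` (variance fractions,
#'   non-increasing), `d`.
#' @export
pca_fit <- function(mat, d = 2L) {
  check_scale(mat, "log2")
  d <- as.integer(d)
  if (d < 1L || d > min(dim(mat)) - 1L) {
    stop("`d` must lie in 1..min(genes, samples) - 1")
  }
  x <- unclass(mat)
  center <- rowMeans(x)
  xc <- t(x - center)              # samples x genes, gene-centered
  total_var <- sum(xc^2)
  if (total_var < 1e-12) stop("zero_variance: expression matrix is constant")
  sv <- svd(xc, nu = 0, nv = d)
  loadings <- sv$v
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(d)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) loadings[, k] <- -loadings[, k]
  }
  dimnames(loadings) <- list(rownames(mat), paste0("PC", seq_len(d)))
  structure(list(center = center, loadings = loadings,
                 explained = sv$d[seq_len(d)]^2 / total_var, d = d),
            class = "pca_model")
}

#' Project samples into a fitted PCA space
#'
#' Uses the reference-fit gene centering (queries never refit the model).
#'
#' @param pca a `pca_model`.
#' @param mat a log2-scale [expr_matrix()] over the same genes.
#' @return samples x d matrix of coordinates.
#' @export
pca_project <- function(pca, mat) {
  check_scale(mat, "log2")
  absent <- setdiff(rownames(pca$loadings), rownames(mat))
  if (length(absent)) {
    stop("gene(s) missing from matrix: ", paste(absent, collapse = ", "))
  }
  x <- unclass(mat)[rownames(pca$loadings), , drop = FALSE]
  t(x - pca$center) %*% pca$loadings
}

#' Assign queries to nearest reference class centroids
#'
#' The tissue-of-origin concordance check behind PCA cluster plots of CUP
#' versus primary tumors, made quantitative: each reference class's centroid
#' is the mean of its projected samples, each query is assigned to the
#' Euclidean-nearest centroid, and the concordant fraction is the share of
#' queries assigned to their true primary type. Distance ties go to the
#' lexicographically smallest class name and are flagged.
#'
#' @param pca a `pca_model`.
#' @param ref_mat,ref_labels reference expression (log2) and its label
#'   data.frame (`sample_id`, `label`); every class needs >= 1 sample.
#' @param query_mat query expression (log2).
#' @param query_labels data.frame with the true primary labels of the
#'   queries.
#' @return a list of class `concordance_assignment`: `assignments`
#'   (data.frame `sample_id`, `true_primary`, `assigned_type`,
#'   `centroid_distance`, `tie_flag`) and `concordant_fraction`.
#' @export
centroid_assign <- function(pca, ref_mat, ref_labels, query_mat, query_labels) {
  ref_proj <- pca_project(pca, ref_mat)
  lab <- stats::setNames(ref_labels$label, ref_labels$sample_id)[rownames(ref_proj)]
  if (anyNA(lab)) stop("reference label missing for sample(s): ",
                       paste(rownames(ref_proj)[is.na(lab)], collapse = ", "))
  classes <- sort(unique(lab))
  centroids <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(ref_proj[lab == cl, , drop = FALSE])
  }))
  rownames(centroids) <- classes
  q_proj <- pca_project(pca, query_mat)
  truth <- stats::setNames(query_labels$label, query_labels$sample_id)[rownames(q_proj)]
  rows <- lapply(seq_len(nrow(q_proj)), function(i) {
    dist <- sqrt(colSums((t(centroids) - q_proj[i, ])^2))
    nearest <- names(dist)[abs(dist - min(dist)) <= 1e-12]
    data.frame(sample_id = rownames(q_proj)[i], true_primary = truth[i],
               assigned_type = min(nearest), centroid_distance = min(dist),
               tie_flag = length(nearest) > 1L, stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  structure(list(assignments = assignments,
                 concordant_fraction =
                   mean(assignments$assigned_type == assignments$true_primary)),
            class = "concordance_assignment")
}
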