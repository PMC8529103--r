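#' Parameters for SVM-RFE panel selection
#'
#' @param top_m number of top-ranked genes kept per tumor type.
#' @param cost soft-margin regularization parameter C of the linear SVM
#'   (hinge loss + L2 penalty of strength 1/C), applied to standardized
#'   features.
#' @param step_threshold while more than this many genes survive, a fraction
#'   of genes is eliminated per iteration; at or below it, exactly one gene
#'   is eliminated per iteration.
#' @param step_fraction fraction of surviving genes eliminated per iteration
#'   above `step_threshold`.
#' @param seed seed recorded for provenance (the elimination itself is
#'   deterministic given the data).
#' @return a list of class `rfe_params`.
#' @export
rfe_params <- function(top_m = 10L, cost = 1, step_threshold = 200L,
                       step_fraction = 0.1, seed = 1L) {
  if (top_m < 1L) stop("`top_m` must be >= 1")
  if (cost <= 0) stop("`cost` must be > 0")
  if (step_fraction <= 0 || step_fraction >= 1) stop("`step_fraction` must lie in (0, 1)")
  structure(list(top_m = as.integer(top_m), cost = cost,
                 step_threshold = as.integer(step_threshold),
                 step_fraction = step_fraction, seed = as.integer(seed)),
            class = "rfe_params")
}

# z-score genes (rows) across samples; constant genes are centered only
standardize_genes <- function(x, center = rowMeans(x),
                              scale = apply(x, 1L, stats::sd)) {
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(z = (x - center) / scale, center = center, scale = scale)
}

# inverse-frequency class weights for a two-class factor
inverse_freq_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab))
  stats::setNames(w, names(tab))
}

# fit a linear soft-margin SVM on samples x features and return the primal
# weight vector and bias of the decision function d(x) = x . w + b, oriented
# so that the `positive` class has the larger decision values
linear_svm_fit <- function(x, y, cost, positive) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = inverse_freq_weights(y))
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  d <- drop(x %*% w) + b
  if (mean(d[y == positive]) < mean(d[y != positive])) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

#' Rank genes by SVM recursive feature elimination
#'
#' Implements the classical SVM-RFE ranking for one binary contrast: fit a
#' linear soft-margin SVM on the surviving genes (standardized internally),
#' score each gene by its squared weight, eliminate the lowest-scoring
#' gene(s), and repeat until no genes remain. Rank 1 is the last survivor.
#' While more than `step_threshold` genes survive, the lowest
#' `step_fraction` are dropped per iteration; after that one gene is dropped
#' at a time. Exact criterion ties are eliminated together, ordered by gene
#' id, so the ranking is deterministic.
#'
#' @param expr a log2-scale [expr_matrix()].
#' @param labels data.frame `sample_id`, `label` with exactly two classes
#'   (e.g. target vs rest), each with at least 2 samples.
#' @param params an [rfe_params()].
#' @return data.frame `gene_id`, `rank` covering every gene (rank 1 = most
#'   predictive).
#' @export
svm_rfe_rank <- function(expr, labels, params = rfe_params()) {
  check_scale(expr, "log2")
  stopifnot(inherits(params, "rfe_params"))
  lab <- stats::setNames(labels$label, labels$sample_id)[colnames(expr)]
  if (anyNA(lab)) stop("label missing for sample(s): ",
                       paste(colnames(expr)[is.na(lab)], collapse = ", "))
  classes <- sort(unique(lab))
  if (length(classes) != 2L) {
    stop("svm_rfe_rank needs exactly 2 classes, got ", length(classes))
  }
  if (any(table(lab) < 2L)) stop("each class needs at least 2 samples")
  y <- factor(lab, levels = classes)
  z <- standardize_genes(unclass(expr))$z
  surviving <- sort(rownames(expr))
  eliminated <- character(0)
  while (length(surviving) > 1L) {
    fit <- linear_svm_fit(t(z[surviving, , drop = FALSE]), y,
                          cost = params$cost, positive = classes[1L])
    crit <- stats::setNames(fit$w^2, surviving)
    n_drop <- if (length(surviving) > params$step_threshold) {
      max(1L, floor(params$step_fraction * length(surviving)))
    } else 1L
    # lowest criterion first; exact ties resolved by gene id
    ord <- surviving[order(crit, surviving)]
    drop_now <- ord[seq_len(n_drop)]
    eliminated <- c(eliminated, drop_now)
    surviving <- setdiff(surviving, drop_now)
  }
  ranking <- rev(c(eliminated, surviving))
  data.frame(gene_id = ranking, rank = seq_along(ranking),
             stringsAsFactors = FALSE)
}

#' Select a marker-gene panel by per-type SVM-RFE
#'
#' For each tumor type, genes are ranked by [svm_rfe_rank()] on the
#' one-vs-rest contrast and the `top_m` kept. The panel gene set is the
#' deduplicated union across types; a gene selected for several types keeps
#' all its per-type entries but appears once in the gene set (the analog of
#' collapsing a `K * top_m` list into a smaller panel by removing redundant
#' genes).
#'
#' @param expr a log2-scale [expr_matrix()].
#' @param labels data.frame `sample_id`, `label` with >= 2 tumor types.
#' @param params an [rfe_params()].
#' @return a `gene_panel`: data.frame `gene_id`, `tumor_type`, `rank` with
#'   attribute `panel_gene_set` (sorted unique gene ids).
#' @export
select_panel <- function(expr, labels, params = rfe_params()) {
  check_scale(expr, "log2")
  lab <- stats::setNames(labels$label, labels$sample_id)[colnames(expr)]
  types <- sort(unique(lab))
  if (length(types) < 2L) stop("select_panel needs >= 2 tumor types")
  small <- names(which(table(lab) < 2L))
  if (length(small)) stop("tumor type(s) with < 2 samples: ",
                          paste(small, collapse = ", "))
  if (params$top_m > nrow(expr)) {
    stop("`top_m` exceeds the number of genes")
  }
  rows <- lapply(types, function(ty) {
    bin <- data.frame(sample_id = colnames(expr),
                      label = ifelse(lab == ty, ty, ".rest"),
                      stringsAsFactors = FALSE)
    rk <- svm_rfe_rank(expr, bin, params)
    data.frame(gene_id = rk$gene_id[seq_len(params$top_m)],
               tumor_type = ty, rank = seq_len(params$top_m),
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  as_gene_panel(panel)
}

#' Coerce a data.frame to a gene panel
#'
#' @param panel data.frame with `gene_id`, `tumor_type`, `rank`.
#' @return the validated `gene_panel` with the `panel_gene_set` attribute.
#' @export
as_gene_panel <- function(panel) {
  need <- c("gene_id", "tumor_type", "rank")
  absent <- setdiff(need, names(panel))
  if (length(absent)) stop("panel lacks column(s): ", paste(absent, collapse = ", "))
  for (ty in unique(panel$tumor_type)) {
    rk <- sort(panel$rank[panel$tumor_type == ty])
    if (!identical(as.integer(rk), seq_along(rk))) {
      stop(sprintf("ranks for type '%s' must be unique and span 1..m", ty))
    }
  }
  structure(as.data.frame(panel), panel_gene_set = sort(unique(panel$gene_id)),
            class = c("gene_panel", "data.frame"))
}

#' Deduplicated gene set of a panel
#' @param panel a `gene_panel`.
#' @return sorted character vector of unique panel gene ids.
#' @export
panel_gene_set <- function(panel) {
  attr(panel, "panel_gene_set") %||% sort(unique(panel$gene_id))
}
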