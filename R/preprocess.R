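#' Specimen quality-control policy
#'
#' Specimens are profiled only when the RNA extract is sufficiently pure and
#' the section sufficiently tumor-rich: A260/A280 within
#' \[`min_ratio`, `max_ratio`\] and tumor-cell content at least
#' `min_tumor_pct`. Both bounds are inclusive. Defaults follow the common
#' FFPE RT-PCR gate of 1.2–2.4 purity and 60% tumor content.
#'
#' @param min_ratio,max_ratio inclusive A260/A280 bounds.
#' @param min_tumor_pct inclusive minimum tumor-cell percentage.
#' @return a list of class `qc_policy`.
#' @export
qc_policy <- function(min_ratio = 1.2, max_ratio = 2.4, min_tumor_pct = 60) {
  if (!(min_ratio < max_ratio)) stop("`min_ratio` must be < `max_ratio`")
  if (min_tumor_pct < 0 || min_tumor_pct > 100) {
    stop("`min_tumor_pct` must lie in [0, 100]")
  }
  structure(list(min_ratio = min_ratio, max_ratio = max_ratio,
                 min_tumor_pct = min_tumor_pct), class = "qc_policy")
}

#' QC-gate specimens
#'
#' Applies the [qc_policy()] to specimen metadata and returns a verdict per
#' specimen. A missing QC field is a failure (reason `missing_field`), never
#' a silent pass. When several rules are violated all reasons are reported,
#' separated by `";"`.
#'
#' @param metadata data.frame with `sample_id`, `a260_a280`,
#'   `tumor_content_pct`.
#' @param policy a [qc_policy()].
#' @return data.frame with `sample_id`, logical `pass`, and `reason`
#'   (`""` for passing specimens).
#' @export
qc_filter <- function(metadata, policy = qc_policy()) {
  stopifnot(inherits(policy, "qc_policy"))
  need <- c("sample_id", "a260_a280", "tumor_content_pct")
  absent <- setdiff(need, names(metadata))
  if (length(absent)) stop("metadata lacks column(s): ", paste(absent, collapse = ", "))
  reasons <- vapply(seq_len(nrow(metadata)), function(i) {
    r <- metadata$a260_a280[i]; t <- metadata$tumor_content_pct[i]
    why <- character()
    if (is.na(r) || is.na(t)) return("missing_field")
    if (r < policy$min_ratio) why <- c(why, "ratio_below_min")
    if (r > policy$max_ratio) why <- c(why, "ratio_above_max")
    if (t < policy$min_tumor_pct) why <- c(why, "tumor_below_min")
    paste(why, collapse = ";")
  }, character(1))
  data.frame(sample_id = metadata$sample_id, pass = reasons == "",
             reason = reasons, stringsAsFactors = FALSE)
}

#' Median-of-ratios size factors
#'
#' The standard count normalization estimator for sequencing depth: the size
#' factor of sample `j` is the median, over genes with strictly positive
#' counts in every sample, of that gene's count divided by its geometric
#' mean across samples. Factors are returned unnormalized.
#'
#' @param counts a counts-scale [expr_matrix()].
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  check_scale(counts, "counts")
  all_pos <- rowSums(counts <= 0) == 0L
  if (!any(all_pos)) {
    stop("no_reference_genes: no gene has strictly positive counts in every sample")
  }
  x <- unclass(counts)[all_pos, , drop = FALSE]
  geomean <- exp(rowMeans(log(x)))
  apply(x, 2L, function(col) stats::median(col / geomean))
}

#' Normalize counts to log2 scale
#'
#' Divides each sample's counts by its size factor and applies `log2(x + 1)`,
#' so a zero count maps to exactly zero.
#'
#' @param counts a counts-scale [expr_matrix()].
#' @param factors named size factors from [size_factors()] covering all
#'   samples.
#' @return a log2-scale [expr_matrix()].
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  check_scale(counts, "counts")
  missing <- setdiff(colnames(counts), names(factors))
  if (length(missing)) {
    stop("no size factor for sample(s): ", paste(missing, collapse = ", "))
  }
  if (any(factors[colnames(counts)] <= 0)) stop("size factors must be positive")
  out <- sweep(unclass(counts), 2L, factors[colnames(counts)], `/`)
  expr_matrix(log2(out + 1), "log2")
}

#' Location-scale batch correction
#'
#' Aligns batches on the log2 scale gene by gene: within each batch, values
#' are standardized by the batch mean and SD and re-expressed around the
#' gene's grand mean and pooled within-batch SD, so that after correction
#' every batch has the same per-gene mean (within numerical tolerance). The
#' pooled within-batch SD as target scale makes the operation exactly
#' idempotent. Genes that are constant within a batch (SD below `eps`) are
#' re-centered only.
#'
#' @param mat a log2-scale [expr_matrix()].
#' @param metadata data.frame with `sample_id` and `batch` covering every
#'   sample; each batch must contain at least 2 samples.
#' @param eps SD threshold below which a gene is treated as constant within
#'   a batch.
#' @return the corrected log2-scale [expr_matrix()].
#' @export
correct_batches <- function(mat, metadata, eps = 1e-12) {
  check_scale(mat, "log2")
  batch <- stats::setNames(metadata$batch, metadata$sample_id)
  missing <- setdiff(colnames(mat), names(batch))
  if (length(missing)) {
    stop("sample(s) with no batch assignment: ", paste(missing, collapse = ", "))
  }
  batch <- batch[colnames(mat)]
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    stop("degenerate_batch: batch(es) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  x <- unclass(mat)
  grand <- rowMeans(x)
  batches <- names(sizes)
  per_batch <- function(f) {
    matrix(unlist(lapply(batches, f)), nrow = nrow(x),
           dimnames = list(rownames(x), batches))
  }
  bm <- per_batch(function(b) rowMeans(x[, batch == b, drop = FALSE]))
  bs <- per_batch(function(b) apply(x[, batch == b, drop = FALSE], 1L, stats::sd))
  # pooled within-batch SD over the batches where the gene varies; using it
  # as the target scale makes the correction exactly idempotent
  nb <- as.numeric(sizes[batches])
  varies <- bs > eps
  wt <- sweep(varies, 2L, nb - 1, `*`)
  denom <- rowSums(wt)
  pooled <- sqrt(ifelse(denom > 0, rowSums(bs^2 * wt) / denom, 0))
  out <- x
  for (b in batches) {
    j <- which(batch == b)
    centred <- out[, j, drop = FALSE] - bm[, b]
    ratio <- ifelse(varies[, b], pooled / bs[, b], 1)
    out[, j] <- centred * ratio + grand
  }
  expr_matrix(out, "log2")
}
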