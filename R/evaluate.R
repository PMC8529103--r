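#' Concordance of predictions with reference diagnoses
#'
#' Exact, case-sensitive agreement between predicted and reference labels,
#' with per-class recall and a confusion matrix. Machine-readable accuracy
#' is kept at full precision; the display string truncates to one decimal
#' (42 of 44 is 95.4545...%, displayed "95.4%" — the convention used when
#' such rates are reported clinically).
#'
#' @param predictions data.frame `sample_id`, `label` of predicted types
#'   (the `predicted_type` column of [predict.too_model()] output works via
#'   [as_label_table()]).
#' @param references data.frame `sample_id`, `label` of reference diagnoses
#'   over the same sample set.
#' @return a list of class `concordance_result`: `n_total`, `n_agree`,
#'   `accuracy_pct` (full precision), `display`, `per_class` (data.frame
#'   with reference counts, agreements, recall), `confusion` (reference x
#'   predicted table).
#' @export
concordance <- function(predictions, references) {
  pred <- stats::setNames(predictions$label, predictions$sample_id)
  ref <- stats::setNames(references$label, references$sample_id)
  only_p <- setdiff(names(pred), names(ref))
  only_r <- setdiff(names(ref), names(pred))
  if (length(only_p) || length(only_r)) {
    stop("sample sets differ; only in predictions: [",
         paste(only_p, collapse = ", "), "], only in references: [",
         paste(only_r, collapse = ", "), "]")
  }
  if (anyNA(pred) || anyNA(ref)) stop("missing labels are not allowed")
  pred <- pred[names(ref)]
  n_total <- length(ref)
  n_agree <- sum(pred == ref)
  roster <- sort(unique(c(pred, ref)))
  confusion <- table(reference = factor(ref, roster),
                     predicted = factor(pred, roster))
  per_class <- data.frame(
    class = roster,
    n_reference = as.integer(rowSums(confusion)),
    n_agree = as.integer(diag(confusion)),
    stringsAsFactors = FALSE)
  per_class$recall_pct <- ifelse(per_class$n_reference > 0,
                                 100 * per_class$n_agree / per_class$n_reference,
                                 NA_real_)
  accuracy <- 100 * n_agree / n_total
  structure(list(n_total = n_total, n_agree = n_agree,
                 accuracy_pct = accuracy,
                 display = paste0(truncate_pct(accuracy), "%"),
                 per_class = per_class, confusion = confusion),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: %s (%d/%d)\n", x$display, x$n_agree, x$n_total))
  invisible(x)
}

#' Extract a label table from a prediction table
#'
#' @param predictions output of [predict.too_model()].
#' @return data.frame `sample_id`, `label` using the predicted type.
#' @export
as_label_table <- function(predictions) {
  data.frame(sample_id = predictions$sample_id,
             label = predictions$predicted_type, stringsAsFactors = FALSE)
}

#' Per-modality diagnosis coincidence rates
#'
#' For a table recording, per specimen and diagnostic modality (e.g.
#' immunohistochemistry, morphology, serology, imaging), whether that
#' modality's call agreed with the reference diagnosis, computes each
#' modality's coincidence rate over its non-missing entries. Denominators
#' differ between modalities whenever a modality was not assessed for every
#' specimen, so they are reported alongside the rates; a modality with no
#' non-missing entries is flagged undefined rather than reported as 0.
#'
#' @param agreement data.frame with `sample_id` and one column per modality
#'   containing `"agree"`, `"disagree"`, or `NA`.
#' @return data.frame `modality`, `n_agree`, `n_assessed`, `rate_pct`,
#'   `display`, `defined`.
#' @export
modality_concordance <- function(agreement) {
  stopifnot("sample_id" %in% names(agreement))
  modalities <- setdiff(names(agreement), "sample_id")
  rows <- lapply(modalities, function(m) {
    v <- agreement[[m]]
    bad <- !is.na(v) & !v %in% c("agree", "disagree")
    if (any(bad)) stop(sprintf("modality '%s' has invalid entries: %s", m,
                               paste(unique(v[bad]), collapse = ", ")))
    n <- sum(!is.na(v))
    a <- sum(v == "agree", na.rm = TRUE)
    rate <- if (n > 0) 100 * a / n else NA_real_
    data.frame(modality = m, n_agree = a, n_assessed = n, rate_pct = rate,
               display = if (n > 0) paste0(truncate_pct(rate), "%") else "undefined",
               defined = n > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Report discordant specimens
#'
#' One record per specimen whose predicted type differs from its reference
#' diagnosis, carrying the predicted type and its top similarity score —
#' the shape of a published discordant-case table. Records are ordered by
#' sample id; a fully concordant input yields an empty table.
#'
#' @param predictions output of [predict.too_model()] (needs
#'   `predicted_type` and `top_score`).
#' @param references data.frame `sample_id`, `label` of reference diagnoses.
#' @param metadata optional specimen metadata; if given, its
#'   `reference_diagnosis` batch and QC fields are ignored but free-text
#'   notes in a `note` column are carried through.
#' @return data.frame `sample_id`, `reference_diagnosis`, `predicted_type`,
#'   `top_score`, `note`.
#' @export
discordance_report <- function(predictions, references, metadata = NULL) {
  ref <- stats::setNames(references$label, references$sample_id)
  out <- predictions[predictions$predicted_type !=
                       ref[predictions$sample_id], , drop = FALSE]
  notes <- if (!is.null(metadata) && "note" %in% names(metadata)) {
    stats::setNames(metadata$note, metadata$sample_id)
  } else NULL
  res <- data.frame(sample_id = out$sample_id,
                    reference_diagnosis = unname(ref[out$sample_id]),
                    predicted_type = out$predicted_type,
                    top_score = out$top_score,
                    note = if (is.null(notes)) character(nrow(out)) else
                      unname(notes[out$sample_id]),
                    stringsAsFactors = FALSE)
  res <- res[order(res$sample_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
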