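# Tab-separated interchange formats. Matrices carry their scale in a
# `#scale=` comment line; panels record their deduplicated size in a
# `#panel_size=` comment. All other tables are plain TSV with headers.

#' Write an expression matrix as tab-separated text
#'
#' Layout: a `#scale=` comment line, a header row (`gene_id` then sample
#' ids), one row per gene. Values are written at full precision so a
#' write/read round trip reproduces the matrix.
#'
#' @param mat an [expr_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  scale <- expr_scale(mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#scale=", scale), con)
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  body <- cbind(rownames(mat),
                format(unclass(mat), digits = 17, trim = TRUE,
                       scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read an expression matrix from tab-separated text
#'
#' Expects the layout of [write_expression()]. Without a `#scale=` comment
#' the scale is inferred as `counts` iff every value is a non-negative
#' integer; otherwise reading fails. Duplicate ids and ragged rows are hard
#' errors.
#'
#' @param path input path.
#' @return an [expr_matrix()].
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  scale <- NULL
  tag <- lines[is_comment][startsWith(lines[is_comment], "#scale=")]
  if (length(tag)) scale <- sub("^#scale=", "", tag[1L])
  body_idx <- which(!is_comment)
  if (length(body_idx) < 2L) stop("no data rows in ", path)
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  width <- length(fields[[1L]])
  ragged <- which(lengths(fields) != width)
  if (length(ragged)) {
    stop(sprintf("ragged row at line %d of %s (expected %d fields, got %d)",
                 body_idx[ragged[1L]], path, width,
                 lengths(fields)[ragged[1L]]))
  }
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  rows <- fields[-1L]
  gene_ids <- vapply(rows, `[[`, character(1), 1L)
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  values <- matrix(as.numeric(unlist(lapply(rows, `[`, -1L))),
                   nrow = length(rows), byrow = TRUE,
                   dimnames = list(gene_ids, sample_ids))
  if (anyNA(values)) stop("non-numeric value in ", path)
  if (is.null(scale)) {
    if (all(values >= 0) && all(values == round(values))) {
      scale <- "counts"
    } else {
      stop("no #scale= comment and values are not non-negative integers; ",
           "cannot infer the scale of ", path)
    }
  }
  expr_matrix(values, scale)
}

write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(comments, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read/write label tables, metadata, panels and score tables
#'
#' Plain tab-separated text with headers. Panels carry a `#panel_size=`
#' comment with the deduplicated panel size. Score tables hold one row per
#' specimen with one column per tumor type; `raw = FALSE` rounds scores to
#' one decimal for display, `raw = TRUE` keeps full precision.
#'
#' @param labels,metadata,panel,predictions data to write.
#' @param path file path.
#' @param raw write full-precision scores instead of one-decimal display.
#' @return the read object, or `path` invisibly for writers.
#' @name tabular_io
NULL

#' @rdname tabular_io
#' @export
write_labels <- function(labels, path) write_tsv(labels, path)

#' @rdname tabular_io
#' @export
read_labels <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "label")
  if (!all(need %in% names(df))) stop("label table needs columns sample_id, label")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  df
}

#' @rdname tabular_io
#' @export
write_metadata <- function(metadata, path) write_tsv(metadata, path)

#' @rdname tabular_io
#' @export
read_metadata <- function(path) {
  df <- read_tsv(path)
  if (!"sample_id" %in% names(df)) stop("metadata needs a sample_id column")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  df
}

#' @rdname tabular_io
#' @export
write_panel <- function(panel, path) {
  panel <- as_gene_panel(panel)
  write_tsv(as.data.frame(panel), path,
            comments = paste0("#panel_size=", length(panel_gene_set(panel))))
}

#' @rdname tabular_io
#' @export
read_panel <- function(path) as_gene_panel(read_tsv(path))

#' @rdname tabular_io
#' @export
write_scores <- function(predictions, path, raw = FALSE) {
  out <- predictions
  if (!raw) {
    num <- setdiff(names(out)[vapply(out, is.numeric, logical(1))], "tie_flag")
    for (cl in num) out[[cl]] <- sprintf("%.1f", out[[cl]])
  }
  write_tsv(out, path)
}
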