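# Shared fixtures and independent oracles. Heavy objects are memoized so the
# acceptance tests can share one full-scale simulation.

.fixtures <- new.env(parent = emptyenv())

memoize <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# quick expr_matrix with generated dimnames
make_expr <- function(values, scale = "log2",
                      genes = sprintf("g%03d", seq_len(nrow(values))),
                      samples = sprintf("s%03d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, scale)
}

# column subset that keeps the scale tag
expr_cols <- function(mat, ids) {
  expr_matrix(unclass(mat)[, ids, drop = FALSE], expr_scale(mat))
}

expr_rows <- function(mat, ids) {
  expr_matrix(unclass(mat)[ids, , drop = FALSE], expr_scale(mat))
}

# Independent median-of-ratios oracle: explicit loops, no shared code with
# size_factors().
brute_force_size_factors <- function(m) {
  keep <- integer(0)
  for (i in seq_len(nrow(m))) {
    if (all(m[i, ] > 0)) keep <- c(keep, i)
  }
  if (!length(keep)) stop("no all-positive gene")
  geo <- numeric(length(keep))
  for (k in seq_along(keep)) {
    geo[k] <- exp(mean(log(m[keep[k], ])))
  }
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- numeric(length(keep))
    for (k in seq_along(keep)) ratios[k] <- m[keep[k], j] / geo[k]
    out[j] <- median(ratios)
  }
  names(out) <- colnames(m)
  out
}

# Wide-margin two-class data: class means far apart relative to noise.
separable_two_class <- function(n_per_class = 20, n_genes = 12, seed = 42) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_genes * 2 * n_per_class), n_genes)
    x[1:3, seq_len(n_per_class)] <- x[1:3, seq_len(n_per_class)] + 8
  })
  mat <- make_expr(x)
  labels <- data.frame(sample_id = colnames(mat),
                       label = rep(c("alpha", "beta"), each = n_per_class),
                       stringsAsFactors = FALSE)
  list(expr = mat, labels = labels)
}

# The desk-scale study conditions: 6 types, 300 genes, 10 disjoint markers
# per type at log2 fold change 2, NB dispersion 0.1, 60 samples per type.
study_config <- function(seed, ...) sim_config(seed = seed, ...)

# Full-scale simulation + panel + model at master seed 1, shared across the
# acceptance checks (~30 s to build, built once).
full_fixture <- function() {
  memoize("full", function() {
    cfg <- study_config(seed = 1)
    ref <- generate_reference(cfg)
    qry <- generate_query(cfg, ref, 90)
    combined <- expr_matrix(cbind(unclass(ref$counts), unclass(qry$counts)),
                            "counts")
    norm <- normalize_counts(combined)
    ref_norm <- expr_cols(norm, ref$labels$sample_id)
    qry_norm <- expr_cols(norm, qry$labels$sample_id)
    panel <- select_panel(ref_norm, ref$labels, rfe_params())
    model <- train_model(ref_norm, ref$labels, panel, seed = 1)
    list(cfg = cfg, ref = ref, qry = qry, norm = norm,
         metadata = rbind(ref$metadata, qry$metadata),
         ref_norm = ref_norm, qry_norm = qry_norm, panel = panel,
         model = model, planted = sort(unique(unlist(ref$params$marker_sets))))
  })
}

# Panel selection + training + held-out prediction under the study
# conditions with a 30% held-out split; used for the label-recovery checks.
split_run <- function(lfc, seed) {
  cfg <- study_config(seed = seed, log2_fold_change = lfc)
  ref <- generate_reference(cfg)
  norm <- normalize_counts(ref$counts)
  n <- ncol(norm)
  test_idx <- withr::with_seed(seed + 1000, sort(sample.int(n, round(0.3 * n))))
  train <- expr_cols(norm, colnames(norm)[-test_idx])
  test <- expr_cols(norm, colnames(norm)[test_idx])
  train_lab <- ref$labels[-test_idx, ]
  test_lab <- ref$labels[test_idx, ]
  panel <- select_panel(train, train_lab, rfe_params())
  model <- train_model(train, train_lab, panel, seed = seed)
  cc <- concordance(as_label_table(predict(model, test)), test_lab)
  list(accuracy_pct = cc$accuracy_pct, n_test = cc$n_total,
       n_types = cfg$n_types)
}
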