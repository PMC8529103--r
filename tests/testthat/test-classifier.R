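# a small hand-built model over 2 genes and 2 classes for contract tests
toy_model <- function(A = c(1, 1), B = c(0, 0)) {
  structure(list(
    version = "1", class_names = c("alpha", "beta"),
    panel = data.frame(gene_id = c("g1", "g2"),
                       tumor_type = c("alpha", "beta"), rank = c(1L, 1L)),
    feature_genes = c("g1", "g2"),
    feature_center = c(g1 = 0, g2 = 0), feature_scale = c(g1 = 1, g2 = 1),
    weights = matrix(c(1, 0, 0, 1), 2,
                     dimnames = list(c("g1", "g2"), c("alpha", "beta"))),
    biases = c(alpha = 0, beta = 0),
    calibration = matrix(c(A[1], B[1], A[2], B[2]), 2,
                         dimnames = list(c("A", "B"), c("alpha", "beta"))),
    cost = 1, n_folds = 5L, seed = 1L, n_train = 0L), class = "too_model")
}

test_that("well-separated classes are classified perfectly out of sample", {
  sep <- separable_two_class(n_per_class = 24)
  idx <- rep(c(TRUE, FALSE), 24)      # alternate train/test within classes
  train <- expr_cols(sep$expr, colnames(sep$expr)[idx])
  test <- expr_cols(sep$expr, colnames(sep$expr)[!idx])
  panel <- select_panel(train, sep$labels[idx, ], rfe_params(top_m = 3))
  model <- train_model(train, sep$labels[idx, ], panel, seed = 2)
  pred <- predict(model, test)
  expect_identical(pred$predicted_type,
                   sep$labels$label[!idx])
  cc <- concordance(as_label_table(pred), sep$labels[!idx, ])
  expect_equal(cc$accuracy_pct, 100)
})

test_that("shuffled labels give chance-level held-out accuracy", {
  cfg <- sim_config(n_types = 3, n_genes = 40, n_per_type = 40,
                    markers_per_type = 5, seed = 17)
  ref <- generate_reference(cfg)
  norm <- normalize_counts(ref$counts)
  lab <- ref$labels
  lab$label <- withr::with_seed(99, sample(lab$label))
  idx <- withr::with_seed(98, sort(sample.int(ncol(norm), 84)))
  train <- expr_cols(norm, colnames(norm)[idx])
  test <- expr_cols(norm, colnames(norm)[-idx])
  panel <- select_panel(train, lab[idx, ], rfe_params(top_m = 5))
  model <- train_model(train, lab[idx, ], panel, seed = 3)
  acc <- mean(predict(model, test)$predicted_type == lab$label[-idx])
  n <- ncol(norm) - length(idx)
  ci <- stats::qbinom(c(0.005, 0.995), n, 1 / 3) / n
  expect_gte(acc, ci[1])
  expect_lte(acc, ci[2])
})

test_that("similarity scores satisfy the range, sum and argmax contract", {
  fx <- full_fixture()
  model <- fx$model
  genes <- model$feature_genes
  withr::with_seed(123, {
    for (i in 1:50) {
      v <- setNames(rnorm(length(genes), 6, 3), genes)
      rep <- similarity_scores(model, v)
      expect_true(all(rep$scores >= 0 & rep$scores <= 100))
      expect_lt(abs(sum(rep$scores) - 100), 1e-6)
      expect_identical(unname(rep$top_score), max(rep$scores))
      expect_identical(rep$predicted_type,
                       names(rep$scores)[which.max(rep$scores)])
    }
  })
})

test_that("decision values at both calibrated midpoints tie at 50/50", {
  model <- toy_model(A = c(2, 2), B = c(-1, -1))
  # midpoint: A*d + B = 0 -> d = 0.5 for both classes
  rep <- similarity_scores(model, c(g1 = 0.5, g2 = 0.5))
  expect_equal(unname(rep$scores), c(50, 50), tolerance = 1e-9)
  expect_true(rep$tie_flag)
  expect_identical(rep$predicted_type, "alpha")   # lexicographic tie-break
})

test_that("raising the projection on a class weight direction never lowers its score", {
  model <- toy_model()
  base <- similarity_scores(model, c(g1 = 0, g2 = 0.3))$scores[["alpha"]]
  prev <- base
  for (d in seq(0.2, 3, by = 0.2)) {
    s <- similarity_scores(model, c(g1 = d, g2 = 0.3))$scores[["alpha"]]
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("degenerate calibration is an error, not a silent zero", {
  model <- toy_model(A = c(1, 1), B = c(-5000, -5000))
  expect_error(similarity_scores(model, c(g1 = 0, g2 = 0)),
               "degenerate_calibration")
})

test_that("models survive a serialize/deserialize round trip bit-exactly", {
  sep <- separable_two_class()
  panel <- select_panel(sep$expr, sep$labels, rfe_params(top_m = 3))
  model <- train_model(sep$expr, sep$labels, panel, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(back$weights, model$weights)
  expect_identical(back$biases, model$biases)
  expect_identical(back$calibration, model$calibration)
  expect_identical(back$feature_center, model$feature_center)
  query <- make_expr(matrix(rnorm(nrow(sep$expr) * 5), nrow(sep$expr)),
                     genes = rownames(sep$expr))
  expect_identical(predict(back, query), predict(model, query))
})

test_that("prediction refuses unnormalized input and missing panel genes", {
  sep <- separable_two_class()
  panel <- select_panel(sep$expr, sep$labels, rfe_params(top_m = 3))
  model <- train_model(sep$expr, sep$labels, panel, seed = 1)
  counts <- make_expr(matrix(1:20, 10), "counts",
                      genes = rownames(sep$expr)[1:10])
  expect_error(predict(model, counts), "unnormalized_input")
  partial <- expr_rows(sep$expr, setdiff(rownames(sep$expr),
                                         model$feature_genes[1]))
  expect_error(predict(model, partial), model$feature_genes[1])
  expect_message(out <- predict(model, partial, impute_mean = TRUE), "imputed")
  expect_identical(nrow(out), ncol(sep$expr))
})

test_that("an empty query set yields an empty report with all columns", {
  sep <- separable_two_class()
  panel <- select_panel(sep$expr, sep$labels, rfe_params(top_m = 2))
  model <- train_model(sep$expr, sep$labels, panel, seed = 1)
  empty <- expr_cols(sep$expr, character(0))
  out <- predict(model, empty)
  expect_identical(nrow(out), 0L)
  expect_true(all(c("sample_id", model$class_names, "predicted_type",
                    "top_score", "tie_flag") %in% names(out)))
})

test_that("training validates panel coverage and class sizes", {
  sep <- separable_two_class()
  panel <- as_gene_panel(data.frame(gene_id = c("g001", "nosuchgene"),
                                    tumor_type = "alpha", rank = 1:2))
  expect_error(train_model(sep$expr, sep$labels, panel, seed = 1), "nosuchgene")
  small <- sep$labels
  small$label[small$label == "beta"] <- "alpha"
  small$label[1:3] <- "tiny"
  panel2 <- as_gene_panel(data.frame(gene_id = c("g001", "g002"),
                                     tumor_type = "alpha", rank = 1:2))
  expect_error(train_model(sep$expr, small, panel2, seed = 1), "tiny")
})
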