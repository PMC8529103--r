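test_that("config validation names the offending field", {
  expect_error(sim_config(n_types = 1), "n_types")
  expect_error(sim_config(n_genes = 10), "n_genes")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(metastasis_attenuation = 0), "metastasis_attenuation")
  expect_error(sim_config(qc_fail_fraction = 1.5), "qc_fail_fraction")
})

test_that("reference dimensions, labels and counts follow the config", {
  cfg <- sim_config(n_types = 3, n_genes = 50, n_per_type = 20, seed = 9)
  ref <- generate_reference(cfg)
  expect_identical(dim(ref$counts), c(50L, 60L))
  expect_identical(expr_scale(ref$counts), "counts")
  expect_true(all(ref$counts >= 0))
  expect_true(all(ref$counts == round(ref$counts)))
  expect_identical(as.vector(table(ref$labels$label)), rep(20L, 3))
  expect_identical(ref$labels$sample_id, colnames(ref$counts))
  expect_length(ref$params$marker_sets, 3L)
  expect_true(all(lengths(ref$params$marker_sets) == cfg$markers_per_type))
  # disjoint by default
  expect_identical(anyDuplicated(unlist(ref$params$marker_sets)), 0L)
})

test_that("identical config and seed reproduce identical outputs", {
  cfg <- sim_config(n_types = 3, n_genes = 40, n_per_type = 10, seed = 4)
  a <- generate_reference(cfg)
  b <- generate_reference(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$labels, b$labels)
  expect_identical(a$metadata, b$metadata)
  qa <- generate_query(cfg, a, 15)
  qb <- generate_query(cfg, b, 15)
  expect_identical(qa$counts, qb$counts)
})

test_that("zero fold change leaves marker genes indistinguishable across types", {
  cfg <- sim_config(n_types = 2, n_genes = 30, n_per_type = 500,
                    markers_per_type = 5, log2_fold_change = 0,
                    libsize_sdlog = 0, seed = 21)
  ref <- generate_reference(cfg)
  lab <- ref$labels$label
  pvals <- vapply(names(ref$params$marker_sets), function(ty) {
    vapply(ref$params$marker_sets[[ty]], function(g) {
      stats::t.test(unclass(ref$counts)[g, lab == ty],
                    unclass(ref$counts)[g, lab != ty])$p.value
    }, numeric(1))
  }, numeric(cfg$markers_per_type))
  # at alpha = 0.01 over 10 tests, more than 2 rejections would be surprising
  expect_lte(sum(pvals < 0.01), 2L)
})

test_that("marker means match the generative 2^lfc effect after removing library factors", {
  cfg <- sim_config(n_types = 2, n_genes = 40, n_per_type = 500,
                    markers_per_type = 5, log2_fold_change = 2,
                    nb_dispersion = 0.1, seed = 33)
  ref <- generate_reference(cfg)
  lab <- ref$labels$label
  descaled <- sweep(unclass(ref$counts), 2, ref$params$lib_factors, `/`)
  for (ty in names(ref$params$marker_sets)) {
    for (g in ref$params$marker_sets[[ty]][1:2]) {
      own <- mean(descaled[g, lab == ty])
      expect_lt(abs(own / (4 * ref$params$baseline_means[g]) - 1), 0.1)
    }
  }
})

test_that("marker separation grows with the fold change", {
  smd <- vapply(c(0.5, 1, 2), function(lfc) {
    cfg <- sim_config(n_types = 2, n_genes = 40, n_per_type = 100,
                      markers_per_type = 5, log2_fold_change = lfc,
                      seed = 8)
    ref <- generate_reference(cfg)
    norm <- normalize_counts(ref$counts)
    lab <- ref$labels$label
    g <- ref$params$marker_sets[[1]]
    ty <- names(ref$params$marker_sets)[1]
    own <- unclass(norm)[g, lab == ty, drop = FALSE]
    rest <- unclass(norm)[g, lab != ty, drop = FALSE]
    mean((rowMeans(own) - rowMeans(rest)) /
           sqrt((apply(own, 1, sd)^2 + apply(rest, 1, sd)^2) / 2))
  }, numeric(1))
  expect_true(all(diff(smd) > 0))
})

test_that("queries carry attenuated primary signal and query batch", {
  cfg <- sim_config(n_types = 3, n_genes = 60, n_per_type = 10, seed = 2)
  ref <- generate_reference(cfg)
  qry <- generate_query(cfg, ref, 25)
  expect_identical(dim(qry$counts), c(60L, 25L))
  expect_true(all(qry$metadata$batch == "query"))
  expect_true(all(qry$labels$label %in% ref$params$type_names))
  expect_error(generate_query(cfg, ref, 0), "n_queries")
})

test_that("attenuation 1 with no noise reproduces the primary mean profile", {
  cfg <- sim_config(n_types = 2, n_genes = 30, n_per_type = 300,
                    markers_per_type = 5, metastasis_attenuation = 1,
                    nb_dispersion = 0, libsize_sdlog = 0, seed = 6)
  ref <- generate_reference(cfg)
  qry <- generate_query(cfg, ref, 600)
  for (ty in ref$params$type_names) {
    q_mean <- rowMeans(unclass(qry$counts)[, qry$labels$label == ty])
    r_mean <- rowMeans(unclass(ref$counts)[, ref$labels$label == ty])
    # Poisson means at ~n=300: agree within a few percent
    expect_lt(max(abs(q_mean / r_mean - 1)), 0.15)
  }
})

test_that("the configured fraction of queries violates the QC gate", {
  cfg <- sim_config(n_types = 2, n_genes = 30, n_per_type = 5,
                    markers_per_type = 5, qc_fail_fraction = 0.25, seed = 13)
  ref <- generate_reference(cfg)
  qry <- generate_query(cfg, ref, 400)
  verdicts <- qc_filter(qry$metadata, qc_policy())
  n_fail <- sum(!verdicts$pass)
  # 99% binomial interval around 100 failures out of 400
  expect_gt(n_fail, stats::qbinom(0.005, 400, 0.25))
  expect_lt(n_fail, stats::qbinom(0.995, 400, 0.25))
})

test_that("batch-effect injection is a no-op at zero spread and shifts per gene otherwise", {
  mat <- make_expr(matrix(rnorm(40 * 12, 5), 40))
  meta <- data.frame(sample_id = colnames(mat),
                     batch = rep(c("b1", "b2"), 6))
  same <- inject_batch_effects(mat, meta, 0, 0, seed = 1)
  expect_equal(unclass(same), unclass(mat), ignore_attr = TRUE, tolerance = 1e-12)
  one <- inject_batch_effects(mat, meta,
                              shift_sd = 2, scale_sdlog = 0, seed = 1)
  # single batch: each gene moves by one constant shift
  meta1 <- data.frame(sample_id = colnames(mat), batch = "all")
  shifted <- inject_batch_effects(mat, meta1, 2, 0, seed = 3)
  deltas <- unclass(shifted) - unclass(mat)
  expect_lt(max(abs(deltas - rowMeans(deltas))), 1e-9)
  expect_error(inject_batch_effects(mat, meta[-1, ], 1, 0, seed = 1),
               "no batch assignment")
})

test_that("between-batch mean differences have the injected spread", {
  mat <- make_expr(matrix(rnorm(2000 * 60, 6, 0.1), 2000))
  meta <- data.frame(sample_id = colnames(mat),
                     batch = rep(c("b1", "b2"), each = 30))
  pert <- inject_batch_effects(mat, meta, shift_sd = 3, scale_sdlog = 0, seed = 5)
  b <- meta$batch[match(colnames(pert), meta$sample_id)]
  diffs <- rowMeans(unclass(pert)[, b == "b1"]) -
    rowMeans(unclass(pert)[, b == "b2"])
  # difference of two independent N(0, 9) shifts: SD = 3 * sqrt(2)
  expect_lt(abs(sd(diffs) / (3 * sqrt(2)) - 1), 0.1)
})
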