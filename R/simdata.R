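#' Simulation configuration for the synthetic pan-cancer compendium
#'
#' The generator emulates the statistical structure a tissue-of-origin
#' pipeline assumes: `n_types` tumor types, each with a planted set of
#' `markers_per_type` marker genes whose expected expression is multiplied by
#' `2^log2_fold_change` in samples of that type; log-normal baseline gene
#' abundances; log-normal per-sample library-size variation; negative-binomial
#' counting noise; optional batch structure; and metastasis-like query
#' samples whose marker effect is attenuated by a factor
#' `metastasis_attenuation` in log2 units.
#'
#' The full-size compendium behind published pan-cancer classifiers of this
#' kind (21 tumor types, thousands of samples, top-10 markers per type) is
#' expressible here (`n_types = 21`, `markers_per_type = 10`), but the
#' defaults are desk-scale: 6 types, 300 genes, 60 samples per type.
#'
#' @param n_types number of tumor types K (>= 2).
#' @param n_genes number of genes G; must fit all disjoint marker sets.
#' @param n_per_type reference samples per type.
#' @param markers_per_type planted markers per type.
#' @param log2_fold_change marker effect size in log2 units.
#' @param nb_dispersion negative-binomial dispersion alpha in the
#'   mean-dispersion parameterization `var = mu + alpha * mu^2`; 0 gives
#'   Poisson counts.
#' @param libsize_sdlog sdlog of the log-normal per-sample library factor.
#' @param metastasis_attenuation multiplicative damping rho in (0, 1] of the
#'   marker log2 effect in query (metastasis) samples.
#' @param batch_shift_sd SD tau of additive per-gene-per-batch shifts used by
#'   [inject_batch_effects()].
#' @param batch_scale_sdlog sdlog of multiplicative per-gene-per-batch scale
#'   factors used by [inject_batch_effects()].
#' @param qc_fail_fraction fraction of query specimens drawn to violate the
#'   QC gate (out-of-range A260/A280 or low tumor content).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   gene mean counts.
#' @param marker_overlap fraction in \[0, 1) of each type's markers drawn
#'   from a pool shared across types (exercises panel deduplication);
#'   0 keeps marker sets disjoint.
#' @param n_batches number of reference batches samples are assigned to.
#' @param seed master seed; every sub-stage derives its own stream from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_types = 6L, n_genes = 300L, n_per_type = 60L,
                       markers_per_type = 10L, log2_fold_change = 2,
                       nb_dispersion = 0.1, libsize_sdlog = 0.25,
                       metastasis_attenuation = 0.8, batch_shift_sd = 0,
                       batch_scale_sdlog = 0, qc_fail_fraction = 0,
                       baseline_meanlog = 4, baseline_sdlog = 1,
                       marker_overlap = 0, n_batches = 2L, seed = 1L) {
  cfg <- list(n_types = as.integer(n_types), n_genes = as.integer(n_genes),
              n_per_type = as.integer(n_per_type),
              markers_per_type = as.integer(markers_per_type),
              log2_fold_change = log2_fold_change,
              nb_dispersion = nb_dispersion, libsize_sdlog = libsize_sdlog,
              metastasis_attenuation = metastasis_attenuation,
              batch_shift_sd = batch_shift_sd,
              batch_scale_sdlog = batch_scale_sdlog,
              qc_fail_fraction = qc_fail_fraction,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              marker_overlap = marker_overlap,
              n_batches = as.integer(n_batches), seed = as.integer(seed))
  chk <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid simulation config: `%s` %s", field, why))
  }
  chk(cfg$n_types >= 2L, "n_types", "must be >= 2")
  chk(cfg$n_per_type >= 1L, "n_per_type", "must be >= 1")
  chk(cfg$markers_per_type >= 1L, "markers_per_type", "must be >= 1")
  disjoint_need <- ceiling(cfg$n_types * cfg$markers_per_type * (1 - cfg$marker_overlap))
  chk(cfg$n_genes >= disjoint_need, "n_genes",
      sprintf("must be >= %d to fit the configured marker sets", disjoint_need))
  chk(cfg$nb_dispersion >= 0, "nb_dispersion", "must be >= 0")
  chk(cfg$libsize_sdlog >= 0, "libsize_sdlog", "must be >= 0")
  chk(cfg$metastasis_attenuation > 0 && cfg$metastasis_attenuation <= 1,
      "metastasis_attenuation", "must lie in (0, 1]")
  chk(cfg$batch_shift_sd >= 0, "batch_shift_sd", "must be >= 0")
  chk(cfg$batch_scale_sdlog >= 0, "batch_scale_sdlog", "must be >= 0")
  chk(cfg$qc_fail_fraction >= 0 && cfg$qc_fail_fraction <= 1,
      "qc_fail_fraction", "must lie in [0, 1]")
  chk(cfg$marker_overlap >= 0 && cfg$marker_overlap < 1,
      "marker_overlap", "must lie in [0, 1)")
  chk(cfg$n_batches >= 1L, "n_batches", "must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# counts with var = mu + alpha * mu^2; alpha = 0 degenerates to Poisson
rcounts <- function(n, mu, alpha) {
  if (alpha == 0) stats::rpois(n, lambda = mu)
  else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

# per-gene expected counts by type: baseline times 2^lfc on each type's markers
type_mean_matrix <- function(baseline, marker_sets, lfc) {
  mu <- matrix(baseline, nrow = length(baseline), ncol = length(marker_sets),
               dimnames = list(names(baseline), names(marker_sets)))
  for (ty in names(marker_sets)) {
    mu[marker_sets[[ty]], ty] <- mu[marker_sets[[ty]], ty] * 2^lfc
  }
  mu
}

draw_metadata <- function(sample_ids, batch, labels, fail_fraction, seed) {
  n <- length(sample_ids)
  with_seed_(seed, {
    ratio <- stats::runif(n, 1.6, 2.2)
    tumor <- stats::runif(n, 65, 100)
    fail <- stats::runif(n) < fail_fraction
    if (any(fail)) {
      # rotate through the three ways a specimen can miss the gate
      mode <- (seq_len(sum(fail)) - 1L) %% 3L
      ratio[fail][mode == 0L] <- stats::runif(sum(mode == 0L), 0.6, 1.15)
      ratio[fail][mode == 1L] <- stats::runif(sum(mode == 1L), 2.45, 3.0)
      tumor[fail][mode == 2L] <- stats::runif(sum(mode == 2L), 10, 55)
    }
  })
  data.frame(sample_id = sample_ids, a260_a280 = ratio,
             tumor_content_pct = tumor, batch = batch,
             reference_diagnosis = labels, stringsAsFactors = FALSE)
}

#' Generate a synthetic reference compendium
#'
#' Draws a genes x samples count matrix for `n_types` tumor types with
#' planted marker genes, a label table, and specimen metadata. The planted
#' marker sets and the generative parameters are returned so downstream
#' checks can use them as oracles.
#'
#' @param config a [sim_config()].
#' @return a list of class `ref_simulation` with elements `counts`
#'   (an [expr_matrix()] of non-negative integers), `labels`
#'   (data.frame `sample_id`, `label`), `metadata` (data.frame with QC and
#'   batch fields), and `params` (baseline means, marker sets, library
#'   factors, type roster, and the config).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_types; G <- config$n_genes; n <- config$n_per_type
  gene_ids <- sprintf("gene%04d", seq_len(G))
  type_names <- sprintf("type%02d", seq_len(K))
  N <- K * n
  sample_ids <- sprintf("ref%04d", seq_len(N))
  labels <- rep(type_names, each = n)

  baseline <- with_seed_(derive_seed(config$seed, "baseline"),
                         stats::rlnorm(G, config$baseline_meanlog, config$baseline_sdlog))
  names(baseline) <- gene_ids

  marker_sets <- with_seed_(derive_seed(config$seed, "markers"), {
    m <- config$markers_per_type
    n_shared <- floor(config$marker_overlap * m)
    pool <- sample(gene_ids, n_shared + K * (m - n_shared))
    shared <- pool[seq_len(n_shared)]
    own <- if (n_shared > 0) pool[-seq_len(n_shared)] else pool
    sets <- lapply(seq_len(K), function(k) {
      sort(c(shared, own[((k - 1) * (m - n_shared) + 1):(k * (m - n_shared))]))
    })
    names(sets) <- type_names
    sets
  })

  mu_type <- type_mean_matrix(baseline, marker_sets, config$log2_fold_change)
  lib <- with_seed_(derive_seed(config$seed, "libsize"),
                    stats::rlnorm(N, 0, config$libsize_sdlog))
  names(lib) <- sample_ids

  counts <- with_seed_(derive_seed(config$seed, "counts"), {
    m <- matrix(0L, G, N, dimnames = list(gene_ids, sample_ids))
    for (j in seq_len(N)) {
      m[, j] <- rcounts(G, mu_type[, labels[j]] * lib[j], config$nb_dispersion)
    }
    m
  })

  batch <- with_seed_(derive_seed(config$seed, "batches"),
                      sample(rep_len(sprintf("batch%02d", seq_len(config$n_batches)), N)))
  metadata <- draw_metadata(sample_ids, batch, labels, fail_fraction = 0,
                            seed = derive_seed(config$seed, "metadata"))

  structure(list(
    counts = expr_matrix(counts, "counts"),
    labels = data.frame(sample_id = sample_ids, label = labels,
                        stringsAsFactors = FALSE),
    metadata = metadata,
    params = list(config = config, baseline_means = baseline,
                  marker_sets = marker_sets, lib_factors = lib,
                  type_names = type_names)
  ), class = "ref_simulation")
}

#' Generate metastasis-like query samples
#'
#' Query samples emulate CUP metastases: each carries a true primary type
#' whose marker effect is attenuated to
#' `log2_fold_change * metastasis_attenuation`. Their metadata is drawn so
#' that on average a `qc_fail_fraction` of specimens violates the QC gate,
#' and all queries are assigned to batch `"query"`.
#'
#' @param config the [sim_config()] used for the reference compendium.
#' @param reference a `ref_simulation` from [generate_reference()] (its
#'   generative parameters are reused).
#' @param n_queries number of query samples (>= 1).
#' @return a list of class `query_simulation` with `counts`, `labels`,
#'   `metadata` as in [generate_reference()].
#' @export
generate_query <- function(config, reference, n_queries) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "ref_simulation"))
  if (n_queries < 1) stop("`n_queries` must be >= 1")
  p <- reference$params
  G <- config$n_genes
  sample_ids <- sprintf("cup%04d", seq_len(n_queries))
  labels <- with_seed_(derive_seed(config$seed, "query_labels"),
                       sample(p$type_names, n_queries, replace = TRUE))
  lfc_q <- config$log2_fold_change * config$metastasis_attenuation
  mu_type <- type_mean_matrix(p$baseline_means, p$marker_sets, lfc_q)
  lib <- with_seed_(derive_seed(config$seed, "query_libsize"),
                    stats::rlnorm(n_queries, 0, config$libsize_sdlog))
  counts <- with_seed_(derive_seed(config$seed, "query_counts"), {
    m <- matrix(0L, G, n_queries,
                dimnames = list(names(p$baseline_means), sample_ids))
    for (j in seq_len(n_queries)) {
      m[, j] <- rcounts(G, mu_type[, labels[j]] * lib[j], config$nb_dispersion)
    }
    m
  })
  metadata <- draw_metadata(sample_ids, batch = "query", labels = labels,
                            fail_fraction = config$qc_fail_fraction,
                            seed = derive_seed(config$seed, "query_metadata"))
  structure(list(
    counts = expr_matrix(counts, "counts"),
    labels = data.frame(sample_id = sample_ids, label = labels,
                        stringsAsFactors = FALSE),
    metadata = metadata,
    params = list(config = config, lib_factors = stats::setNames(lib, sample_ids))
  ), class = "query_simulation")
}

#' Inject batch effects into a log-scale expression matrix
#'
#' For every gene and batch, an additive shift drawn from
#' `Normal(0, shift_sd^2)` and a multiplicative scale drawn log-normal with
#' sdlog `scale_sdlog` are applied around the gene's grand mean:
#' `y = m + scale * (x - m) + shift`. The drawn effects are attached as the
#' `batch_effects` attribute so correction routines can be tested against
#' the ground truth.
#'
#' @param mat a log2-scale [expr_matrix()].
#' @param metadata specimen metadata with `sample_id` and `batch` covering
#'   every column of `mat`.
#' @param shift_sd SD of the additive per-gene-per-batch shift.
#' @param scale_sdlog sdlog of the multiplicative per-gene-per-batch scale.
#' @param seed RNG seed for the effect draws.
#' @return the perturbed matrix (log2 scale) with attribute `batch_effects`,
#'   a list of `shift` and `scale` gene-x-batch matrices.
#' @export
inject_batch_effects <- function(mat, metadata, shift_sd, scale_sdlog, seed) {
  check_scale(mat, "log2")
  batch <- stats::setNames(metadata$batch, metadata$sample_id)
  missing <- setdiff(colnames(mat), metadata$sample_id)
  if (length(missing)) {
    stop("sample(s) with no batch assignment: ", paste(missing, collapse = ", "))
  }
  batches <- sort(unique(batch[colnames(mat)]))
  grand <- rowMeans(mat)
  out <- unclass(mat)
  eff <- with_seed_(seed, list(
    shift = matrix(stats::rnorm(nrow(mat) * length(batches), 0, shift_sd),
                   nrow(mat), length(batches),
                   dimnames = list(rownames(mat), batches)),
    scale = matrix(stats::rlnorm(nrow(mat) * length(batches), 0, scale_sdlog),
                   nrow(mat), length(batches),
                   dimnames = list(rownames(mat), batches))
  ))
  for (b in batches) {
    j <- which(batch[colnames(mat)] == b)
    out[, j] <- grand + eff$scale[, b] * (out[, j] - grand) + eff$shift[, b]
  }
  res <- expr_matrix(out, "log2")
  attr(res, "batch_effects") <- eff
  res
}
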