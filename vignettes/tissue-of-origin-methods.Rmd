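---
title: "Methods: marker-panel tissue-of-origin classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-panel tissue-of-origin classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A cancer of unknown primary (CUP) is a metastasis whose originating organ
cannot be established clinically. Expression-based tissue-of-origin assays
address this by profiling a small set of tumor-type-specific genes and
scoring how similar a specimen's pattern is to each candidate type. This
package implements that workflow — panel construction, classification with
calibrated similarity scores, the surrounding QC/normalization/batch
stages, and a PCA concordance validation — against a synthetic pan-cancer
compendium with planted ground truth, so that every stage's claim is
checkable.

# The generative model behind the simulator

`sim_config()` fixes the study conditions. For gene *i*, baseline mean
counts are log-normal(meanlog 4, sdlog 1), spanning realistic count
magnitudes (medians near e⁴ ≈ 55, upper tail in the thousands). Each of
the *K* types owns a disjoint set of *m* marker genes (defaults K = 6,
m = 10) whose mean is multiplied by `2^log2_fold_change` (default 2, i.e.
4×) in samples of that type. A per-sample library factor is
log-normal(0, 0.25). Counts are negative binomial in the mean–dispersion
parameterization `var = μ + αμ²` with α = 0.1 (α = 0 degenerates to
Poisson). Query ("metastasis") samples keep their primary's marker set but
with the log2 effect damped by ρ = 0.8, reflecting partial retention of
the primary signature in secondary lesions; their metadata is drawn so a
configurable fraction misses the QC gate. Batch effects are additive
shifts N(0, τ²) plus multiplicative scales log-normal(0, sdlog) applied
per gene and batch around the gene's grand mean, and the drawn effects are
retained as oracles.

Defaults are desk-scale: 6 types × 60 samples × 300 genes. The published
full-scale setting of this assay family — 21 tumor types, thousands of
compendium samples, top-10 markers per type collapsing to ~90 panel genes
— is expressible (`n_types = 21`, `markers_per_type = 10`) but is not a
test default; the test suite and the acceptance script state the sizes
they use. One master seed drives every stage through derived sub-streams,
so adding a stage never perturbs earlier draws and identical
configurations are bit-reproducible.

What the generator deliberately does not model: RT-PCR chemistry and Ct
scaling, FFPE degradation, correlated gene modules, impure (stromal)
expression mixtures, or the empirical relationship between PCR panels and
RNA-seq counts beyond a location–scale batch effect plus attenuation.
Passing tests therefore demonstrate the correctness and calibration of the
machinery under the stated statistical structure, not clinical performance
on tissue.

# Preprocessing

**QC gate.** A specimen passes iff A260/A280 ∈ [1.2, 2.4] and tumor-cell
content ≥ 60%, both bounds inclusive ("between" and "at least" read
inclusively); a missing field fails with reason `missing_field` rather
than passing silently, and all violated rules are reported.

**Normalization.** Size factors are median-of-ratios: over the genes with
strictly positive counts in every sample, `s_j = median_i(x_ij / g_i)`
with `g_i` the geometric mean of gene *i*. The median of an even count is
the mean of the two central ratios, taken on the ratio scale (not the log
scale — the two differ, and the brute-force oracle in the test suite pins
the ratio-scale definition). If no gene is everywhere positive the
estimator refuses (`no_reference_genes`). The transform is
`log2(x/s + 1)`, chosen over a 0.5 offset so a zero count maps to exactly
zero. Matrices carry a scale tag (`counts`/`log2`) that every operation
propagates, and wrong-scale input is a hard error, not a warning.

**Batch correction.** Per gene and batch, values are standardized by the
batch mean and SD and re-expressed around the gene's grand mean and its
*pooled within-batch* SD (weighted by batch degrees of freedom, computed
over the batches where the gene varies). The contract is that per-gene
batch means agree to 1e-9 after correction. Using the pooled within-batch
SD — rather than the global SD — is what makes the operation exactly
idempotent, which is part of its contract. Genes constant within a batch
(SD < 1e-12) are re-centered only; batches of size 1 are an error
(`degenerate_batch`) since no within-batch scale exists. This is a plain
location–scale adjustment by design: no empirical-Bayes shrinkage of batch
effects is attempted, because the tested contract (equal batch means,
idempotence, restored downstream accuracy) does not require it and the
simpler estimator is exactly analyzable.

# Panel selection

SVM-RFE is implemented in its classical form: fit a linear soft-margin SVM
(cost C = 1 on internally z-scored genes; inverse-frequency class weights
because "rest" dwarfs "target" in one-vs-rest), score each surviving gene
by *w_i²*, eliminate the lowest, repeat; rank 1 is the last survivor.
While more than 200 genes survive, the lowest 10% are dropped per
iteration for tractability; below that, exactly one per iteration for
fidelity. Exact criterion ties (e.g. duplicated columns) are eliminated
together, ordered by gene id, so rankings are deterministic. The panel is
the union of per-type top-*m* lists with duplicates recorded once —
"removing redundant genes" is read as union-deduplication, the minimal
interpretation; correlation-based pruning is intentionally out of scope.

One structural caveat found while validating against planted markers: with
exactly two types, the two one-vs-rest contrasts are the same binary
problem mirrored, so both types produce essentially the same ranking and
the union stays near size *m* rather than 2*m*. Marker-recovery properties
are therefore meaningful for K ≥ 3, and the package's recovery checks run
at K = 3 and K = 6.

# The classifier and its similarity scores

"Similarity score" is specified only by its contract — each score in
[0, 100], all scores summing to 100, argmax is the call. The construction
chosen here is the standard probability mapping for margin classifiers:
per-class Platt sigmoids `p_k = σ(A_k d_k + B_k)` on one-vs-rest decision
values, renormalized to 100. (A_k, B_k) are fit by penalized maximum
likelihood (Platt's smoothed targets, ridge 1e-6 for degenerate decision
sets, BFGS) on decision values from 5 stratified cross-validation folds
under a fixed seed — calibrating on training-set values would be
overconfident. Renormalization guarantees the sum contract regardless of
calibration quality; score ties (within 1e-9) go to the lexicographically
smallest type name and set an explicit flag rather than relying on an
arbitrary argmax.

Degenerate cases: if every calibrated probability underflows to zero the
score is undefined and the classifier errors (`degenerate_calibration`);
queries missing panel genes are a hard error unless mean imputation from
the training statistics is explicitly requested (each imputation is
messaged). Counts-scale input to `predict()` is refused
(`unnormalized_input`). Models serialize to versioned JSON with 17
significant digits, the precision at which IEEE doubles round-trip
exactly; a deserialized model reproduces predictions identically.

# PCA centroid concordance

The in-silico validation projects reference and query specimens (panel
genes only, batch-corrected when cohorts are mixed) into a PCA space fit
on the reference: genes are centered but not rescaled, since panel genes
share the log2 scale and rescaling would flatten the very effect sizes
being visualized; queries are projected with reference-fit centering, with
no refitting. Component signs are fixed (largest-magnitude loading
positive) for cross-platform reproducibility. Each query is assigned to
the Euclidean-nearest class centroid; the concordant fraction is the share
assigned to their true primary.

`pca_fit()` defaults to d = 2, the dimension of the published style of
cluster figure. For the quantitative concordance check, however, the
pipeline uses d = K − 1: K centroids span a (K − 1)-dimensional subspace,
and with 6 types a 2-component projection demonstrably merges distinct
clusters (measured concordance ≈ 0.8 at d = 2 versus 1.0 at d = 5 on the
same data). Two components remain the right choice for plotting; K − 1 is
the right choice for measuring.

# Evaluation conventions

Concordance is exact, case-sensitive label agreement; the machine-readable
accuracy is full precision while the display string *truncates* to one
decimal (42/44 = 95.4545…% displays as "95.4%" — consistent with how such
rates appear in clinical reports, which is truncation rather than
rounding). Per-modality coincidence rates are computed over each
modality's non-missing entries with the denominator reported alongside —
modalities are rarely assessed for every specimen, so a shared denominator
cannot be assumed — and a modality with no assessments is flagged
undefined rather than scored 0. Discordant specimens are reported one row
each with the predicted type and its top similarity score, ordered by
sample id.

# Problem sizes and numerical choices

The test suite and acceptance script run the desk-scale conditions (K = 6,
G = 300, 60 samples/type, 90 queries; panel selection is the dominant cost
at roughly 200 SVM fits per type). The demonstration pipeline
(`demo_pipeline_config()`) uses K = 4, G = 120, 30 samples/type with batch
effects and QC failures enabled, and completes in seconds. Key tolerances:
batch-mean equality and idempotence at 1e-9; score-sum contract at 1e-6;
SVD orthonormality and reconstruction at 1e-8; within-batch degenerate-SD
threshold 1e-12; tie detection at 1e-9 (scores) and 1e-12 (centroid
distances).

# Limitations

Validation is entirely against the synthetic compendium; no claim is made
about tissue performance, where correlated expression programs, impure
sections, platform transfer and label noise all matter and are not
modeled. The calibration construction (per-class Platt + renormalization)
is one of several reasonable choices (pairwise coupling, multinomial
regression); only the stated score contract, not a specific probability
construction, should be relied on downstream. SVM-RFE is run once on the
full training set — no stability selection or cross-validated elimination
— and the regularization C = 1 is a convention on standardized features,
not a tuned value.
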